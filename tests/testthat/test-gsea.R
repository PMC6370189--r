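test_that("Signal2Noise matches closed forms including the sd floor", {
  design <- sample_design(paste0("s", 1:6), rep(c("A", "B"), each = 3))
  v <- rbind(flat = rep(1, 6),
             unit = c(1, 2, 3, -1, 0, 1),     # means 2 vs 0, sds exactly 1
             const = c(1, 1, 1, 0, 0, 0))     # zero variance both sides
  colnames(v) <- design$sample_id
  r <- signal_to_noise(expr_matrix(v, "log2"), design, "A", "B")
  expect_equal(unname(r["flat"]), 0)
  expect_equal(unname(r["unit"]), 1.0)
  expect_equal(unname(r["const"]), 1 / (0.2 + 0.2))  # floors: 0.2|mu| vs 0.2
  d2 <- sample_design(paste0("s", 1:3), c("A", "A", "B"))
  expect_error(signal_to_noise(expr_matrix(v[, 1:3], "log2"), d2, "A", "B"),
               ">= 2 samples")
})

test_that("ranking is descending with lexicographic tie-break", {
  m <- c(b = 1, a = 1, c = 3, d = -2)
  rk <- rank_genes(m)
  expect_equal(rk$gene, c("c", "a", "b", "d"))
  expect_equal(rk$score, c(3, 1, 1, -2))
  expect_error(rank_genes(c(1, 2)), "named")
})

ranked_fixture <- function(scores, genes = sprintf("g%02d", seq_along(scores))) {
  rank_genes(stats::setNames(scores, genes))
}

test_that("enrichment score matches hand-derivable extremes", {
  rk <- ranked_fixture(10:1)
  top <- enrichment_score(rk, rk$gene[1])
  expect_equal(top$es, 1.0)
  expect_equal(top$leading_edge, rk$gene[1])
  bottom <- enrichment_score(rk, rk$gene[10])
  # nine misses accrue 9/(N - N_h) = 1 before the hit at the bottom
  expect_equal(bottom$es, -1.0)
  expect_equal(bottom$leading_edge, rk$gene[10])
  expect_error(enrichment_score(rk, "absent"), "no members")
  expect_error(enrichment_score(rk, rk$gene), "universe")
  zero <- rank_genes(stats::setNames(c(1, 0, -1), c("a", "b", "c")))
  expect_warning(res <- enrichment_score(zero, "b"), "zero")
  expect_equal(res$es, 0)
})

test_that("enrichment score equals the exhaustive running-sum oracle", {
  set.seed(41)
  for (rep in 1:40) {
    N <- sample(5:20, 1)
    scores <- round(rnorm(N), 3)
    rk <- ranked_fixture(scores)
    nh <- sample(1:min(6, N - 1), 1)
    members <- sample(rk$gene, nh)
    got <- enrichment_score(rk, members)$es
    want <- es_oracle(rk$score, rk$gene, members)
    expect_equal(got, want, tolerance = 1e-12)
    # fast positional form used in permutation loops agrees too
    pos <- sort(match(members, rk$gene))
    expect_equal(trmsig:::es_from_positions(pos, abs(rk$score[pos]), N),
                 want, tolerance = 1e-12)
    expect_lte(abs(got), 1)
  }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(43)
  for (rep in 1:20) {
    N <- sample(20:60, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    rk <- ranked_fixture(scores)
    members <- sample(rk$gene, sample(3:8, 1))
    got <- enrichment_score(rk, members)$es
    want <- fgsea::calcGseaStat(stats::setNames(rk$score, rk$gene),
                                sort(match(members, rk$gene)),
                                gseaParam = 1)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("reversing the list and negating the metric negates the ES", {
  set.seed(47)
  scores <- rnorm(30)  # continuous: no exact ties to hit the sign rule
  rk <- ranked_fixture(scores)
  members <- sample(rk$gene, 5)
  fwd <- enrichment_score(rk, members)$es
  flipped <- rank_genes(stats::setNames(-rk$score, rk$gene))
  rev <- enrichment_score(flipped, members)$es
  expect_equal(rev, -fwd, tolerance = 1e-12)
})

test_that("phenotype permutation enumerates distinct splits exhaustively", {
  sim <- simulate_expression(sim_config(n_genes = 120, seed = 51))
  lg <- log2_transform(sim$matrix)
  sets <- list(s1 = rownames(lg)[1:20], s2 = rownames(lg)[21:40])
  null <- permutation_null(lg, sim$design, sets, "TGFb", "Untreated",
                           mode = "phenotype", n_perm = 1000, seed = 1)
  expect_equal(nrow(null), 10L)  # choose(6,3)/2 distinct 3v3 splits
  expect_true(attr(null, "exhaustive"))
  # fewer than 10 distinct splits is refused
  d22 <- sample_design(paste0("s", 1:4), rep(c("A", "B"), each = 2))
  m22 <- expr_matrix(matrix(rnorm(40), 10, 4,
                            dimnames = list(paste0("g", 1:10), d22$sample_id)),
                     "log2")
  expect_error(permutation_null(m22, d22, sets["s1"], "A", "B",
                                mode = "phenotype", n_perm = 10, seed = 1),
               "gene_set")
})

test_that("gene-set permutation null is centred and seed-reproducible", {
  sim <- simulate_expression(sim_config(n_genes = 400, seed = 53,
                                        frac_tgfb_responsive = 0,
                                        frac_il2_responsive = 0))
  lg <- log2_transform(sim$matrix)
  sets <- list(s = sample(rownames(lg), 25))
  a <- permutation_null(lg, sim$design, sets, "TGFb", "Untreated",
                        n_perm = 400, seed = 9)
  b <- permutation_null(lg, sim$design, sets, "TGFb", "Untreated",
                        n_perm = 400, seed = 9)
  expect_identical(a, b)
  se <- stats::sd(a[, 1]) / sqrt(nrow(a))
  expect_lt(abs(mean(a[, 1])), 3 * se + 0.02)
})

test_that("nominal P, NES and q behave at the distribution extremes", {
  null <- matrix(c(runif(99, 0.05, 0.4), -runif(99, 0.05, 0.4)),
                 ncol = 2)
  colnames(null) <- c("pos", "neg")
  res <- gsea_significance(c(pos = 0.9, neg = -0.9), null)
  expect_equal(res$p, c(1 / 100, 1 / 100))
  expect_true(all(res$q < 0.25))
  expect_true(all(res$significant))

  sym <- matrix(c(seq(-0.5, 0.5, length.out = 100),
                  seq(-0.5, 0.5, length.out = 100)), ncol = 2)
  colnames(sym) <- c("a", "b")
  res0 <- gsea_significance(c(a = 0, b = 0.49), sym)
  expect_equal(res0$p[1], 1)
  expect_equal(res0$q[1], 1)
  expect_equal(res0$nes[1], 0)

  onesided <- matrix(-runif(50, 0.1, 0.5), ncol = 1,
                     dimnames = list(NULL, "s"))
  flag <- gsea_significance(c(s = 0.5), onesided)
  expect_true(flag$flagged)
  expect_true(is.na(flag$p))
})

test_that("run_gsea filters small sets, is deterministic, honours the rule", {
  sim <- simulate_expression(sim_config(n_genes = 600, seed = 55))
  lg <- log2_transform(sim$matrix)
  truth <- sim$truth$genes
  up <- truth$gene[truth$tgfb_lfc > 0]
  sets <- list(planted = up[1:20],
               tiny = rownames(lg)[1:5],
               random = sample(rownames(lg), 30))
  res <- run_gsea(lg, sim$design, sets, c("TGFb", "IL2_TGFb"),
                  c("Untreated", "IL2"), n_perm = 200, seed = 6)
  expect_equal(attr(res, "excluded")$set, "tiny")
  expect_match(attr(res, "excluded")$reason, "minimum gene set size of 15")
  expect_setequal(res$set, c("planted", "random"))
  expect_true(res$significant[res$set == "planted"])
  expect_true(all(res$significant == (res$p < 0.05 & res$q < 0.25)))
  res2 <- run_gsea(lg, sim$design, sets, c("TGFb", "IL2_TGFb"),
                   c("Untreated", "IL2"), n_perm = 200, seed = 6)
  expect_equal(as.data.frame(res), as.data.frame(res2))
})

test_that("GMT, CLS and RNK files round-trip and reject malformed input", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, description = c("first", "second"))
  back <- read_gmt(path)
  expect_equal(back[], sets[], ignore_attr = TRUE)
  expect_equal(attr(back, "description"), c("first", "second"))
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("ok\tdesc\tg1\tg2", "broken\tdesc_only"), bad)
  expect_error(read_gmt(bad), "line 2")

  cls <- withr::local_tempfile(fileext = ".cls")
  labels <- rep(c("treated", "untreated"), each = 3)
  write_cls(labels, cls)
  expect_equal(read_cls(cls), labels)
  writeLines(c("6 2 1", "# A B", "0 0 0 1 1 1"), cls)
  expect_equal(read_cls(cls), rep(c("A", "B"), each = 3))
  writeLines(c("4 2 1", "# A B", "A A B"), cls)
  expect_error(read_cls(cls), "4 samples")

  rk <- ranked_fixture(c(3, 1, -2))
  rnk <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(rk, rnk)
  df <- utils::read.delim(rnk, header = FALSE)
  expect_equal(df[[2]], c(3, 1, -2))
})
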