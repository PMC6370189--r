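make_log2 <- function(v, design) {
  dimnames(v) <- list(sprintf("g%03d", seq_len(nrow(v))), design$sample_id)
  expr_matrix(v, "log2")
}

test_that("identical groups with zero noise give log2FC 0 and P 1", {
  design <- toy_design()
  v <- matrix(rep(c(2, 5, 3, 7), each = 12), nrow = 4, byrow = TRUE)
  de <- differential_expression(make_log2(v, design), design,
                                comparison_spec("t_vs_u", "TGFb", "Untreated"))
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$p == 1))
  expect_true(all(de$direction == "ns"))
})

test_that("swapping treated and reference negates log2FC, preserves P", {
  sim <- simulate_expression(sim_config(n_genes = 200, seed = 17))
  lg <- log2_transform(sim$matrix)
  fwd <- differential_expression(lg, sim$design,
                                 comparison_spec("f", "TGFb", "Untreated"))
  rev <- differential_expression(lg, sim$design,
                                 comparison_spec("r", "Untreated", "TGFb"))
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$p, fwd$p, tolerance = 1e-12)
})

test_that("replicate requirements and design mismatches are caught", {
  design <- toy_design(1)
  v <- matrix(rnorm(16), 4, 4)
  expect_error(differential_expression(make_log2(v, design), design,
                                       comparison_spec("c", "TGFb", "Untreated")),
               ">= 2 replicates")
  d3 <- toy_design()
  expect_error(comparison_spec("bad", "TGFb", "TGFb"), "overlap")
  wrong <- make_log2(matrix(rnorm(48), 4, 12), d3)
  colnames(wrong)[1] <- "other"
  expect_error(differential_expression(expr_matrix(unclass(wrong), "log2"),
                                       d3, comparison_spec("c", "TGFb", "Untreated")),
               "sample ids")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # exhaustive oracle over random small instances
  set.seed(31)
  for (n in 2:8) {
    p <- round(runif(n), 3)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # adjusted >= raw, order-preserving
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("planted strong effects are recovered with high power", {
  design <- toy_design()
  set.seed(23)
  n_alt <- 100; n_null <- 400
  mu <- c(rep(2, n_alt + n_null))
  v <- matrix(rnorm(500 * 12, mu, 0.35), 500, 12)
  tg <- design$condition %in% c("TGFb", "IL2_TGFb")
  v[seq_len(n_alt), tg] <- v[seq_len(n_alt), tg] + 2  # delta = +2
  de <- differential_expression(make_log2(v, design), design,
                                comparison_spec("t", "TGFb", "Untreated"))
  power <- mean(de$direction[seq_len(n_alt)] == "up")
  expect_gt(power, 0.9)
  # directions obey the definition
  expect_true(all((de$direction == "up") == (de$fdr < 0.05 & de$log2fc > 0)))
  expect_true(all((de$direction == "down") == (de$fdr < 0.05 & de$log2fc < 0)))
})

test_that("tier counts match enumeration and brute-force scans", {
  de <- structure(
    data.frame(gene = paste0("g", 1:5),
               mean_treated = 0, mean_reference = 0,
               log2fc = c(0.5, 1.5, 2.5, -1.2, 0.3),
               t = 0, p = c(rep(0.001, 4), 0.9),
               fdr = c(rep(0.01, 4), 0.9),
               direction = c("up", "up", "up", "down", "ns"),
               stringsAsFactors = FALSE),
    comparison = "toy", alpha = 0.05, n_treated = 3, n_reference = 3,
    class = c("de_result", "data.frame"))
  tc <- tier_counts(de)
  expect_equal(tc$total, c(4, 3, 1))
  expect_equal(tc$up, c(3, 2, 1))
  expect_equal(tc$down, c(1, 1, 0))

  empty <- de; empty$fdr <- 1; empty$direction <- "ns"
  expect_true(all(tier_counts(empty)[, c("total", "up", "down")] == 0))

  sim <- simulate_expression(sim_config(n_genes = 1500, seed = 19))
  lg <- log2_transform(filter_low_expression(sim$matrix))
  d <- differential_expression(lg, sim$design,
                               comparison_spec("t", "TGFb", "Untreated"))
  tc <- tier_counts(d)
  for (i in seq_len(nrow(tc))) {
    keep <- d$fdr < 0.05 & abs(d$log2fc) > tc$tier[i] & d$direction != "ns"
    expect_equal(tc$total[i], sum(keep))
    expect_equal(tc$up[i], sum(keep & d$log2fc > 0))
  }
  # stricter tiers are nested
  expect_true(all(diff(tc$total) <= 0))
  expect_true(all(tc$up + tc$down == tc$total))
})

test_that("direction-consistent intersection behaves on constructed cases", {
  base <- data.frame(gene = paste0("g", 1:4), mean_treated = 0,
                     mean_reference = 0, log2fc = 1, t = 1, p = 0.01,
                     fdr = 0.01, direction = "up", stringsAsFactors = FALSE)
  mk <- function(dirs, name) {
    d <- base; d$direction <- dirs
    structure(d, comparison = name, alpha = 0.05, n_treated = 3,
              n_reference = 3, class = c("de_result", "data.frame"))
  }
  a <- mk(c("up", "up", "down", "ns"), "a")
  b <- mk(c("up", "down", "down", "up"), "b")
  got <- intersect_comparisons(list(a, b))
  expect_equal(got$up, "g1")        # g2 flips direction, g4 ns in a
  expect_equal(got$down, "g3")
  disjoint <- intersect_comparisons(list(mk(c("up", "ns", "ns", "ns"), "a"),
                                         mk(c("ns", "up", "ns", "ns"), "b")))
  expect_length(disjoint$all, 0)
  other <- mk(rep("up", 4), "c"); other$gene <- paste0("h", 1:4)
  expect_error(intersect_comparisons(list(a, other)), "universe")
})
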