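fake_de <- function(genes, dirs, name = "toy") {
  structure(data.frame(gene = genes, mean_treated = 0, mean_reference = 0,
                       log2fc = ifelse(dirs == "down", -1,
                                       ifelse(dirs == "up", 1, 0)),
                       t = 0, p = 0.01,
                       fdr = ifelse(dirs == "ns", 0.9, 0.01),
                       direction = dirs, stringsAsFactors = FALSE),
            comparison = name, alpha = 0.05, n_treated = 3, n_reference = 3,
            class = c("de_result", "data.frame"))
}

test_that("directional overlap counts only same-direction significant genes", {
  sig <- as_signature(c("A", "B"), c("up", "down"))
  de <- fake_de(c("A", "B", "C"), c("up", "up", "ns"))
  ov <- directional_overlap(sig, de)
  expect_equal(ov$o_obs, 1L)
  expect_equal(ov$k, 2L)
  expect_equal(ov$m, 2L)
  expect_equal(ov$per_gene$status, c("concordant", "discordant"))

  # missing and non-DE members are labelled, not fatal
  sig2 <- as_signature(c("A", "C", "Z"), c("up", "up", "down"))
  ov2 <- directional_overlap(sig2, de)
  expect_equal(ov2$per_gene$status, c("concordant", "not_de", "not_measured"))
  expect_equal(ov2$percent, 100 / 3)

  none <- directional_overlap(sig, fake_de(c("A", "B"), c("ns", "ns")))
  expect_equal(none$o_obs, 0L)
  expect_equal(none$percent, 0)
  expect_error(as_signature(character(0), character(0)), ">= 1")
  expect_error(as_signature(c("A", "A"), c("up", "up")), "duplicate")
})

test_that("a 21-of-35 concordant construction reports 60 percent overlap", {
  genes <- sprintf("g%02d", 1:35)
  sig <- as_signature(genes, c(rep("up", 30), rep("down", 5)))
  dirs <- c(rep("up", 18), rep("down", 9), rep("ns", 3),
            rep("down", 3), rep("up", 2))
  ov <- directional_overlap(sig, fake_de(genes, dirs))
  expect_equal(ov$o_obs, 21L)
  expect_equal(ov$percent, 60)
})

test_that("bootstrap P handles edge cases and is reproducible", {
  expect_equal(bootstrap_enrichment(0L, universe = 100L, B = 50, seed = 1,
                                    k = 5, m = 10)$p, 1)
  a <- bootstrap_enrichment(3L, universe = 200L, B = 500, seed = 5,
                            k = 10, m = 20)
  b <- bootstrap_enrichment(3L, universe = 200L, B = 500, seed = 5,
                            k = 10, m = 20)
  expect_identical(a$p, b$p)
  expect_gt(a$p, 0)
  expect_lte(a$p, 1)
  expect_error(bootstrap_enrichment(3L, universe = 200L, B = 500,
                                    k = 10, m = 20), "seed")
  expect_error(bootstrap_enrichment(3L, universe = 200L, B = 0, seed = 1,
                                    k = 10, m = 20), "B must be")
  expect_error(bootstrap_enrichment(3L, universe = 5L, B = 10, seed = 1,
                                    k = 10, m = 20), "universe")
})

test_that("bootstrap P is non-increasing in the observed overlap", {
  ps <- vapply(0:6, function(o)
    bootstrap_enrichment(o, universe = 300L, B = 400, seed = 77,
                         k = 15, m = 30)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("bootstrap null agrees with the hypergeometric tail for k,m << N", {
  B <- 4000
  grid <- list(c(k = 15, m = 30, N = 2000, o = 1),
               c(k = 20, m = 60, N = 3000, o = 1),
               c(k = 35, m = 120, N = 5000, o = 2))
  for (g in grid) {
    got <- bootstrap_enrichment(g[["o"]], universe = g[["N"]], B = B,
                                seed = 101, k = g[["k"]], m = g[["m"]])$p
    want <- hyper_tail(g[["o"]], g[["k"]], g[["m"]], g[["N"]])
    se <- sqrt(want * (1 - want) / B)
    # 3 Monte-Carlo SEs plus a small allowance for the dedup-after-
    # replacement null being slightly thinner than fixed-size sampling
    expect_lt(abs(got - want), 3 * se + 0.02 * want + 1 / (B + 1))
  }
})

test_that("direction-aware null is more permissive than direction-blind", {
  sig <- as_signature(sprintf("s%02d", 1:20), rep(c("up", "down"), 10))
  genes <- sprintf("g%03d", 1:300)
  dirs <- c(rep("up", 20), rep("down", 20), rep("ns", 260))
  ov <- directional_overlap(sig, fake_de(genes, dirs))
  blind <- bootstrap_enrichment(ov, genes, B = 500, seed = 3)
  aware <- bootstrap_enrichment(ov, genes, B = 500, seed = 3,
                                mode = "direction_aware")
  # same-direction matching can only shrink null overlaps
  expect_lte(aware$null_mean, blind$null_mean)
})

test_that("overlap reports serialise to JSON and TSV", {
  sig <- as_signature(c("A", "B"), c("up", "down"))
  ov <- directional_overlap(sig, fake_de(c("A", "B"), c("up", "down")))
  ov <- bootstrap_enrichment(ov, c("A", "B", "C", "D"), B = 50, seed = 2)
  js <- withr::local_tempfile(fileext = ".json")
  ts <- withr::local_tempfile(fileext = ".tsv")
  write_overlap_report(ov, js, ts)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$o_obs, 2L)
  expect_equal(parsed$k, 2L)
  expect_equal(nrow(utils::read.delim(ts)), 2L)
})
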