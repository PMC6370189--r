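# Independent oracles used across the suite. These are deliberately naive
# re-implementations (direct definitions, exhaustive loops) kept separate from
# the package's code paths.

# Benjamini-Hochberg by the raw definition: adj_i = min over ranks j >= rank_i
# of p_(j) * n / j, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    ri <- which(ord == i)  # rank of p[i]
    cand <- vapply(ri:n, function(j) p[ord[j]] * n / j, numeric(1))
    adj[i] <- min(1, cand)
  }
  adj
}

# Weighted running-sum enrichment score by direct accumulation over every
# rank position; same tie rule (positive extreme wins exact ties).
es_oracle <- function(scores, genes, members, p = 1) {
  N <- length(scores)
  hit <- genes %in% members
  NR <- sum(abs(scores[hit])^p)
  Nh <- sum(hit)
  phit <- pmiss <- 0
  D <- numeric(N)
  for (i in seq_len(N)) {
    if (hit[i]) phit <- phit + abs(scores[i])^p / NR
    else pmiss <- pmiss + 1 / (N - Nh)
    D[i] <- phit - pmiss
  }
  if (max(D) >= -min(D)) max(D) else min(D)
}

# Upper tail P(X >= o) of the overlap of two fixed-size random subsets.
hyper_tail <- function(o, k, m, N) {
  stats::phyper(o - 1, k, N - k, m, lower.tail = FALSE)
}

# Small deterministic fpkm matrix for format/pipeline tests.
tiny_fpkm <- function(n_genes = 8, seed = 1) {
  set.seed(seed)
  v <- matrix(round(stats::rexp(n_genes * 4, 1 / 5), 4), n_genes, 4,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              paste0("s", 1:4)))
  expr_matrix(v, "fpkm")
}

design_cols <- function(design, condition) {
  design$sample_id[design$condition %in% condition]
}

# Four-condition design with planted group means, for hand-built DE inputs.
toy_design <- function(n_rep = 3) {
  cond <- rep(c("Untreated", "TGFb", "IL2", "IL2_TGFb"), each = n_rep)
  sample_design(paste(cond, rep(seq_len(n_rep), 4), sep = "_"), cond)
}
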