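#' Configuration for the synthetic expression generator
#'
#' Defines the statistical structure of a simulated 12-sample study: four
#' conditions (Untreated, TGFb, IL2, IL2_TGFb) x `n_replicates`, gene-level
#' log2 baselines, a TGF-beta main effect biased toward up-regulation, an
#' independent IL-2 effect, a directional signature of which a configurable
#' fraction responds concordantly to TGF-beta, and planted gene sets for
#' enrichment testing.
#'
#' Effect sizes are |log2FC| ~ Exponential(mean = `effect_size_mean`) + 0.5;
#' the 0.5 floor keeps "responsive" well separated from replicate noise at
#' n = 3. Replicate noise is Normal(0, `replicate_sd`) in log2 space and
#' FPKM = max(2^signal - 1, 0).
#'
#' @param n_genes number of genes (default 11000).
#' @param n_replicates replicates per condition (default 3).
#' @param baseline_mean,baseline_sd log2-FPKM baseline distribution.
#' @param replicate_sd log2-scale replicate noise SD.
#' @param frac_tgfb_responsive fraction of genes with a TGF-beta effect.
#' @param frac_up_among_responsive fraction of TGF-beta effects that are
#'   up-regulated (default 0.6).
#' @param effect_size_mean mean of the exponential |log2FC| component.
#' @param frac_il2_responsive fraction of genes with an IL-2 effect
#'   (sign unbiased; drawn independently of the TGF-beta set).
#' @param signature_size,signature_concordance,signature_up_count directional
#'   signature size (default 35), fraction of members planted concordantly
#'   (default 0.6) and number annotated "up" (default 30).
#' @param n_planted_sets,set_size planted gene-set count (default 10, half up
#'   half down) and size (default 50; must be >= 15).
#' @param n_control_sets negative-control sets drawn from non-responsive
#'   genes (default 2).
#' @param seed integer seed; the same config + seed reproduces every output
#'   bit-for-bit.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 11000L, n_replicates = 3L,
                       baseline_mean = 3.0, baseline_sd = 1.5,
                       replicate_sd = 0.35,
                       frac_tgfb_responsive = 0.08,
                       frac_up_among_responsive = 0.6,
                       effect_size_mean = 1.5,
                       frac_il2_responsive = 0.08,
                       signature_size = 35L,
                       signature_concordance = 0.6,
                       signature_up_count = 30L,
                       n_planted_sets = 10L, set_size = 50L,
                       n_control_sets = 2L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              replicate_sd = replicate_sd,
              frac_tgfb_responsive = frac_tgfb_responsive,
              frac_up_among_responsive = frac_up_among_responsive,
              effect_size_mean = effect_size_mean,
              frac_il2_responsive = frac_il2_responsive,
              signature_size = as.integer(signature_size),
              signature_concordance = signature_concordance,
              signature_up_count = as.integer(signature_up_count),
              n_planted_sets = as.integer(n_planted_sets),
              set_size = as.integer(set_size),
              n_control_sets = as.integer(n_control_sets),
              seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$n_replicates < 1L)
    stop("n_genes and n_replicates must be positive")
  fr <- c(cfg$frac_tgfb_responsive, cfg$frac_up_among_responsive,
          cfg$frac_il2_responsive, cfg$signature_concordance)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$replicate_sd < 0 || cfg$baseline_sd < 0)
    stop("standard deviations must be non-negative")
  if (cfg$signature_up_count > cfg$signature_size)
    stop("signature_up_count cannot exceed signature_size")
  if (cfg$signature_size > cfg$n_genes)
    stop("signature_size cannot exceed n_genes")
  if (cfg$set_size < 15L)
    stop("set_size must be >= 15 (minimum gene set size)")
  if (cfg$effect_size_mean <= 0) stop("effect_size_mean must be positive")
  class(cfg) <- "sim_config"
  cfg
}

sim_conditions <- c("Untreated", "TGFb", "IL2", "IL2_TGFb")

#' Generate a synthetic FPKM matrix with planted truth
#'
#' Draws per-gene log2 baselines, plants a TGF-beta effect delta_g in a
#' random subset of genes (sign up with probability
#' `frac_up_among_responsive`, |delta| ~ Exp(mean) + 0.5) and an independent
#' IL-2 effect gamma_g, then emits
#' `FPKM = max(2^(baseline + delta*[TGFb in condition] +
#' gamma*[IL2 in condition] + noise) - 1, 0)`.
#'
#' @param config a [sim_config].
#' @return list with components `matrix` (an [expr_matrix] on the fpkm
#'   scale), `design` (a [sample_design]) and `truth` (class `sim_truth`:
#'   data.frame `genes` with per-gene `tgfb_lfc`, `il2_lfc`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("gene%05d", seq_len(ng))

  baseline <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)

  n_tgfb <- round(config$frac_tgfb_responsive * ng)
  tgfb_idx <- sample.int(ng, n_tgfb)
  tgfb_lfc <- numeric(ng)
  if (n_tgfb > 0) {
    sign <- ifelse(stats::runif(n_tgfb) < config$frac_up_among_responsive, 1, -1)
    mag <- stats::rexp(n_tgfb, rate = 1 / config$effect_size_mean) + 0.5
    tgfb_lfc[tgfb_idx] <- sign * mag
  }

  n_il2 <- round(config$frac_il2_responsive * ng)
  il2_idx <- sample.int(ng, n_il2)
  il2_lfc <- numeric(ng)
  if (n_il2 > 0) {
    sign <- ifelse(stats::runif(n_il2) < 0.5, 1, -1)
    mag <- stats::rexp(n_il2, rate = 1 / config$effect_size_mean) + 0.5
    il2_lfc[il2_idx] <- sign * mag
  }

  nr <- config$n_replicates
  condition <- rep(sim_conditions, each = nr)
  sample_id <- paste(condition, rep(seq_len(nr), times = 4), sep = "_")
  design <- sample_design(sample_id, condition, rep(seq_len(nr), times = 4))

  has_tgfb <- condition %in% c("TGFb", "IL2_TGFb")
  has_il2 <- condition %in% c("IL2", "IL2_TGFb")
  signal <- baseline +
    outer(tgfb_lfc, as.numeric(has_tgfb)) +
    outer(il2_lfc, as.numeric(has_il2))
  noise <- matrix(stats::rnorm(ng * length(sample_id), 0, config$replicate_sd),
                  ng, length(sample_id))
  fpkm <- pmax(2^(signal + noise) - 1, 0)
  dimnames(fpkm) <- list(genes, sample_id)

  truth <- structure(
    list(genes = data.frame(gene = genes, tgfb_lfc = tgfb_lfc,
                            il2_lfc = il2_lfc, stringsAsFactors = FALSE),
         config = config),
    class = "sim_truth")
  list(matrix = expr_matrix(fpkm, "fpkm"), design = design, truth = truth)
}

#' Generate a directional gene signature with planted concordance
#'
#' Builds a `signature_size`-gene directional signature from the planted
#' truth: `round(signature_concordance * signature_size)` members are
#' concordant — TGF-beta-responsive genes whose planted effect sign matches
#' their annotated direction — and the remainder are discordant members drawn
#' from non-responsive genes. Annotated directions total
#' `signature_up_count` up and the rest down, with the concordant members
#' split between up and down in proportion to that annotation.
#'
#' @param config the [sim_config] used to generate the data.
#' @param truth the `sim_truth` returned by [simulate_expression()].
#' @param seed seed for member sampling (default `config$seed + 1`).
#' @return data.frame of class `directional_signature` with columns `gene`,
#'   `direction` and a logical `concordant` column recording the planted
#'   truth; the truth columns are annotation, not part of the signature file
#'   format.
#' @export
simulate_signature <- function(config, truth, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(seed)
  k <- config$signature_size
  k_up <- config$signature_up_count
  k_down <- k - k_up
  n_conc <- round(config$signature_concordance * k)
  conc_up <- min(round(n_conc * k_up / k), k_up)
  conc_down <- min(n_conc - conc_up, k_down)
  conc_up <- n_conc - conc_down

  lfc <- truth$genes$tgfb_lfc
  pool_up <- truth$genes$gene[lfc > 0]
  pool_down <- truth$genes$gene[lfc < 0]
  pool_null <- truth$genes$gene[lfc == 0]
  if (length(pool_up) < conc_up || length(pool_down) < conc_down)
    stop("not enough responsive genes for the requested concordant members; ",
         "increase frac_tgfb_responsive")
  n_disc <- k - n_conc
  if (length(pool_null) < n_disc)
    stop("not enough non-responsive genes for discordant signature members")

  g_conc_up <- sample(pool_up, conc_up)
  g_conc_down <- sample(pool_down, conc_down)
  g_disc <- sample(pool_null, n_disc)
  disc_up <- k_up - conc_up
  sig <- data.frame(
    gene = c(g_conc_up, g_conc_down, g_disc),
    direction = c(rep("up", conc_up), rep("down", conc_down),
                  rep("up", disc_up), rep("down", n_disc - disc_up)),
    concordant = c(rep(TRUE, n_conc), rep(FALSE, n_disc)),
    stringsAsFactors = FALSE)
  sig <- sig[order(sig$gene), ]
  rownames(sig) <- NULL
  class(sig) <- c("directional_signature", "data.frame")
  sig
}

#' Generate planted and negative-control gene sets
#'
#' Creates `n_planted_sets` gene sets of `set_size` members: half sampled
#' from planted up-regulated genes, half from planted down-regulated genes,
#' plus `n_control_sets` negative-control sets drawn from TGF-beta
#' non-responsive genes. Controls are disjoint from the responsive pool by
#' construction.
#'
#' @inheritParams simulate_signature
#' @param seed seed for member sampling (default `config$seed + 2`).
#' @return named list of character vectors with a `set_direction` attribute
#'   (`"up"`, `"down"` or `"none"` per set).
#' @export
simulate_gene_sets <- function(config, truth, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(seed)
  lfc <- truth$genes$tgfb_lfc
  pool_up <- truth$genes$gene[lfc > 0]
  pool_down <- truth$genes$gene[lfc < 0]
  pool_null <- truth$genes$gene[lfc == 0]
  n_up_sets <- ceiling(config$n_planted_sets / 2)
  n_down_sets <- config$n_planted_sets - n_up_sets
  sz <- config$set_size
  if (length(pool_up) < sz || (n_down_sets > 0 && length(pool_down) < sz))
    stop("not enough responsive genes to fill planted sets of size ", sz,
         "; increase frac_tgfb_responsive")
  if (length(pool_null) < sz)
    stop("not enough non-responsive genes for control sets")
  sets <- c(
    lapply(seq_len(n_up_sets), function(i) sample(pool_up, sz)),
    lapply(seq_len(n_down_sets), function(i) sample(pool_down, sz)),
    lapply(seq_len(config$n_control_sets), function(i) sample(pool_null, sz))
  )
  names(sets) <- c(paste0("TRM_up_", seq_len(n_up_sets)),
                   paste0("TRM_down_", seq_len(n_down_sets)),
                   paste0("control_", seq_len(config$n_control_sets)))
  attr(sets, "set_direction") <- stats::setNames(
    c(rep("up", n_up_sets), rep("down", n_down_sets),
      rep("none", config$n_control_sets)), names(sets))
  sets
}

#' @export
print.sim_truth <- function(x, ...) {
  g <- x$genes
  cat(sprintf("sim_truth: %d genes; %d TGF-beta responsive (%d up / %d down), %d IL-2 responsive\n",
              nrow(g), sum(g$tgfb_lfc != 0), sum(g$tgfb_lfc > 0),
              sum(g$tgfb_lfc < 0), sum(g$il2_lfc != 0)))
  invisible(x)
}

#' Persist the planted truth as JSON
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(
    list(config = unclass(truth$config), genes = truth$genes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
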