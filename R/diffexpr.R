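#' Moderated two-sample t differential expression
#'
#' Per-gene two-group test on log2-scale expression with empirical-Bayes-style
#' variance shrinkage, suited to small replicate numbers (n = 3 per side in
#' the study design). For gene g with group means `mu_A` (treated), `mu_B`
#' (reference), pooled variance `s_g^2` on `d = n_A + n_B - 2` degrees of
#' freedom, the shrunken variance is
#' `s~_g^2 = (d0 * s0^2 + d * s_g^2) / (d0 + d)` with prior df `d0 = 4` and
#' prior scale `s0^2` the median of the per-gene pooled variances. The
#' statistic `t = (mu_A - mu_B) / (s~_g * sqrt(1/n_A + 1/n_B))` is referred
#' to a Student t with `d0 + d` df (two-sided). `log2FC = mu_A - mu_B`.
#'
#' Direction calls: `up` iff BH-adjusted P < `alpha` and log2FC > 0, `down`
#' iff adjusted P < `alpha` and log2FC < 0, otherwise `ns` (a gene at exactly
#' log2FC = 0 is `ns` even when significant). Genes with zero variance on
#' both sides and zero difference get P = 1 by convention.
#'
#' @param x an [expr_matrix] on the log2 scale.
#' @param design a [sample_design] covering the matrix columns.
#' @param comparison a [comparison_spec].
#' @param alpha FDR threshold for direction calls (default 0.05).
#' @param d0 prior degrees of freedom for variance shrinkage (default 4).
#' @return data.frame of class `de_result` with columns `gene`,
#'   `mean_treated`, `mean_reference`, `log2fc`, `t`, `p`, `fdr`,
#'   `direction`; attributes `comparison`, `alpha`, `n_treated`,
#'   `n_reference`.
#' @export
differential_expression <- function(x, design, comparison, alpha = 0.05,
                                    d0 = 4) {
  assert_scale(x, "log2")
  stopifnot(inherits(comparison, "comparison_spec"))
  check_design_matches(design, x)
  a_ids <- design_samples(design, comparison$treated)
  b_ids <- design_samples(design, comparison$reference)
  nA <- length(a_ids); nB <- length(b_ids)
  if (nA < 2 || nB < 2)
    stop("each side of a comparison needs >= 2 replicates (got ",
         nA, " vs ", nB, ")")
  A <- unclass(x)[, a_ids, drop = FALSE]
  B <- unclass(x)[, b_ids, drop = FALSE]
  muA <- rowMeans(A); muB <- rowMeans(B)
  varA <- apply(A, 1, stats::var); varB <- apply(B, 1, stats::var)
  d <- nA + nB - 2
  s2 <- ((nA - 1) * varA + (nB - 1) * varB) / d
  s02 <- stats::median(s2)
  s2_tilde <- (d0 * s02 + d * s2) / (d0 + d)
  lfc <- muA - muB
  se <- sqrt(s2_tilde * (1 / nA + 1 / nB))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- 2 * stats::pt(-abs(tstat), df = d0 + d)
  fdr <- bh_adjust(p)
  direction <- ifelse(fdr < alpha & lfc > 0, "up",
                      ifelse(fdr < alpha & lfc < 0, "down", "ns"))
  out <- data.frame(gene = rownames(x), mean_treated = muA,
                    mean_reference = muB, log2fc = lfc, t = tstat,
                    p = p, fdr = fdr, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "comparison") <- comparison$name
  attr(out, "alpha") <- alpha
  attr(out, "n_treated") <- nA
  attr(out, "n_reference") <- nB
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted P-values `min over j >= i of p_(j) * n / j` (step-up), preserving
#' the order of the inputs. Delegates to [stats::p.adjust()] after validating
#' the inputs.
#'
#' @param p numeric vector of P-values in \[0, 1\].
#' @return adjusted P-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("P-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %s (%d vs %d replicates), %d genes\n",
              attr(x, "comparison"), attr(x, "n_treated"),
              attr(x, "n_reference"), nrow(x)))
  n_up <- sum(x$direction == "up"); n_down <- sum(x$direction == "down")
  cat(sprintf("  FDR < %g: %d DE genes (%d up / %d down)\n",
              attr(x, "alpha"), n_up + n_down, n_up, n_down))
  invisible(x)
}

#' Fold-change tier counts for one comparison
#'
#' Counts significant genes (FDR < `alpha`) overall and within stricter
#' absolute fold-change tiers (`|log2FC| >` each element of `lfc_tiers`),
#' split into up- and down-regulated — the layout of a DE summary table with
#' columns "FDR < 0.05", "|log2FC| > 1 & FDR < 0.05", "|log2FC| > 2 &
#' FDR < 0.05".
#'
#' @param de a `de_result`.
#' @param alpha FDR threshold (default the one stored in `de`).
#' @param lfc_tiers additional |log2FC| cutoffs (default `c(1, 2)`).
#' @return data.frame with columns `comparison`, `tier`, `total`, `up`,
#'   `down`; one row per tier (tier `0` is the plain FDR cut).
#' @export
tier_counts <- function(de, alpha = attr(de, "alpha"), lfc_tiers = c(1, 2)) {
  stopifnot(inherits(de, "de_result"))
  sig <- de$fdr < alpha
  tiers <- c(0, lfc_tiers)
  rows <- lapply(tiers, function(th) {
    keep <- sig & abs(de$log2fc) > th
    data.frame(comparison = attr(de, "comparison"), tier = th,
               total = sum(keep & de$direction != "ns"),
               up = sum(keep & de$direction == "up"),
               down = sum(keep & de$direction == "down"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname tier_counts
#' @param de_list list of `de_result` objects.
#' @export
tier_table <- function(de_list, alpha = NULL, lfc_tiers = c(1, 2)) {
  rows <- lapply(de_list, function(de)
    tier_counts(de, alpha = if (is.null(alpha)) attr(de, "alpha") else alpha,
                lfc_tiers = lfc_tiers))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Direction-consistent intersection of DE results
#'
#' Genes called significant (direction `up` or `down`) in *every* supplied
#' result with the *same* direction throughout, partitioned into common-up
#' and common-down — the "common DE genes across comparisons" analysis.
#'
#' @param de_list list of >= 2 `de_result` objects on the same gene universe.
#' @return list with components `up`, `down` (character vectors) and `all`
#'   (their union), plus `n_comparisons`.
#' @export
intersect_comparisons <- function(de_list) {
  if (length(de_list) < 2) stop("need >= 2 DE results to intersect")
  genes <- de_list[[1]]$gene
  for (de in de_list[-1])
    if (!identical(sort(de$gene), sort(genes)))
      stop("DE results are not on the same gene universe")
  dirs <- sapply(de_list, function(de) de$direction[match(genes, de$gene)])
  common_up <- genes[rowSums(dirs == "up") == length(de_list)]
  common_down <- genes[rowSums(dirs == "down") == length(de_list)]
  list(up = common_up, down = common_down,
       all = c(common_up, common_down), n_comparisons = length(de_list))
}

#' Write a DE result as TSV
#'
#' @param de a `de_result`.
#' @param path output path.
#' @export
write_de_tsv <- function(de, path) {
  stopifnot(inherits(de, "de_result"))
  utils::write.table(as.data.frame(de)[, c("gene", "log2fc", "p", "fdr",
                                           "direction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
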