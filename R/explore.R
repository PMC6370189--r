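#' Principal component analysis of sample expression profiles
#'
#' PCA of the samples of a gene-standardised matrix: components of the
#' sample-by-sample covariance (covariance between sample columns across
#' genes). Zero-variance genes flagged by [standardise()] are dropped first.
#' Variance fractions are the normalised eigenvalue spectrum; per-sample
#' scores are the eigenvectors scaled by the component standard deviations.
#'
#' @param x an [expr_matrix] on the standardised scale.
#' @param design optional [sample_design]; carried into the result for
#'   plotting.
#' @return list of class `trm_pca` with `variance_fraction` (non-increasing,
#'   sums to 1), `scores` (samples x components) and `design`.
#' @export
expression_pca <- function(x, design = NULL) {
  assert_scale(x, "standardised")
  if (ncol(x) < 2) stop("PCA needs >= 2 samples")
  v <- drop_zero_variance(x)
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$rotation %*% diag(pc$sdev, length(pc$sdev))
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(variance_fraction = frac, scores = scores, design = design),
            class = "trm_pca")
}

drop_zero_variance <- function(x) {
  v <- unclass(x)
  zv <- attr(x, "zero_variance")
  if (!is.null(zv) && any(zv)) v <- v[!zv, , drop = FALSE]
  v
}

#' @export
print.trm_pca <- function(x, ...) {
  k <- min(5L, length(x$variance_fraction))
  cat("PCA of", nrow(x$scores), "samples\n")
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * x$variance_fraction[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.trm_pca <- function(x, components = c(1, 2), ...) {
  s <- x$scores[, components, drop = FALSE]
  cond <- if (!is.null(x$design))
    factor(x$design$condition[match(rownames(s), x$design$sample_id)])
  else factor(rep("sample", nrow(s)))
  graphics::plot(s[, 1], s[, 2], col = as.integer(cond), pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                100 * x$variance_fraction[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                100 * x$variance_fraction[components[2]]), ...)
  graphics::legend("topright", legend = levels(cond),
                   col = seq_along(levels(cond)), pch = 19, bty = "n")
  invisible(x)
}

cluster_distances <- c(maximum = "maximum", euclidean = "euclidean",
                       manhattan = "manhattan")
cluster_linkages <- c(ward = "ward.D2", complete = "complete",
                      average = "average", single = "single")

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of sample expression profiles. The default
#' matches the study's dendrogram: Ward's method run on a precomputed
#' Chebyshev ("maximum") dissimilarity matrix between sample profiles. Ward
#' linkage on a non-Euclidean dissimilarity is formally a heuristic and merge
#' heights need not be monotone in rare cases; with `distance = "euclidean"`
#' heights are non-decreasing.
#'
#' @param x an [expr_matrix] on the standardised scale (zero-variance genes
#'   dropped).
#' @param linkage one of `"ward"`, `"complete"`, `"average"`, `"single"`.
#' @param distance one of `"maximum"` (Chebyshev), `"euclidean"`,
#'   `"manhattan"`.
#' @return `hclust` object (merge history, heights, leaf order) with the
#'   chosen linkage/distance recorded in `$method` and `$dist.method`.
#' @export
cluster_samples <- function(x, linkage = "ward", distance = "maximum") {
  assert_scale(x, "standardised")
  if (ncol(x) < 2) stop("clustering needs >= 2 samples")
  if (!linkage %in% names(cluster_linkages))
    stop("unknown linkage '", linkage, "'; supported: ",
         paste(names(cluster_linkages), collapse = ", "))
  if (!distance %in% names(cluster_distances))
    stop("unknown distance '", distance, "'; supported: ",
         paste(names(cluster_distances), collapse = ", "))
  v <- drop_zero_variance(x)
  d <- stats::dist(t(v), method = cluster_distances[[distance]])
  hc <- stats::hclust(d, method = cluster_linkages[[linkage]])
  hc$dist.method <- distance
  hc
}

#' Purity of a k-cluster cut against sample labels
#'
#' Cuts the tree into `k` clusters and reports the fraction of samples whose
#' cluster's majority label matches their own — 1.0 means the cut separates
#' the label groups perfectly.
#'
#' @param hc an `hclust` over samples.
#' @param labels named vector (names = sample ids) or vector in leaf-label
#'   order.
#' @param k number of clusters (default 2).
#' @return purity in \[0, 1\].
#' @export
cluster_purity <- function(hc, labels, k = 2) {
  cl <- stats::cutree(hc, k = k)
  if (!is.null(names(labels))) labels <- labels[names(cl)]
  agree <- sum(unlist(lapply(split(as.character(labels), cl),
                             function(lab) max(table(lab)))))
  agree / length(cl)
}
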