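#' Expression matrix with an explicit scale tag
#'
#' An `expr_matrix` is a dense numeric genes x samples matrix carrying a
#' `scale` attribute recording what the values are: `"fpkm"` (non-negative
#' abundances), `"log2"` (log2(FPKM + pseudocount)) or `"standardised"`
#' (per-gene z-scores). Downstream stages check the tag so that, e.g., the
#' low-expression filter cannot be run on already-log-transformed values.
#'
#' @param values numeric matrix with unique, non-empty rownames (gene ids)
#'   and colnames (sample ids).
#' @param scale one of `"fpkm"`, `"log2"`, `"standardised"`.
#' @return A matrix of class `expr_matrix` with a `scale` attribute.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' x <- expr_matrix(m, "fpkm")
#' expr_scale(x)
#' @export
expr_matrix <- function(values, scale = c("fpkm", "log2", "standardised")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  gn <- rownames(values)
  sn <- colnames(values)
  if (is.null(gn) && nrow(values) == 0L)  # empty after filtering
    rownames(values) <- gn <- character(0)
  if (is.null(gn) || is.null(sn))
    stop("expression matrix needs rownames (genes) and colnames (samples)")
  if (anyDuplicated(gn))
    stop("duplicate gene ids: ",
         paste(unique(gn[duplicated(gn)]), collapse = ", "))
  if (anyDuplicated(sn))
    stop("duplicate sample ids: ",
         paste(unique(sn[duplicated(sn)]), collapse = ", "))
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (scale == "fpkm" && any(values < 0))
    stop("fpkm values must be non-negative")
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) stop("not an expr_matrix: no scale attribute")
  s
}

assert_scale <- function(x, expected) {
  s <- expr_scale(x)
  if (!s %in% expected)
    stop(sprintf("expected a matrix on scale %s, got '%s'",
                 paste(sQuote(expected), collapse = " or "), s))
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [scale: %s]\n",
              nrow(x), ncol(x), expr_scale(x)))
  zv <- attr(x, "zero_variance")
  if (!is.null(zv) && any(zv))
    cat(sprintf("  %d zero-variance gene(s) flagged\n", sum(zv)))
  n <- min(5L, nrow(x)); m <- min(6L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n) cat(sprintf("  ... %d more genes\n", nrow(x) - n))
  invisible(x)
}

#' Read / write an expression matrix as TSV
#'
#' The TSV layout is: header line with `gene_id` followed by sample ids; one
#' row per gene, first field the gene id, remaining fields numeric. Parsing is
#' strict: ragged rows, non-numeric cells and duplicate ids raise errors that
#' name the offending line or id.
#'
#' @param path file path.
#' @param scale scale tag to attach on read (files store plain numbers).
#' @return `read_expression_tsv` returns an [expr_matrix];
#'   `write_expression_tsv` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, scale = "fpkm") {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) < 2) stop("expression TSV needs a header and >= 1 gene row: ", path)
  bad <- which(nf != nf[1])
  if (length(bad))
    stop(sprintf("ragged row in %s at line %d (%d fields, expected %d)",
                 path, bad[1], nf[bad[1]], nf[1]))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicated gene id(s) in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell in %s at line %d (gene '%s', sample '%s')",
                 path, bad[1] + 1L, genes[bad[1]], colnames(vals)[bad[2]]))
  }
  dimnames(num) <- list(genes, colnames(vals))
  expr_matrix(num, scale)
}

#' @rdname read_expression_tsv
#' @param x an [expr_matrix].
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove lowly expressed genes
#'
#' Keeps genes whose mean FPKM across all samples exceeds `cutoff`
#' (default 0.3, the conventional threshold for calling a gene expressed in
#' FPKM units). Set `rule = "all_samples"` to instead require every sample to
#' exceed the cutoff. Gene order is preserved.
#'
#' @param x an [expr_matrix] on the fpkm scale.
#' @param cutoff non-negative FPKM threshold.
#' @param rule `"mean"` (default) or `"all_samples"`.
#' @return filtered [expr_matrix], still on the fpkm scale.
#' @export
filter_low_expression <- function(x, cutoff = 0.3, rule = c("mean", "all_samples")) {
  assert_scale(x, "fpkm")
  rule <- match.arg(rule)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0)
    stop("'cutoff' must be a single non-negative number")
  keep <- if (rule == "mean") rowMeans(x) > cutoff else
    apply(unclass(x), 1, function(v) all(v > cutoff))
  expr_matrix(unclass(x)[keep, , drop = FALSE], "fpkm")
}

#' Log2 transform with pseudocount
#'
#' `value = log2(fpkm + pseudocount)`. The default pseudocount of 1 keeps
#' zero FPKM at zero and is monotone in the input.
#'
#' @param x an [expr_matrix] on the fpkm scale.
#' @param pseudocount positive offset (must be > 0 whenever any fpkm is 0).
#' @return an [expr_matrix] on the log2 scale.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  assert_scale(x, "fpkm")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0)
    stop("'pseudocount' must be a single non-negative number")
  if (pseudocount == 0 && any(x == 0))
    stop("pseudocount must be > 0 when the matrix contains zero fpkm values")
  expr_matrix(log2(unclass(x) + pseudocount), "log2")
}

#' Per-gene standardisation (row z-scores)
#'
#' Each gene is centred and scaled to unit standard deviation across samples.
#' Zero-variance genes are mapped to all-zero rows and flagged in the
#' `zero_variance` attribute (a named logical vector); PCA and clustering drop
#' them since a z-score is undefined there.
#'
#' @param x an [expr_matrix] on the log2 scale (an already standardised matrix
#'   is accepted, making the operation idempotent).
#' @return an [expr_matrix] on the standardised scale.
#' @export
standardise <- function(x) {
  assert_scale(x, c("log2", "standardised"))
  v <- unclass(x)
  mu <- rowMeans(v)
  sd <- apply(v, 1, stats::sd)
  zero <- sd == 0
  sd[zero] <- 1
  z <- (v - mu) / sd
  z[zero, ] <- 0
  out <- expr_matrix(z, "standardised")
  attr(out, "zero_variance") <- stats::setNames(zero, rownames(v))
  out
}
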