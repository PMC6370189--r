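#' Sample design for the four-condition stimulation experiment
#'
#' Maps sample ids to a condition and replicate. The four conditions of the
#' study design are `Untreated`, `TGFb`, `IL2` and `IL2_TGFb`; any condition
#' labels are accepted as long as each condition used in a comparison has at
#' least two replicates.
#'
#' @param sample_id character vector of unique sample ids.
#' @param condition character/factor vector, same length.
#' @param replicate integer vector, same length (defaults to 1..n within
#'   condition).
#' @return data.frame of class `sample_design` with columns
#'   `sample_id`, `condition`, `replicate`.
#' @export
sample_design <- function(sample_id, condition, replicate = NULL) {
  sample_id <- as.character(sample_id)
  condition <- as.character(condition)
  if (length(sample_id) != length(condition))
    stop("'sample_id' and 'condition' must have equal length")
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in design")
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  df <- data.frame(sample_id = sample_id, condition = condition,
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  class(df) <- c("sample_design", "data.frame")
  df
}

#' @rdname sample_design
#' @param path TSV with columns sample_id, condition, replicate.
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% names(df)))
    stop("design TSV must have columns: ", paste(need, collapse = ", "))
  sample_design(df$sample_id, df$condition,
                if ("replicate" %in% names(df)) df$replicate else NULL)
}

#' @rdname sample_design
#' @param design a `sample_design`.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

design_samples <- function(design, conditions) {
  conditions <- as.character(conditions)
  miss <- setdiff(conditions, design$condition)
  if (length(miss))
    stop("condition(s) not in design: ", paste(miss, collapse = ", "))
  design$sample_id[design$condition %in% conditions]
}

check_design_matches <- function(design, x) {
  if (!setequal(design$sample_id, colnames(x)) ||
      length(design$sample_id) != ncol(x))
    stop("design sample ids do not match matrix columns")
  invisible(TRUE)
}

#' Pairwise comparison specification
#'
#' A comparison names a treated and a reference side, each one or more
#' condition labels (composite groups such as all TGF-beta-exposed samples are
#' allowed). Fold changes are treated minus reference.
#'
#' @param name comparison label.
#' @param treated,reference character vectors of condition labels; must be
#'   disjoint.
#' @return list of class `comparison_spec`.
#' @export
comparison_spec <- function(name, treated, reference) {
  treated <- as.character(treated); reference <- as.character(reference)
  if (length(intersect(treated, reference)))
    stop("treated and reference conditions overlap: ",
         paste(intersect(treated, reference), collapse = ", "))
  if (!length(treated) || !length(reference))
    stop("both sides of a comparison need >= 1 condition")
  structure(list(name = name, treated = treated, reference = reference),
            class = "comparison_spec")
}

#' The study's four pairwise comparisons
#'
#' Returns the four treated-vs-untreated pairwise comparisons of the design.
#' The first three (TGFb vs Untreated, IL2_TGFb vs Untreated, IL2_TGFb vs
#' IL2) contrast TGF-beta-exposed with TGF-beta-naive cells and feed the
#' signature-overlap stage; the fourth (IL2_TGFb vs TGFb) isolates the IL-2
#' effect and is reported but not used downstream.
#'
#' @return named list of [comparison_spec] objects with a
#'   `feeds_signature_stage` logical attribute.
#' @export
default_comparisons <- function() {
  cmp <- list(
    TGFb_vs_Untreated     = comparison_spec("TGFb_vs_Untreated", "TGFb", "Untreated"),
    IL2_TGFb_vs_Untreated = comparison_spec("IL2_TGFb_vs_Untreated", "IL2_TGFb", "Untreated"),
    IL2_TGFb_vs_IL2       = comparison_spec("IL2_TGFb_vs_IL2", "IL2_TGFb", "IL2"),
    IL2_TGFb_vs_TGFb      = comparison_spec("IL2_TGFb_vs_TGFb", "IL2_TGFb", "TGFb")
  )
  attr(cmp, "feeds_signature_stage") <-
    c(TRUE, TRUE, TRUE, FALSE)
  cmp
}
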