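#' Read / write a directional signature TSV
#'
#' Format: two tab-separated columns, `gene` and `direction` (`up` or
#' `down`), with a header line.
#'
#' @param path file path.
#' @return data.frame of class `directional_signature` with columns `gene`,
#'   `direction`.
#' @export
read_signature_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% names(df)))
    stop("signature TSV must have columns 'gene' and 'direction': ", path)
  as_signature(df$gene, df$direction)
}

#' @rdname read_signature_tsv
#' @param signature a `directional_signature`.
#' @export
write_signature_tsv <- function(signature, path) {
  utils::write.table(as.data.frame(signature)[, c("gene", "direction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_signature_tsv
#' @param gene,direction character vectors defining the signature.
#' @export
as_signature <- function(gene, direction) {
  gene <- as.character(gene); direction <- as.character(direction)
  if (!length(gene)) stop("a signature needs >= 1 gene")
  if (anyDuplicated(gene))
    stop("duplicate signature genes: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  if (!all(direction %in% c("up", "down")))
    stop("signature directions must be 'up' or 'down'")
  df <- data.frame(gene = gene, direction = direction,
                   stringsAsFactors = FALSE)
  class(df) <- c("directional_signature", "data.frame")
  df
}

#' Directional concordant overlap between a signature and a DE result
#'
#' A signature gene counts as overlapping only when it is significantly DE
#' in the comparison *and* its DE direction equals its annotated signature
#' direction. Each signature gene is labelled `concordant`, `discordant`
#' (significant but opposite direction), `not_de`, or `not_measured` (absent
#' from the tested universe; reported, not fatal).
#'
#' @param signature a `directional_signature` (k genes).
#' @param de a `de_result` (m = its significant gene count).
#' @return list of class `overlap_result`: `o_obs` (observed concordant
#'   overlap), `k`, `m`, `percent` (100 * o_obs / k), `per_gene`
#'   (data.frame gene, signature_direction, de_direction, status),
#'   `comparison`. The bootstrap fields (`p`, `B`, ...) are filled by
#'   [bootstrap_enrichment()].
#' @export
directional_overlap <- function(signature, de) {
  stopifnot(inherits(signature, "directional_signature"),
            inherits(de, "de_result"))
  idx <- match(signature$gene, de$gene)
  de_dir <- ifelse(is.na(idx), NA_character_, de$direction[idx])
  status <- ifelse(is.na(idx), "not_measured",
            ifelse(de_dir == "ns", "not_de",
            ifelse(de_dir == signature$direction, "concordant", "discordant")))
  per_gene <- data.frame(gene = signature$gene,
                         signature_direction = signature$direction,
                         de_direction = de_dir, status = status,
                         stringsAsFactors = FALSE)
  o_obs <- sum(status == "concordant")
  k <- nrow(signature)
  m <- sum(de$direction != "ns")
  structure(list(o_obs = o_obs, k = k, m = m, percent = 100 * o_obs / k,
                 per_gene = per_gene, comparison = attr(de, "comparison"),
                 N = NULL, B = NULL, p = NULL, null_mean = NULL),
            class = "overlap_result")
}

#' Bootstrap enrichment P-value for a gene-list overlap
#'
#' Null model for the significance of an overlap of `o_obs` genes between a
#' k-gene signature and an m-gene DE list drawn from a universe of N genes:
#' each bootstrap draws k gene labels and m gene labels with replacement
#' from the universe, deduplicates each draw, and records the intersection
#' size `o_b`. The enrichment P is the add-one empirical tail
#' `P = (1 + #\{b : o_b >= o_obs\}) / (B + 1)`, the probability of an overlap
#' at least as large as observed; the add-one keeps P > 0 at finite B.
#'
#' The default null is direction-blind (random labels carry no direction)
#' while `o_obs` is direction-constrained, which is conservative;
#' `mode = "direction_aware"` draws a direction for every label (signature
#' directions resampled from the signature, DE directions from the DE calls)
#' and counts only same-direction matches.
#'
#' @param overlap an `overlap_result` from [directional_overlap()], or a
#'   bare observed overlap count (then `k` and `m` must be supplied).
#' @param universe character vector of gene labels (or a single integer N).
#' @param B number of bootstraps (default 10000).
#' @param seed integer seed (required: no silent global RNG state).
#' @param mode `"direction_blind"` (default) or `"direction_aware"`.
#' @param k,m draw sizes when `overlap` is a bare count.
#' @param signature_directions,de_directions direction label pools for
#'   `mode = "direction_aware"` (defaults taken from the overlap object).
#' @return the `overlap_result` with `N`, `B`, `p`, `null_mean` filled in
#'   (for a bare count, a new `overlap_result` with those fields).
#' @export
bootstrap_enrichment <- function(overlap, universe, B = 10000L, seed,
                                 mode = c("direction_blind", "direction_aware"),
                                 k = NULL, m = NULL,
                                 signature_directions = NULL,
                                 de_directions = NULL) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for a reproducible bootstrap")
  if (!is.numeric(B) || length(B) != 1 || B < 1) stop("B must be >= 1")
  B <- as.integer(B)
  if (inherits(overlap, "overlap_result")) {
    o_obs <- overlap$o_obs; k <- overlap$k; m <- overlap$m
    if (is.null(signature_directions))
      signature_directions <- overlap$per_gene$signature_direction
    if (is.null(de_directions)) {
      dd <- overlap$per_gene$de_direction
      de_directions <- dd[!is.na(dd) & dd != "ns"]
    }
  } else {
    o_obs <- as.integer(overlap)
    if (is.null(k) || is.null(m))
      stop("with a bare observed count, supply k and m")
    overlap <- structure(list(o_obs = o_obs, k = k, m = m,
                              percent = 100 * o_obs / k, per_gene = NULL,
                              comparison = NA_character_),
                         class = "overlap_result")
  }
  N <- if (is.character(universe)) length(unique(universe)) else
    as.integer(universe)
  if (N < max(k, m))
    stop("universe (N = ", N, ") smaller than a draw size")
  set.seed(as.integer(seed))
  if (mode == "direction_blind") {
    null_o <- vapply(seq_len(B), function(b) {
      sk <- unique(sample.int(N, k, replace = TRUE))
      sm <- unique(sample.int(N, m, replace = TRUE))
      length(intersect(sk, sm))
    }, integer(1))
  } else {
    if (!length(de_directions)) de_directions <- c("up", "down")
    null_o <- vapply(seq_len(B), function(b) {
      gk <- sample.int(N, k, replace = TRUE)
      dk <- sample(signature_directions, k, replace = TRUE)
      keep <- !duplicated(gk); gk <- gk[keep]; dk <- dk[keep]
      gm <- sample.int(N, m, replace = TRUE)
      dm <- sample(de_directions, m, replace = TRUE)
      keep <- !duplicated(gm); gm <- gm[keep]; dm <- dm[keep]
      i <- match(gk, gm)
      sum(!is.na(i) & dk == dm[i])
    }, integer(1))
  }
  overlap$N <- N
  overlap$B <- B
  overlap$p <- (1 + sum(null_o >= o_obs)) / (B + 1)
  overlap$null_mean <- mean(null_o)
  overlap$mode <- mode
  overlap
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result%s: o_obs = %d of k = %d signature genes (%.1f%%), m = %d DE genes\n",
              if (is.na(x$comparison %||% NA)) "" else
                paste0(" [", x$comparison, "]"),
              x$o_obs, x$k, x$percent, x$m))
  if (!is.null(x$p))
    cat(sprintf("  bootstrap (B = %d, N = %d, %s): P = %.4g (null mean overlap %.2f)\n",
                x$B, x$N, x$mode, x$p, x$null_mean))
  if (!is.null(x$per_gene)) {
    tab <- table(factor(x$per_gene$status,
                        c("concordant", "discordant", "not_de", "not_measured")))
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an overlap report
#'
#' JSON summary (counts, percentage, bootstrap P) plus the per-gene
#' concordance table as TSV.
#'
#' @param overlap an `overlap_result`.
#' @param json_path,tsv_path output paths (either may be NULL to skip).
#' @export
write_overlap_report <- function(overlap, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(overlap, "overlap_result"))
  if (!is.null(json_path))
    jsonlite::write_json(overlap_summary(overlap), json_path,
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path) && !is.null(overlap$per_gene))
    utils::write.table(overlap$per_gene, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(overlap)
}

overlap_summary <- function(x) {
  st <- if (is.null(x$per_gene)) NULL else
    table(factor(x$per_gene$status,
                 c("concordant", "discordant", "not_de", "not_measured")))
  list(comparison = x$comparison, o_obs = x$o_obs, k = x$k, m = x$m,
       N = x$N, percent_overlap = x$percent, B = x$B, p = x$p,
       null_mean = x$null_mean,
       percent_concordant = if (!is.null(st)) 100 * st[["concordant"]] / x$k,
       percent_discordant = if (!is.null(st)) 100 * st[["discordant"]] / x$k,
       percent_not_de = if (!is.null(st)) 100 * st[["not_de"]] / x$k)
}
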