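#' Signal2Noise ranking metric
#'
#' Per-gene `r_g = (mu_A - mu_B) / (sigma_A + sigma_B)` between two phenotype
#' groups, where each group standard deviation is floored at
#' `max(0.2 * |mu|, 0.2)` before summing (the floor keeps low-variance genes
#' from dominating the ranking). Group A is the treated/positive phenotype:
#' positive metric values mean higher expression in A.
#'
#' @param x an [expr_matrix] on the log2 or standardised scale.
#' @param design a [sample_design].
#' @param group_a,group_b character vectors of condition labels (>= 2 samples
#'   each).
#' @return named numeric vector of metric values, one per gene.
#' @export
signal_to_noise <- function(x, design, group_a, group_b) {
  assert_scale(x, c("log2", "standardised"))
  a_ids <- design_samples(design, group_a)
  b_ids <- design_samples(design, group_b)
  if (length(a_ids) < 2 || length(b_ids) < 2)
    stop("each group needs >= 2 samples for Signal2Noise")
  s2n_from_columns(unclass(x), a_ids, b_ids)
}

s2n_from_columns <- function(v, a_ids, b_ids) {
  A <- v[, a_ids, drop = FALSE]
  B <- v[, b_ids, drop = FALSE]
  muA <- rowMeans(A); muB <- rowMeans(B)
  sdA <- apply(A, 1, stats::sd); sdB <- apply(B, 1, stats::sd)
  sdA <- pmax(sdA, 0.2 * abs(muA), 0.2)
  sdB <- pmax(sdB, 0.2 * abs(muB), 0.2)
  stats::setNames((muA - muB) / (sdA + sdB), rownames(v))
}

#' Rank genes by a metric, descending
#'
#' Stable deterministic ordering: descending metric with gene-id
#' lexicographic order (C locale) as the final tie-break key.
#'
#' @param metric named numeric vector (e.g. from [signal_to_noise()]).
#' @return data.frame of class `ranked_list` with columns `gene`, `score`,
#'   most up-regulated first.
#' @export
rank_genes <- function(metric) {
  if (is.null(names(metric))) stop("metric must be a named vector")
  if (anyDuplicated(names(metric))) stop("duplicate genes in metric")
  ord <- order(-metric, xtfrm(names(metric)), method = "radix")
  df <- data.frame(gene = names(metric)[ord], score = unname(metric[ord]),
                   stringsAsFactors = FALSE)
  class(df) <- c("ranked_list", "data.frame")
  df
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list accumulating
#' `P_hit(i) = sum of |r_g|^p over set members with rank <= i / N_R` (with
#' `N_R` the total member weight) against
#' `P_miss(i) = #non-members with rank <= i / (N - N_h)`. The enrichment
#' score is the signed maximum deviation of `P_hit - P_miss`; on an exact
#' tie between the positive and negative extremes the positive one is taken.
#' The leading edge is the member genes at or before the extremum (at or
#' after it, for a negative ES).
#'
#' @param ranked a `ranked_list` from [rank_genes()] (or a named numeric
#'   vector already in rank order).
#' @param members character vector of gene-set members (restricted to the
#'   ranked universe; members outside it are ignored).
#' @param weight exponent p on |r_g| (default 1, the standard weighted
#'   scheme; 0 gives the unweighted Kolmogorov-Smirnov form).
#' @return list of class `es_result`: `es`, `profile` (the running deviation
#'   at every rank), `leading_edge`, `extremum` (rank index of the
#'   deviation extreme).
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  if (inherits(ranked, "ranked_list")) {
    genes <- ranked$gene; score <- ranked$score
  } else {
    genes <- names(ranked); score <- unname(ranked)
  }
  N <- length(genes)
  hits <- genes %in% members
  Nh <- sum(hits)
  if (Nh == 0) stop("gene set has no members in the ranked list")
  if (Nh == N) stop("gene set equals the ranked universe; P_miss undefined")
  w <- abs(score)^weight * hits
  NR <- sum(w)
  if (NR == 0) {
    warning("all member metric values are zero; ES = 0")
    return(structure(list(es = 0, profile = rep(0, N),
                          leading_edge = character(0), extremum = NA_integer_),
                     class = "es_result"))
  }
  D <- cumsum(w) / NR - cumsum(!hits) / (N - Nh)
  maxD <- max(D); minD <- min(D)
  es <- if (maxD >= -minD) maxD else minD
  extremum <- if (es >= 0) which.max(D) else which.min(D)
  leading <- if (es >= 0) genes[seq_len(extremum)][hits[seq_len(extremum)]]
  else genes[extremum:N][hits[extremum:N]]
  structure(list(es = es, profile = D, leading_edge = leading,
                 extremum = extremum), class = "es_result")
}

# O(N_h) enrichment score from sorted member positions and their weights;
# same extremum rule as enrichment_score(). Used inside permutation loops.
es_from_positions <- function(pos, w, N) {
  nh <- length(pos)
  NR <- sum(w)
  if (NR == 0) return(0)
  H <- cumsum(w) / NR
  miss <- (pos - seq_len(nh)) / (N - nh)
  maxD <- max(H - miss)
  minD <- min(c(0, H[-nh]) - miss)
  if (maxD >= -minD) maxD else minD
}

#' Null enrichment-score distributions by permutation
#'
#' Two null models. `"phenotype"` shuffles sample labels preserving group
#' sizes, recomputing the Signal2Noise metric, ranking and per-set ES for
#' each relabelling; distinct unordered splits are enumerated exhaustively
#' when `n_perm` is at least their number (a 3v3 design has only
#' `choose(6,3)/2 = 10`), and the mode errors when fewer than 10 distinct
#' splits exist. `"gene_set"` keeps the observed ranking and draws random
#' member sets of matched size from the ranked universe — the default for
#' small designs, where phenotype permutation is under-powered.
#'
#' @inheritParams signal_to_noise
#' @param sets named list of character vectors (already size-filtered).
#' @param mode `"gene_set"` or `"phenotype"`.
#' @param n_perm permutations per set (default 1000).
#' @param seed integer seed (required).
#' @param weight ES weight exponent.
#' @return numeric matrix (permutations x sets) of null ES values, with
#'   attributes `mode` and `exhaustive`.
#' @export
permutation_null <- function(x, design, sets, group_a, group_b,
                             mode = c("gene_set", "phenotype"),
                             n_perm = 1000L, seed, weight = 1) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  if (n_perm < 1) stop("n_perm must be >= 1")
  n_perm <- as.integer(n_perm)
  v <- unclass(x)
  a_ids <- design_samples(design, group_a)
  b_ids <- design_samples(design, group_b)
  set.seed(as.integer(seed))
  exhaustive <- FALSE
  if (mode == "phenotype") {
    pool <- c(a_ids, b_ids)
    nA <- length(a_ids); n <- length(pool)
    n_distinct <- choose(n, nA) / (if (nA * 2 == n) 2 else 1)
    if (n_distinct < 10)
      stop("only ", n_distinct, " distinct phenotype splits; ",
           "use mode = 'gene_set' instead")
    if (n_perm >= n_distinct) {
      splits <- utils::combn(n, nA, simplify = FALSE)
      if (nA * 2 == n)  # unordered: keep splits containing the first sample
        splits <- Filter(function(s) 1L %in% s, splits)
      exhaustive <- TRUE
    } else {
      splits <- lapply(seq_len(n_perm), function(b) sample.int(n, nA))
    }
    null_es <- t(vapply(splits, function(s) {
      metric <- s2n_from_columns(v, pool[s], pool[-s])
      ranked <- rank_genes(metric)
      absr <- abs(ranked$score)^weight
      vapply(sets, function(g) {
        pos <- sort(match(intersect(g, ranked$gene), ranked$gene))
        es_from_positions(pos, absr[pos], nrow(ranked))
      }, numeric(1))
    }, numeric(length(sets))))
  } else {
    metric <- s2n_from_columns(v, a_ids, b_ids)
    ranked <- rank_genes(metric)
    absr <- abs(ranked$score)^weight
    N <- nrow(ranked)
    null_es <- matrix(NA_real_, n_perm, length(sets))
    sizes <- vapply(sets, function(g) length(intersect(g, ranked$gene)),
                    integer(1))
    for (s in seq_along(sets)) {
      nh <- sizes[s]
      null_es[, s] <- vapply(seq_len(n_perm), function(b) {
        pos <- sort(sample.int(N, nh))
        es_from_positions(pos, absr[pos], N)
      }, numeric(1))
    }
  }
  if (is.null(dim(null_es))) null_es <- matrix(null_es, ncol = length(sets))
  colnames(null_es) <- names(sets)
  attr(null_es, "mode") <- mode
  attr(null_es, "exhaustive") <- exhaustive
  null_es
}

#' Nominal P, NES and FDR q from null ES distributions
#'
#' Nominal P is the side-matched tail frequency with add-one correction:
#' for a positive observed ES, `(1 + #\{null >= ES among null > 0\}) /
#' (1 + #\{null > 0\})`, mirrored for negative ES. NES divides ES by the
#' mean |null ES| of the same sign. FDR q follows the pooled-NES procedure:
#' every null ES is normalised by its own set's same-sign null mean, pooled
#' across sets, and q is the ratio of null to observed tail fractions at the
#' observed NES, capped at 1 and monotonised so a more extreme NES never has
#' a larger q. A set whose same-sign null is empty is flagged (`flagged =
#' TRUE`, P/NES/q = NA), not dropped.
#'
#' @param es_obs named numeric vector of observed ES per set.
#' @param null_es matrix (permutations x sets) from [permutation_null()].
#' @param p_cutoff,q_cutoff significance rule (defaults 0.05 and 0.25: the
#'   standard GSEA cut-off).
#' @return data.frame of class `gsea_result`: `set`, `es`, `nes`, `p`, `q`,
#'   `significant`, `flagged`.
#' @export
gsea_significance <- function(es_obs, null_es, p_cutoff = 0.05,
                              q_cutoff = 0.25) {
  stopifnot(length(es_obs) == ncol(null_es))
  ns <- length(es_obs)
  p <- nes <- rep(NA_real_, ns)
  mean_pos <- mean_neg <- rep(NA_real_, ns)
  flagged <- rep(FALSE, ns)
  for (s in seq_len(ns)) {
    null <- null_es[, s]
    pos <- null[null > 0]; neg <- null[null < 0]
    mean_pos[s] <- if (length(pos)) mean(pos) else NA_real_
    mean_neg[s] <- if (length(neg)) mean(abs(neg)) else NA_real_
    es <- es_obs[s]
    if (es == 0) { p[s] <- 1; nes[s] <- 0; next }
    if (es > 0) {
      if (!length(pos)) { flagged[s] <- TRUE; next }
      p[s] <- (1 + sum(pos >= es)) / (1 + length(pos))
      nes[s] <- es / mean_pos[s]
    } else {
      if (!length(neg)) { flagged[s] <- TRUE; next }
      p[s] <- (1 + sum(neg <= es)) / (1 + length(neg))
      nes[s] <- es / mean_neg[s]
    }
  }
  # pooled null NES: each permutation ES scaled by its set's same-sign mean
  null_nes <- unlist(lapply(seq_len(ns), function(s) {
    null <- null_es[, s]
    out <- rep(NA_real_, length(null))
    if (!is.na(mean_pos[s])) out[null > 0] <- null[null > 0] / mean_pos[s]
    if (!is.na(mean_neg[s])) out[null < 0] <- null[null < 0] / mean_neg[s]
    out[null == 0] <- 0
    out
  }))
  null_nes <- null_nes[!is.na(null_nes)]
  q <- rep(NA_real_, ns)
  ok <- !is.na(nes)
  for (s in which(ok)) {
    if (nes[s] == 0) { q[s] <- 1; next }
    if (nes[s] > 0) {
      num <- sum(null_nes >= nes[s]) / max(1, sum(null_nes >= 0))
      den <- sum(nes[ok] >= nes[s]) / max(1, sum(nes[ok] >= 0))
    } else {
      num <- sum(null_nes <= nes[s]) / max(1, sum(null_nes <= 0))
      den <- sum(nes[ok] <= nes[s]) / max(1, sum(nes[ok] <= 0))
    }
    q[s] <- min(1, num / den)
  }
  # monotonise within each sign: more extreme NES keeps the smaller q
  for (sgn in c(1, -1)) {
    idx <- which(ok & sign(nes) == sgn)
    if (length(idx) > 1) {
      ord <- idx[order(-abs(nes[idx]))]   # most extreme first
      q[ord] <- rev(cummin(rev(q[ord])))  # q non-decreasing as |NES| shrinks
    }
  }
  out <- data.frame(set = names(es_obs) %||% paste0("set", seq_len(ns)),
                    es = unname(es_obs), nes = nes, p = p, q = q,
                    significant = !is.na(p) & !is.na(q) &
                      p < p_cutoff & q < q_cutoff,
                    flagged = flagged,
                    stringsAsFactors = FALSE)
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Run the full gene set enrichment analysis
#'
#' Orchestrates the stages: restrict each set to the ranked universe and drop
#' sets below `min_size` (recording the reason), rank genes by Signal2Noise
#' between the two phenotype groups, compute the weighted running-sum ES and
#' leading edge per set, build the permutation null, and derive nominal P,
#' NES, FDR q and the significance call (nominal P < 0.05 and q < 0.25).
#' Deterministic given `seed`.
#'
#' @inheritParams permutation_null
#' @param min_size minimum post-restriction set size (default 15).
#' @param p_cutoff,q_cutoff significance rule.
#' @return `gsea_result` data.frame with extra columns `size` and
#'   `leading_edge` (list column); attributes `excluded` (data.frame of
#'   dropped sets with reasons), `ranked` (the ranked list), `mode`,
#'   `n_perm`.
#' @export
run_gsea <- function(x, design, sets, group_a, group_b,
                     mode = c("gene_set", "phenotype"),
                     n_perm = 1000L, seed, weight = 1, min_size = 15L,
                     p_cutoff = 0.05, q_cutoff = 0.25) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  if (!length(sets) || is.null(names(sets)))
    stop("'sets' must be a non-empty named list")
  universe <- rownames(x)
  restricted <- lapply(sets, intersect, y = universe)
  sizes <- lengths(restricted)
  drop <- sizes < min_size
  excluded <- data.frame(set = names(sets)[drop], size = sizes[drop],
                         reason = rep(sprintf("below minimum gene set size of %d",
                                              min_size), sum(drop)),
                         stringsAsFactors = FALSE, row.names = NULL)
  kept <- restricted[!drop]
  if (!length(kept))
    stop("no gene set reaches the minimum size of ", min_size)
  metric <- signal_to_noise(x, design, group_a, group_b)
  ranked <- rank_genes(metric)
  es_list <- lapply(kept, function(g) enrichment_score(ranked, g, weight))
  es_obs <- vapply(es_list, `[[`, numeric(1), "es")
  null_es <- permutation_null(x, design, kept, group_a, group_b,
                              mode = mode, n_perm = n_perm, seed = seed,
                              weight = weight)
  res <- gsea_significance(es_obs, null_es, p_cutoff, q_cutoff)
  res$size <- lengths(kept)
  res$leading_edge <- I(lapply(es_list, `[[`, "leading_edge"))
  attr(res, "excluded") <- excluded
  attr(res, "ranked") <- ranked
  attr(res, "mode") <- attr(null_es, "mode")
  attr(res, "n_perm") <- nrow(null_es)
  res
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: %d gene sets (%s mode, %s permutations)\n",
              nrow(x), attr(x, "mode") %||% "?",
              attr(x, "n_perm") %||% "?"))
  df <- as.data.frame(x)[, c("set", "size", "es", "nes", "p", "q",
                             "significant")]
  df$es <- round(df$es, 3); df$nes <- round(df$nes, 3)
  df$p <- signif(df$p, 3); df$q <- signif(df$q, 3)
  print(df, row.names = FALSE)
  ex <- attr(x, "excluded")
  if (!is.null(ex) && nrow(ex))
    cat(sprintf("  excluded: %s\n",
                paste(sprintf("%s (%s)", ex$set, ex$reason), collapse = "; ")))
  invisible(x)
}

#' Write a GSEA report as TSV
#'
#' One row per set: name, size, ES, NES, nominal P, FDR q, significance,
#' comma-joined leading edge.
#'
#' @param res a `gsea_result` from [run_gsea()].
#' @param path output path.
#' @export
write_gsea_tsv <- function(res, path) {
  stopifnot(inherits(res, "gsea_result"))
  df <- as.data.frame(res)
  df$leading_edge <- vapply(df$leading_edge, paste, character(1),
                            collapse = ",")
  utils::write.table(df[, c("set", "size", "es", "nes", "p", "q",
                            "significant", "leading_edge")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- gene set / phenotype file formats -------------------------------------

#' Read / write gene-set collections (GMT) and phenotype labels (CLS)
#'
#' GMT: one set per line, tab-separated `name<TAB>description<TAB>gene...`.
#' CLS (categorical, 3 lines): `n_samples n_classes 1`, `# label...`, then
#' the per-sample labels (names or 0-based class indices).
#' RNK: two tab-separated columns, gene and ranking metric, best first.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors with a `description`
#'   attribute; `read_cls`: character vector of per-sample class labels.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop(sprintf("malformed GMT %s at line %d: need name, description and >= 1 gene",
                 path, bad[1]))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets)))
    stop("duplicate set names in ", path)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_gmt
#' @export
read_cls <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("CLS file needs 3 lines: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  classes <- strsplit(trimws(sub("^#\\s*", "", lines[2])), "\\s+")[[1]]
  labels <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (length(labels) != hdr[1])
    stop(sprintf("CLS %s: header announces %d samples, found %d labels",
                 path, hdr[1], length(labels)))
  if (all(grepl("^[0-9]+$", labels)))
    labels <- classes[as.integer(labels) + 1L]
  labels
}

#' @rdname read_gmt
#' @param labels character vector of per-sample class labels.
#' @export
write_cls <- function(labels, path) {
  classes <- unique(labels)
  writeLines(c(paste(length(labels), length(classes), 1),
               paste("#", paste(classes, collapse = " ")),
               paste(labels, collapse = " ")), path)
  invisible(path)
}

#' @rdname read_gmt
#' @param ranked a `ranked_list`.
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_list"))
  utils::write.table(as.data.frame(ranked), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
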