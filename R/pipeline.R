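#' Pipeline run configuration
#'
#' Collects every threshold and resampling parameter of the analysis in one
#' object. All randomness fans out from the single root `seed` (simulation
#' uses `seed`, the overlap bootstrap `seed + 101`, the GSEA null
#' `seed + 202`), so one number reproduces a whole run; the seeds actually
#' used are persisted in the run report.
#'
#' @param fpkm_cutoff low-expression filter threshold (default 0.3).
#' @param alpha DE FDR threshold (default 0.05).
#' @param lfc_tiers |log2FC| tier cutoffs for the summary table (default
#'   `c(1, 2)`).
#' @param bootstraps overlap bootstrap count B (default 10000).
#' @param n_perm GSEA permutations (default 1000).
#' @param perm_mode GSEA null model, `"gene_set"` or `"phenotype"`.
#' @param min_set_size GSEA minimum gene set size (default 15).
#' @param q_cutoff GSEA FDR q threshold (default 0.25).
#' @param universe bootstrap universe: `"expressed"` (genes passing the
#'   filter; default) or `"annotated"` (all genes in the input matrix).
#' @param overlap_mode bootstrap null, `"direction_blind"` (default) or
#'   `"direction_aware"`.
#' @param seed root seed.
#' @param sim a [sim_config] to simulate inputs, or `NULL` when inputs are
#'   supplied as files/objects.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fpkm_cutoff = 0.3, alpha = 0.05,
                            lfc_tiers = c(1, 2), bootstraps = 10000L,
                            n_perm = 1000L,
                            perm_mode = c("gene_set", "phenotype"),
                            min_set_size = 15L, q_cutoff = 0.25,
                            universe = c("expressed", "annotated"),
                            overlap_mode = c("direction_blind",
                                             "direction_aware"),
                            seed = 1L, sim = NULL) {
  stopifnot(fpkm_cutoff >= 0, alpha > 0, all(lfc_tiers > 0),
            bootstraps >= 1, n_perm >= 1, min_set_size > 0, q_cutoff > 0)
  structure(list(fpkm_cutoff = fpkm_cutoff, alpha = alpha,
                 lfc_tiers = lfc_tiers, bootstraps = as.integer(bootstraps),
                 n_perm = as.integer(n_perm),
                 perm_mode = match.arg(perm_mode),
                 min_set_size = as.integer(min_set_size),
                 q_cutoff = q_cutoff, universe = match.arg(universe),
                 overlap_mode = match.arg(overlap_mode),
                 seed = as.integer(seed), sim = sim),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: (1) obtain inputs — simulate from
#' `config$sim`, or use the supplied matrix/design/signature/sets; (2)
#' preprocess: low-expression filter, then log2 transform, then per-gene
#' standardisation (exactly that order); (3) exploratory PCA and
#' Ward/Chebyshev clustering of samples; (4) moderated-t DE for the four
#' pairwise comparisons with the fold-change tier table and the
#' direction-consistent intersection of the three comparisons feeding the
#' signature stage; (5) directional signature overlap with the bootstrap
#' enrichment P for each of those three comparisons; (6) GSEA of the gene
#' sets for the TGF-beta-treated vs -untreated group contrast.
#'
#' @param config a [pipeline_config].
#' @param matrix,design,signature,sets inputs (ignored when `config$sim` is
#'   set): an [expr_matrix] on the fpkm scale, a [sample_design], a
#'   `directional_signature`, a named list of gene sets.
#' @param out_dir optional directory; when given, every stage table is
#'   written there (TSV) together with `run_report.json`.
#' @return list of class `run_report` with components `params`, `counts`,
#'   `pca`, `clustering`, `tier_table`, `common_de`, `overlap`, `gsea`, and
#'   the fitted objects in `objects`.
#' @export
run_pipeline <- function(config, matrix = NULL, design = NULL,
                         signature = NULL, sets = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- simulate_expression(config$sim)
    matrix <- sim$matrix; design <- sim$design; truth <- sim$truth
    if (is.null(signature)) signature <- simulate_signature(config$sim, truth)
    if (is.null(sets)) sets <- simulate_gene_sets(config$sim, truth)
  }
  if (is.null(matrix) || is.null(design))
    stop("run_pipeline needs a matrix and design (or config$sim)")
  check_design_matches(design, matrix)

  # preprocess: filter -> log2 -> standardise (order matters)
  annotated_universe <- rownames(matrix)
  filtered <- filter_low_expression(matrix, config$fpkm_cutoff)
  logmat <- log2_transform(filtered)
  zmat <- standardise(logmat)
  expressed_universe <- rownames(filtered)

  pca <- expression_pca(zmat, design)
  hc <- cluster_samples(zmat)
  tgfb_treated <- intersect(c("TGFb", "IL2_TGFb"), unique(design$condition))
  tgfb_untreated <- setdiff(unique(design$condition), tgfb_treated)
  labels <- stats::setNames(design$condition %in% tgfb_treated,
                            design$sample_id)
  purity <- cluster_purity(hc, ifelse(labels, "treated", "untreated"), k = 2)

  comparisons <- default_comparisons()
  feeds <- attr(comparisons, "feeds_signature_stage")
  de_list <- lapply(comparisons, function(cmp)
    differential_expression(logmat, design, cmp, alpha = config$alpha))
  tiers <- tier_table(de_list, lfc_tiers = config$lfc_tiers)
  common <- intersect_comparisons(de_list[feeds])

  # Fig-2B/S2-analog separation check: cluster the samples on the top common
  # DE genes (by mean |log2FC| across the comparisons feeding the signature
  # stage). On the full standardised matrix the Chebyshev max-statistic is
  # dominated by the most extreme of the ~10^4 non-responsive genes, so the
  # treatment structure is read off the DE-restricted profiles instead.
  purity_top_de <- NA_real_
  top_de_genes <- character(0)
  if (length(common$all) >= 2) {
    mean_abs_lfc <- rowMeans(sapply(de_list[feeds], function(de)
      abs(de$log2fc[match(common$all, de$gene)])))
    top_de_genes <-
      common$all[order(-mean_abs_lfc)][seq_len(min(30, length(common$all)))]
    ztop <- expr_matrix(unclass(zmat)[top_de_genes, , drop = FALSE],
                        "standardised")
    purity_top_de <- cluster_purity(
      cluster_samples(ztop),
      stats::setNames(ifelse(labels, "treated", "untreated"), names(labels)))
  }

  overlaps <- NULL
  if (!is.null(signature)) {
    universe <- if (config$universe == "expressed") expressed_universe
    else annotated_universe
    overlaps <- lapply(de_list[feeds], function(de)
      bootstrap_enrichment(directional_overlap(signature, de),
                           universe, B = config$bootstraps,
                           seed = config$seed + 101L,
                           mode = config$overlap_mode))
  }

  gsea <- NULL
  if (!is.null(sets)) {
    gsea <- run_gsea(logmat, design, sets,
                     group_a = tgfb_treated, group_b = tgfb_untreated,
                     mode = config$perm_mode, n_perm = config$n_perm,
                     seed = config$seed + 202L,
                     min_size = config$min_set_size,
                     q_cutoff = config$q_cutoff)
  }

  report <- structure(list(
    params = list(fpkm_cutoff = config$fpkm_cutoff, alpha = config$alpha,
                  lfc_tiers = config$lfc_tiers,
                  bootstraps = config$bootstraps, n_perm = config$n_perm,
                  perm_mode = config$perm_mode,
                  min_set_size = config$min_set_size,
                  q_cutoff = config$q_cutoff, universe = config$universe,
                  seed = config$seed,
                  stage_seeds = list(simulation = config$seed,
                                     bootstrap = config$seed + 101L,
                                     gsea = config$seed + 202L)),
    counts = list(genes_input = length(annotated_universe),
                  genes_expressed = length(expressed_universe),
                  samples = ncol(matrix)),
    pca = list(variance_fraction = pca$variance_fraction,
               top3_variance = sum(pca$variance_fraction[1:3])),
    clustering = list(linkage = "ward", distance = "maximum",
                      two_cut_purity_tgfb = purity,
                      two_cut_purity_top_de = purity_top_de,
                      top_de_genes = top_de_genes),
    tier_table = tiers,
    common_de = list(up = common$up, down = common$down,
                     n_up = length(common$up), n_down = length(common$down),
                     n_total = length(common$all)),
    comparisons_feeding_signature = names(comparisons)[feeds],
    overlap = if (!is.null(overlaps)) lapply(overlaps, overlap_summary),
    gsea = if (!is.null(gsea)) {
      df <- as.data.frame(gsea)
      df$leading_edge <- NULL
      df
    },
    objects = list(matrix = matrix, log2 = logmat, standardised = zmat,
                   design = design, truth = truth, de = de_list, pca = pca,
                   hclust = hc, overlaps = overlaps, gsea = gsea,
                   signature = signature, sets = sets)
  ), class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  cat(sprintf("  %d/%d genes expressed, %d samples\n",
              x$counts$genes_expressed, x$counts$genes_input,
              x$counts$samples))
  cat(sprintf("  PCA: first 3 PCs explain %.1f%% of variance\n",
              100 * x$pca$top3_variance))
  cat(sprintf("  2-cluster purity on TGF-beta treatment: %.2f (all genes), %.2f (top common DE genes)\n",
              x$clustering$two_cut_purity_tgfb,
              x$clustering$two_cut_purity_top_de))
  cat(sprintf("  common DE genes across %s: %d (%d up / %d down)\n",
              paste(x$comparisons_feeding_signature, collapse = ", "),
              x$common_de$n_total, x$common_de$n_up, x$common_de$n_down))
  if (!is.null(x$overlap))
    for (ov in x$overlap)
      cat(sprintf("  overlap [%s]: %d/%d (%.0f%%), P = %.3g\n",
                  ov$comparison, ov$o_obs, ov$k, ov$percent_overlap, ov$p))
  if (!is.null(x$gsea))
    cat(sprintf("  GSEA: %d/%d sets significant\n",
                sum(x$gsea$significant), nrow(x$gsea)))
  invisible(x)
}

#' Write the machine-readable run report
#'
#' Emits `run_report.json` plus per-stage TSVs (tier table, DE results,
#' overlap per-gene tables, GSEA table, PCA scores, cluster merge table)
#' into `out_dir`.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param out_dir output directory (created if absent).
#' @export
write_run_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- report[setdiff(names(report), "objects")]
  jsonlite::write_json(json, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.table(report$tier_table, file.path(out_dir, "tier_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  obj <- report$objects
  for (nm in names(obj$de))
    write_de_tsv(obj$de[[nm]], file.path(out_dir, paste0("de_", nm, ".tsv")))
  if (!is.null(obj$overlaps))
    for (nm in names(obj$overlaps))
      write_overlap_report(obj$overlaps[[nm]],
                           tsv_path = file.path(out_dir,
                                                paste0("overlap_", nm, ".tsv")))
  if (!is.null(obj$gsea))
    write_gsea_tsv(obj$gsea, file.path(out_dir, "gsea.tsv"))
  scores <- data.frame(sample_id = rownames(obj$pca$scores),
                       obj$pca$scores[, 1:min(4, ncol(obj$pca$scores))])
  utils::write.table(scores, file.path(out_dir, "pca_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  merges <- data.frame(obj$hclust$merge, height = obj$hclust$height)
  names(merges) <- c("left", "right", "height")
  utils::write.table(merges, file.path(out_dir, "cluster_merges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file.path(out_dir, "run_report.json"))
}
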