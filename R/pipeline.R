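# End-to-end driver: segmentation -> CNVR catalog -> CNV-driven gene
# discovery -> enrichment -> survival validation, with per-stage counts
# logged the way the discovery flowchart reports them.

#' Run the integrated CNV/expression pipeline on a cohort
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()], or any list
#'   with the same elements (`tumor_tracks`, `expression`, `genes`,
#'   `gene_sets`, `clinical`).
#' @param params [segmentation_params()].
#' @param recurrence_threshold Cohort fraction defining a recurrent CNVR.
#' @param mode `"paired"` or `"tumor_only"` grouping for the per-gene tests.
#' @param n_iter Null iterations per gene set for survival validation;
#'   `0` skips the survival stage.
#' @param seed Seed for the survival null draws.
#' @param quiet Suppress per-stage count messages.
#' @return List with `segments`, `freq_track`, `cnvrs`, `gene_map`,
#'   `status`, `results`, `drivers` (output of [concordance_filter()]),
#'   `cn_matrix`, `correlations`, `enrichment` and `survival` (named list of
#'   `survival_validation` objects, one per gene set).
#' @export
run_pipeline <- function(cohort, params = segmentation_params(),
                         recurrence_threshold = 0.30,
                         mode = c("paired", "tumor_only"),
                         n_iter = 1000, seed = 1, quiet = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (!quiet) message(sprintf(...))
  n <- length(cohort$tumor_tracks)
  say("segmenting %d tumor/normal pairs", n)
  segments <- segment_cohort(cohort$tumor_tracks, params)
  n_var <- sum(vapply(segments, function(s) sum(s$state != "neutral"),
                      numeric(1)))
  say("  %d variant segments called", n_var)

  freq_track <- build_frequency_track(segments, n)
  cnvrs <- call_cnvrs(freq_track, recurrence_threshold, segments)
  say("step 1: %d recurrent CNVRs at the %.0f%% threshold (>= %d samples)",
      nrow(cnvrs), 100 * recurrence_threshold,
      min_recurrent_samples(n, recurrence_threshold))

  gene_map <- map_genes(cnvrs, cohort$genes,
                        chromosomes = unique(freq_track$chrom))
  say("step 2: %d genes mapped into CNVRs", nrow(gene_map))

  status <- build_cnv_status(gene_map, segments)
  results <- test_all_genes(cohort$expression, status, gene_map, mode = mode)
  say("step 3: %d differentially expressed genes (Bonferroni 0.05/%d)",
      sum(results$significant), nrow(gene_map))

  drivers <- concordance_filter(results)
  say("step 4: %d concordant CNV-driven genes (%d discordant dropped)",
      drivers$n_concordant, drivers$n_discordant)

  cn_matrix <- gene_cn_matrix(cohort$genes, segments)
  correlations <- correlation_profile(
    cn_matrix, tumor_matrix(cohort$expression),
    driver_genes = drivers$drivers$gene, cnvr_genes = unique(gene_map$gene))

  enrichment <- NULL
  if (!is.null(cohort$gene_sets)) {
    enrichment <- enrich_gene_sets(unique(drivers$drivers$gene),
                                   cohort$gene_sets, cohort$genes$gene)
    say("enrichment: %d of %d sets significant at -log10 p > 2",
        sum(enrichment$significant), nrow(enrichment))
  }

  surv <- NULL
  if (n_iter > 0 && !is.null(cohort$clinical) &&
      !is.null(cohort$gene_sets)) {
    tum <- tumor_matrix(cohort$expression)
    surv <- lapply(names(cohort$gene_sets), function(nm) {
      validate_gene_set(tum, cohort$clinical, cohort$gene_sets[[nm]],
                        n_iter = n_iter, seed = seed, set_name = nm)
    })
    names(surv) <- names(cohort$gene_sets)
    for (nm in names(surv)) {
      say("survival: set '%s' observed log-rank p = %.3g, empirical p = %.4g",
          nm, surv[[nm]]$observed_p, surv[[nm]]$empirical_p)
    }
  }

  list(segments = segments, freq_track = freq_track, cnvrs = cnvrs,
       gene_map = gene_map, status = status, results = results,
       drivers = drivers, cn_matrix = cn_matrix,
       correlations = correlations, enrichment = enrichment,
       survival = surv)
}

#' Recovery of planted CNV-driven genes against ground truth
#'
#' Compares the pipeline's concordant gene set with the generator's truth
#' table: sensitivity over planted positively coupled genes and the false
#' flag rate over uncoupled CNVR genes.
#'
#' @param pipeline Result of [run_pipeline()].
#' @param truth The `truth` element of the cohort.
#' @return List with `sensitivity`, `false_flag_rate`, `n_true_positive`,
#'   `n_planted` and `n_false_flag`.
#' @export
recovery_stats <- function(pipeline, truth) {
  g <- truth$genes
  planted <- g$gene[g$coupled & g$coupling_sign > 0]
  uncoupled_cnvr <- g$gene[g$in_cnvr & !g$coupled]
  found <- unique(pipeline$drivers$drivers$gene)
  tp <- sum(planted %in% found)
  ff <- sum(uncoupled_cnvr %in% found)
  list(sensitivity = if (length(planted) > 0) tp / length(planted)
         else NA_real_,
       false_flag_rate = if (length(uncoupled_cnvr) > 0)
         ff / length(uncoupled_cnvr) else NA_real_,
       n_true_positive = tp, n_planted = length(planted), n_false_flag = ff)
}

#' Recovery of planted CNVRs against ground truth
#'
#' Matches every called CNVR to planted regions of the same direction and
#' reports, for each planted region at or above the recurrence threshold,
#' the best reciprocal overlap achieved.
#'
#' @param cnvrs Called CNVR table ([call_cnvrs()]).
#' @param truth The `truth` element of the cohort.
#' @param threshold Recurrence threshold the pipeline used.
#' @return `data.frame`, one row per planted CNVR: the spec columns plus
#'   `above_threshold` and `reciprocal_overlap` (0 when uncalled).
#' @export
cnvr_recovery <- function(cnvrs, truth, threshold = 0.30) {
  specs <- truth$cnvrs
  ro <- vapply(seq_len(nrow(specs)), function(i) {
    cand <- cnvrs[cnvrs$chrom == specs$chrom[i] &
                    cnvrs$direction == specs$direction[i], , drop = FALSE]
    if (nrow(cand) == 0) return(0)
    inter <- pmin(cand$end, specs$end[i]) - pmax(cand$start, specs$start[i])
    inter <- pmax(inter, 0)
    max(pmin(inter / (specs$end[i] - specs$start[i]),
             inter / (cand$end - cand$start)))
  }, numeric(1))
  out <- specs
  out$above_threshold <- specs$observed_freq >= threshold
  out$reciprocal_overlap <- ro
  out
}
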