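# CNV-expression integration: per-gene copy-number-status grouping, Welch
# t-tests with Bonferroni control over all CNVR genes, concordance filtering,
# Z-value normalization for heatmap-style output, and Pearson correlation
# profiling of copy number against tumor expression.

#' Assign per-patient copy-number status for genes in CNVRs
#'
#' For every (gene, CNVR) membership and every patient: `varied` iff the
#' gene's interval overlaps a variant segment of that patient whose state
#' matches the CNVR direction; `opposite` iff it overlaps only variant
#' segments of the opposite direction; `neutral` otherwise. `opposite`
#' patients are excluded from both t-test groups downstream.
#'
#' @param gene_map Gene-to-CNVR membership from [map_genes()].
#' @param segments Named list of per-sample segment frames (or one combined
#'   `data.frame` with a `sample` column).
#' @return Character matrix, rows = rows of `gene_map`, columns = samples.
#' @export
build_cnv_status <- function(gene_map, segments) {
  if (is.list(segments) && !is.data.frame(segments)) {
    segments <- do.call(rbind, segments)
  }
  patients <- sort(unique(segments$sample))
  nr <- nrow(gene_map)
  amp_cov <- matrix(FALSE, nr, length(patients),
                    dimnames = list(NULL, patients))
  del_cov <- amp_cov
  variant <- segments[segments$state != "neutral", , drop = FALSE]
  if (nrow(variant) > 0 && nr > 0) {
    hits <- GenomicRanges::findOverlaps(
      .gr(gene_map$chrom, gene_map$gene_start, gene_map$gene_end),
      .gr(variant$chrom, variant$start, variant$end))
    gi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    pj <- match(variant$sample[si], patients)
    amp <- variant$state[si] == "amplified"
    amp_cov[cbind(gi[amp], pj[amp])] <- TRUE
    del_cov[cbind(gi[!amp], pj[!amp])] <- TRUE
  }
  isamp <- gene_map$direction == "amplification"
  match_cov <- del_cov; match_cov[isamp, ] <- amp_cov[isamp, ]
  opp_cov <- amp_cov; opp_cov[isamp, ] <- del_cov[isamp, ]
  status <- matrix("neutral", nr, length(patients),
                   dimnames = list(NULL, patients))
  status[opp_cov] <- "opposite"
  status[match_cov] <- "varied"    # matching direction takes precedence
  status
}

# Welch two-sample test; falls back to the closed-form statistic with
# variances floored at 1e-12 when both groups are (near-)constant, so that
# identical groups give t = 0, p = 1 deterministically.
.welch <- function(x, y) {
  tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
  if (!is.null(tt)) {
    return(list(t = unname(tt$statistic), p = tt$p.value))
  }
  n1 <- length(x); n2 <- length(y)
  v1 <- max(stats::var(x), 1e-12); v2 <- max(stats::var(y), 1e-12)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Test every CNVR gene for CNV-associated differential expression
#'
#' Patients are grouped by the gene's copy-number status; the Welch
#' unequal-variance t-test (two-sided) compares, in `paired` mode, tumor
#' expression of copy-number-varied patients against normal expression of
#' copy-number-neutral patients; in `tumor_only` mode (for cohorts without
#' adjacent normals), tumor expression of varied versus neutral patients.
#' Significance is Bonferroni-controlled at `alpha / G` with `G` the number
#' of (gene, CNVR) rows tested -- untestable genes (either group below 2)
#' remain in `G`, keeping the threshold conservative.
#'
#' @param expression Expression matrix with `<patient>_tumor` /
#'   `<patient>_normal` columns ([read_expression()] layout).
#' @param status Status matrix from [build_cnv_status()].
#' @param gene_map Gene-to-CNVR membership from [map_genes()].
#' @param mode `"paired"` or `"tumor_only"`.
#' @param alpha Family-wise error rate for the Bonferroni rule.
#' @return `data.frame` with one row per (gene, CNVR): group sizes, Welch
#'   `t`, `p`, expression `direction` (`"up"`/`"down"`, sign of varied-mean
#'   minus neutral-mean, ties to `"up"`), `testable`, `significant` and
#'   `concordant` flags. Attribute `alpha_per_test` records `alpha / G`.
#' @export
test_all_genes <- function(expression, status, gene_map,
                           mode = c("paired", "tumor_only"), alpha = 0.05) {
  mode <- match.arg(mode)
  info <- sample_info(colnames(expression))
  tum_col <- stats::setNames(
    which(info$tissue == "tumor"), info$patient[info$tissue == "tumor"])
  nor_col <- stats::setNames(
    which(info$tissue == "normal"), info$patient[info$tissue == "normal"])
  patients <- colnames(status)
  G <- nrow(gene_map)
  alpha_per_test <- alpha / G
  rows <- lapply(seq_len(G), function(i) {
    g <- gene_map$gene[i]
    varied <- patients[status[i, ] == "varied"]
    neutral <- patients[status[i, ] == "neutral"]
    x <- expression[g, tum_col[varied]]
    y <- if (mode == "paired") expression[g, nor_col[neutral]]
      else expression[g, tum_col[neutral]]
    testable <- length(x) >= 2 && length(y) >= 2
    if (testable) {
      w <- .welch(x, y)
      dirn <- if (mean(x) - mean(y) >= 0) "up" else "down"
      data.frame(gene = g, cnvr_id = gene_map$cnvr_id[i],
                 direction = gene_map$direction[i],
                 n_varied = length(x), n_neutral = length(y),
                 t = w$t, p = w$p, expr_direction = dirn,
                 testable = TRUE, significant = w$p < alpha_per_test,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g, cnvr_id = gene_map$cnvr_id[i],
                 direction = gene_map$direction[i],
                 n_varied = length(x), n_neutral = length(y),
                 t = NA_real_, p = NA_real_, expr_direction = NA_character_,
                 testable = FALSE, significant = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  res$concordant <- res$significant &
    ((res$direction == "amplification" & res$expr_direction == "up") |
     (res$direction == "deletion" & res$expr_direction == "down"))
  res$concordant[is.na(res$concordant)] <- FALSE
  attr(res, "alpha_per_test") <- alpha_per_test
  attr(res, "G") <- G
  res
}

#' Keep significant genes whose expression change matches the CNV direction
#'
#' CNV-driven genes are those passing the Bonferroni threshold whose
#' expression direction is concordant with the CNVR direction (amplification
#' with up-regulation, deletion with down-regulation).
#'
#' @param results Result table from [test_all_genes()].
#' @return List with `drivers` (the concordant subset), `n_significant`,
#'   `n_concordant`, `n_discordant` and `concordant_fraction` (share of
#'   significant genes that are concordant).
#' @export
concordance_filter <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  drv <- sig[sig$concordant, , drop = FALSE]
  list(drivers = drv,
       n_significant = nrow(sig),
       n_concordant = nrow(drv),
       n_discordant = nrow(sig) - nrow(drv),
       concordant_fraction = if (nrow(sig) > 0) nrow(drv) / nrow(sig)
         else NA_real_)
}

#' Z-value normalization of expression against copy-number-neutral samples
#'
#' Two-step, per gene: subtract the median intensity over the *normal*
#' tissues of copy-number-neutral patients from all samples, then divide by
#' the standard deviation of intensity among copy-number-neutral samples.
#' By default the divisor SD is computed on the same normal-tissue values
#' (`sd_tissue = "normal"`); `"both"` pools the tumor and normal values of
#' neutral patients.
#'
#' @param expression Expression matrix (`<patient>_tumor` /
#'   `<patient>_normal` columns).
#' @param status Status matrix from [build_cnv_status()].
#' @param gene_map Gene-to-CNVR membership aligned with `status`.
#' @param sd_tissue Which neutral-sample values feed the SD.
#' @return List with `z` (matrix, rows aligned with `gene_map`, all sample
#'   columns) and `flagged` (genes with zero SD or fewer than two neutral
#'   patients; their rows are set to 0).
#' @export
z_value_normalize <- function(expression, status, gene_map,
                              sd_tissue = c("normal", "both")) {
  sd_tissue <- match.arg(sd_tissue)
  info <- sample_info(colnames(expression))
  tum_col <- stats::setNames(
    which(info$tissue == "tumor"), info$patient[info$tissue == "tumor"])
  nor_col <- stats::setNames(
    which(info$tissue == "normal"), info$patient[info$tissue == "normal"])
  patients <- colnames(status)
  z <- matrix(0, nrow(gene_map), ncol(expression),
              dimnames = list(NULL, colnames(expression)))
  flagged <- logical(nrow(gene_map))
  for (i in seq_len(nrow(gene_map))) {
    g <- gene_map$gene[i]
    neutral <- patients[status[i, ] == "neutral"]
    ref <- expression[g, nor_col[neutral]]
    sd_vals <- if (sd_tissue == "normal") ref
      else expression[g, c(nor_col[neutral], tum_col[neutral])]
    s <- stats::sd(sd_vals)
    if (length(neutral) < 2 || !is.finite(s) || s == 0) {
      flagged[i] <- TRUE
      next
    }
    z[i, ] <- (expression[g, ] - stats::median(ref)) / s
  }
  list(z = z, flagged = flagged)
}

#' Gene-level copy number from called segments
#'
#' The copy number of a gene in a sample is the mean of the overlapping
#' segment means weighted by the overlapped gene length.
#'
#' @param genes Gene annotation `data.frame` (`chrom`, `start`, `end`,
#'   `gene`).
#' @param segments Named list of per-sample segment frames or one combined
#'   `data.frame`.
#' @return Numeric matrix, genes x samples; `NA` where no segment overlaps.
#' @export
gene_cn_matrix <- function(genes, segments) {
  if (is.list(segments) && !is.data.frame(segments)) {
    segments <- do.call(rbind, segments)
  }
  patients <- sort(unique(segments$sample))
  hits <- GenomicRanges::findOverlaps(
    .gr(genes$chrom, genes$start, genes$end),
    .gr(segments$chrom, segments$start, segments$end))
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  w <- pmin(genes$end[gi], segments$end[si]) -
    pmax(genes$start[gi], segments$start[si])
  pj <- match(segments$sample[si], patients)
  num <- matrix(0, nrow(genes), length(patients))
  den <- matrix(0, nrow(genes), length(patients))
  idx <- cbind(gi, pj)
  for (k in seq_along(gi)) {
    num[gi[k], pj[k]] <- num[gi[k], pj[k]] + w[k] * segments$mean_cn[si[k]]
    den[gi[k], pj[k]] <- den[gi[k], pj[k]] + w[k]
  }
  cn <- num / den
  cn[den == 0] <- NA_real_
  dimnames(cn) <- list(genes$gene, patients)
  cn
}

#' Pearson correlation between gene-level copy number and tumor expression
#'
#' @param cn Copy-number vector over tumor samples.
#' @param expr Expression vector over the same samples.
#' @return Pearson product-moment correlation; `NA` if fewer than 3 complete
#'   pairs or either vector has zero variance.
#' @export
correlate_cn_expression <- function(cn, expr) {
  ok <- is.finite(cn) & is.finite(expr)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(cn[ok]) == 0 || stats::sd(expr[ok]) == 0) return(NA_real_)
  stats::cor(cn[ok], expr[ok])
}

#' Per-gene copy-number/expression correlation profile
#'
#' Computes the per-gene Pearson correlation between tumor copy number and
#' tumor expression and labels each gene as CNV-driven, CNVR-resident, or
#' genome background, giving the three comparison distributions used to show
#' that recovered CNV-driven genes carry elevated correlations.
#'
#' @param cn_matrix Gene-level copy-number matrix over tumor samples
#'   ([gene_cn_matrix()], columns = patients).
#' @param tumor_expr Tumor expression matrix with patient columns
#'   ([tumor_matrix()]).
#' @param driver_genes Character vector of CNV-driven gene ids.
#' @param cnvr_genes Character vector of all CNVR gene ids.
#' @return `data.frame` with columns `gene`, `r`, `driver`, `in_cnvr`.
#' @export
correlation_profile <- function(cn_matrix, tumor_expr, driver_genes,
                                cnvr_genes) {
  genes <- intersect(rownames(cn_matrix), rownames(tumor_expr))
  patients <- intersect(colnames(cn_matrix), colnames(tumor_expr))
  r <- vapply(genes, function(g) {
    correlate_cn_expression(cn_matrix[g, patients], tumor_expr[g, patients])
  }, numeric(1))
  data.frame(gene = genes, r = unname(r),
             driver = genes %in% driver_genes,
             in_cnvr = genes %in% cnvr_genes,
             stringsAsFactors = FALSE)
}

#' One-sided Fisher's exact test for gene-list overlap
#'
#' Enrichment p-value for the overlap of two gene lists against a common
#' universe, from the 2x2 table (in both / A only / B only / neither).
#'
#' @param list_a,list_b Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of all candidate genes.
#' @return One-sided (enrichment) Fisher's exact p-value.
#' @export
gene_list_overlap <- function(list_a, list_b, universe) {
  if (length(universe) == 0) stop("empty universe")
  list_a <- unique(list_a); list_b <- unique(list_b)
  if (!all(list_a %in% universe) || !all(list_b %in% universe)) {
    stop("gene lists must be subsets of the universe")
  }
  both <- length(intersect(list_a, list_b))
  a_only <- length(list_a) - both
  b_only <- length(list_b) - both
  neither <- length(universe) - both - a_only - b_only
  tab <- matrix(c(both, a_only, b_only, neither), nrow = 2)
  stats::fisher.test(tab, alternative = "greater")$p.value
}
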