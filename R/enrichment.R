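# Gene-set enrichment of the CNV-driven gene list by one-sided Fisher's
# exact tests against user-supplied GMT collections.

#' Fisher's-exact enrichment of a gene list against gene sets
#'
#' For each set, a one-sided Fisher's exact test on the 2x2 table (in set and
#' driver / in set only / driver only / neither) against the platform
#' universe. No multiplicity correction is applied across sets; significance
#' is reported on the raw \eqn{-\log_{10} p > 2.0} rule, matching the
#' convention of reporting raw log p-values for canonical-pathway tables.
#'
#' @param driver_genes Character vector of CNV-driven gene ids (subset of
#'   `universe`).
#' @param gene_sets Named list of character vectors ([read_gmt()] layout).
#'   Sets are intersected with the universe before testing; sets with empty
#'   intersection are skipped with a warning.
#' @param universe Character vector of all genes on the platform.
#' @param neg_log10_cutoff Significance cutoff on \eqn{-\log_{10} p}.
#' @return `data.frame` sorted by p with columns `set`, `set_size` (after
#'   intersection), `overlap` (associated gene number), `p`, `neg_log10_p`,
#'   `significant`.
#' @export
enrich_gene_sets <- function(driver_genes, gene_sets, universe,
                             neg_log10_cutoff = 2.0) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  driver_genes <- unique(driver_genes)
  if (!all(driver_genes %in% universe)) {
    stop("driver genes must be a subset of the universe")
  }
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    if (length(members) == 0) {
      warning(sprintf("gene set '%s' has no genes in the universe; skipped",
                      nm))
      return(NULL)
    }
    k <- length(intersect(members, driver_genes))
    tab <- matrix(c(k,
                    length(members) - k,
                    length(driver_genes) - k,
                    length(universe) - length(members) -
                      length(driver_genes) + k), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(set = nm, set_size = length(members), overlap = k, p = p,
               neg_log10_p = -log10(p),
               significant = -log10(p) > neg_log10_cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      neg_log10_p = numeric(0), significant = logical(0)))
  }
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}
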