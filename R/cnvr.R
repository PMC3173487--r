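# Cohort-level aggregation: frequency tracks, recurrent CNVR calling and
# gene-to-CNVR mapping.

#' Smallest carrier count meeting a recurrence threshold
#'
#' Returns \eqn{\lceil threshold \cdot n \rceil}, the smallest integer k with
#' k/n at or above the threshold (13 for a 30% threshold in a 42-sample
#' cohort).
#'
#' @param n Cohort size.
#' @param threshold Recurrence threshold as a fraction in (0, 1].
#' @return Integer carrier count.
#' @export
min_recurrent_samples <- function(n, threshold) {
  stopifnot(n >= 1, threshold > 0, threshold <= 1)
  # guard against binary representation pushing e.g. 0.1 * 10 above 1
  as.integer(ceiling(threshold * n - 1e-9))
}

#' Build per-direction carrier-frequency tracks from cohort segments
#'
#' At every genomic bin the amplification (deletion) frequency is the number
#' of samples whose overlapping segment is amplified (deleted), divided by the
#' cohort size. Bins are delimited by the union of all segment boundaries;
#' since every boundary sits on a marker position this is marker-resolution
#' frequency with no information loss.
#'
#' @param segments Named list of per-sample segment frames
#'   (from [segment_cohort()]) or a single combined `data.frame`.
#' @param n Cohort size (number of samples, must be positive).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `amp_count`,
#'   `del_count`, `amp_freq`, `del_freq`; attribute `n` carries the cohort
#'   size.
#' @export
build_frequency_track <- function(segments, n) {
  if (n == 0) stop("cohort size n must be positive")
  if (is.list(segments) && !is.data.frame(segments)) {
    segments <- do.call(rbind, segments)
  }
  variant <- segments[segments$state != "neutral", , drop = FALSE]
  chroms <- unique(segments$chrom)
  out <- lapply(chroms, function(ch) {
    d <- segments[segments$chrom == ch, ]
    bks <- sort(unique(c(d$start, d$end)))
    nb <- length(bks) - 1L
    bins <- data.frame(chrom = ch, start = bks[-length(bks)], end = bks[-1])
    counts <- function(state) {
      v <- variant[variant$chrom == ch & variant$state == state, ]
      acc <- numeric(nb + 1L)
      if (nrow(v) > 0) {
        i1 <- findInterval(v$start, bks)
        i2 <- findInterval(v$end, bks)   # end is exclusive: bins i1..(i2-1)
        for (j in seq_len(nrow(v))) {
          acc[i1[j]] <- acc[i1[j]] + 1
          acc[i2[j]] <- acc[i2[j]] - 1
        }
      }
      cumsum(acc)[seq_len(nb)]
    }
    bins$amp_count <- counts("amplified")
    bins$del_count <- counts("deleted")
    bins
  })
  track <- do.call(rbind, out)
  track$amp_freq <- track$amp_count / n
  track$del_freq <- track$del_count / n
  rownames(track) <- NULL
  attr(track, "n") <- n
  track
}

#' Call recurrent copy-number variable regions
#'
#' Per direction, maximal runs of adjacent bins whose carrier count reaches
#' [min_recurrent_samples()] are merged into one CNVR. Overlapping
#' amplification and deletion CNVRs may coexist. The carrier set of a CNVR is
#' the set of samples with a variant segment of the matching direction
#' overlapping the region.
#'
#' @param track Frequency track from [build_frequency_track()].
#' @param threshold Recurrence threshold (fraction of the cohort; default the
#'   published 30% rule).
#' @param segments The per-sample segments used to build `track`, needed to
#'   recover carrier identities.
#' @return `data.frame` with columns `cnvr_id`, `chrom`, `start`, `end`,
#'   `direction`, `n_carriers`, `frequency` and a list-column `carriers`.
#' @export
call_cnvrs <- function(track, threshold = 0.30, segments = NULL) {
  n <- attr(track, "n")
  stopifnot(!is.null(n))
  k <- min_recurrent_samples(n, threshold)
  if (!is.null(segments) && is.list(segments) && !is.data.frame(segments)) {
    segments <- do.call(rbind, segments)
  }
  res <- list()
  for (direction in c("amplification", "deletion")) {
    cnt <- if (direction == "amplification") track$amp_count else
      track$del_count
    state <- if (direction == "amplification") "amplified" else "deleted"
    for (ch in unique(track$chrom)) {
      sel <- track$chrom == ch
      bins <- track[sel, ]
      hit <- cnt[sel] >= k
      if (!any(hit)) next
      r <- rle(hit)
      ends_idx <- cumsum(r$lengths)
      starts_idx <- ends_idx - r$lengths + 1L
      for (j in which(r$values)) {
        s <- bins$start[starts_idx[j]]
        e <- bins$end[ends_idx[j]]
        carriers <- character(0)
        if (!is.null(segments)) {
          v <- segments[segments$chrom == ch & segments$state == state &
                          segments$start < e & segments$end > s, ]
          carriers <- sort(unique(v$sample))
        }
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, start = s, end = e, direction = direction,
          n_carriers = length(carriers),
          frequency = length(carriers) / n, stringsAsFactors = FALSE)
        res[[length(res)]]$carriers <- I(list(carriers))
      }
    }
  }
  if (length(res) == 0) {
    out <- data.frame(cnvr_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      direction = character(0), n_carriers = integer(0),
                      frequency = numeric(0))
    out$carriers <- I(list())
    return(out)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$direction), ]
  out <- cbind(cnvr_id = sprintf("%s:%d-%d:%s", out$chrom, out$start, out$end,
                                 ifelse(out$direction == "amplification",
                                        "amp", "del")),
               out)
  out$cnvr_id <- as.character(out$cnvr_id)
  rownames(out) <- NULL
  out
}

#' Map genes into CNVRs
#'
#' A gene belongs to a CNVR iff their intervals intersect by at least one
#' base (half-open coordinates). A gene overlapping CNVRs of both directions
#' is assigned to both and analyzed per direction downstream.
#'
#' @param cnvrs CNVR table from [call_cnvrs()].
#' @param genes Gene annotation `data.frame` (columns `chrom`, `start`,
#'   `end`, `gene`), e.g. from [read_bed()].
#' @param chromosomes Optional character vector of known chromosomes; genes on
#'   other chromosomes are skipped with a warning.
#' @return `data.frame` with one row per (gene, CNVR) membership: columns
#'   `gene`, `cnvr_id`, `direction`, `chrom`, `gene_start`, `gene_end`.
#' @export
map_genes <- function(cnvrs, genes, chromosomes = NULL) {
  stopifnot(all(genes$start < genes$end))
  if (!is.null(chromosomes)) {
    unknown <- !(genes$chrom %in% chromosomes)
    if (any(unknown)) {
      warning(sprintf("skipping %d gene(s) on unknown chromosome(s): %s",
                      sum(unknown),
                      paste(unique(genes$chrom[unknown]), collapse = ", ")))
      genes <- genes[!unknown, , drop = FALSE]
    }
  }
  if (nrow(cnvrs) == 0 || nrow(genes) == 0) {
    return(data.frame(gene = character(0), cnvr_id = character(0),
                      direction = character(0), chrom = character(0),
                      gene_start = numeric(0), gene_end = numeric(0)))
  }
  hits <- GenomicRanges::findOverlaps(
    .gr(genes$chrom, genes$start, genes$end),
    .gr(cnvrs$chrom, cnvrs$start, cnvrs$end))
  gi <- S4Vectors::queryHits(hits)
  ci <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    gene = genes$gene[gi], cnvr_id = cnvrs$cnvr_id[ci],
    direction = cnvrs$direction[ci], chrom = genes$chrom[gi],
    gene_start = genes$start[gi], gene_end = genes$end[gi],
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$gene_start, out$direction), ]
  rownames(out) <- NULL
  out
}
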