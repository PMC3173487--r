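# Copy-number segmentation by recursive binary splitting.
#
# Each tumor/normal pair yields a marker track of absolute copy-number
# estimates (diploid = 2). A breakpoint is placed where the unequal-variance
# t statistic between the two flanks is maximal, and is accepted only if
# (i) both flanks carry at least `min_markers` markers, (ii) the two-sided
# Welch p-value is at or below `split_p`, and (iii) the signal-to-noise ratio
# |mean_left - mean_right| / pooled within-flank SD is at least `snr`.
# Splitting recurses until no admissible breakpoint remains.

#' Segmentation parameters
#'
#' Defaults are the published segment criteria: at least 100 consecutive
#' markers, breakpoint p-value \eqn{\le} 0.001, SNR \eqn{\ge} 0.3, and a
#' minimum copy-number change of 0.3 from the diploid baseline for a segment
#' to be called variant (amplified above 2.3, deleted below 1.7).
#'
#' @param min_markers Minimum consecutive markers per segment.
#' @param split_p Maximum two-sided Welch p-value for an admissible breakpoint.
#' @param snr Minimum signal-to-noise ratio at a breakpoint.
#' @param min_cn_change Minimum |mean copy number - baseline| for a variant
#'   call.
#' @param baseline_cn Diploid baseline copy number.
#' @return A classed list of parameters.
#' @export
segmentation_params <- function(min_markers = 100, split_p = 0.001,
                                snr = 0.3, min_cn_change = 0.3,
                                baseline_cn = 2) {
  stopifnot(min_markers >= 2, split_p > 0, snr > 0, min_cn_change > 0,
            baseline_cn > 0)
  structure(list(min_markers = as.integer(min_markers), split_p = split_p,
                 snr = snr, min_cn_change = min_cn_change,
                 baseline_cn = baseline_cn),
            class = "segmentation_params")
}

#' Classify a segment mean as amplified, deleted or neutral
#'
#' Amplified iff `mean_cn > baseline_cn + min_cn_change` (above 2.3 at
#' defaults), deleted iff `mean_cn < baseline_cn - min_cn_change` (below 1.7),
#' neutral otherwise.
#'
#' @param mean_cn Mean copy number of a segment (vectorized).
#' @param params [segmentation_params()].
#' @return Character vector in `{"amplified", "deleted", "neutral"}`.
#' @export
call_state <- function(mean_cn, params = segmentation_params()) {
  stopifnot(all(mean_cn > 0))
  ifelse(mean_cn > params$baseline_cn + params$min_cn_change, "amplified",
         ifelse(mean_cn < params$baseline_cn - params$min_cn_change,
                "deleted", "neutral"))
}

# Welch statistics for every admissible split of cn[lo..hi].
# Returns NULL when no candidate exists, else the best (max |t|, leftmost tie)
# candidate with its p-value and SNR. Variances are floored at 1e-12 so
# noiseless fixtures do not divide by zero.
.best_split <- function(cn, lo, hi, min_markers) {
  n <- hi - lo + 1L
  if (n < 2L * min_markers) return(NULL)
  x <- cn[lo:hi]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  k <- min_markers:(n - min_markers)   # left flank sizes
  n1 <- k
  n2 <- n - k
  s1 <- cs[k]
  s2 <- cs[n] - s1
  q1 <- cs2[k]
  q2 <- cs2[n] - q1
  m1 <- s1 / n1
  m2 <- s2 / n2
  v1 <- pmax((q1 - n1 * m1^2) / (n1 - 1), 1e-12)
  v2 <- pmax((q2 - n2 * m2^2) / (n2 - 1), 1e-12)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  best <- which.max(abs(tstat))
  df <- se2[best]^2 / ((v1[best] / n1[best])^2 / (n1[best] - 1) +
                       (v2[best] / n2[best])^2 / (n2[best] - 1))
  p <- 2 * stats::pt(-abs(tstat[best]), df)
  pooled_sd <- sqrt(((n1[best] - 1) * v1[best] + (n2[best] - 1) * v2[best]) /
                    (n1[best] + n2[best] - 2))
  list(split_after = lo + k[best] - 1L,      # last index of the left flank
       t = tstat[best], p = p,
       snr = abs(m1[best] - m2[best]) / max(pooled_sd, 1e-12))
}

# Recursive splitter over marker indices [lo, hi]; returns a data.frame of
# leaves with the boundary statistics of the split that created each leaf.
.split_rec <- function(cn, lo, hi, params, boundary_p = NA_real_,
                       boundary_snr = NA_real_) {
  cand <- .best_split(cn, lo, hi, params$min_markers)
  if (!is.null(cand) && cand$p <= params$split_p && cand$snr >= params$snr) {
    left <- .split_rec(cn, lo, cand$split_after, params, cand$p, cand$snr)
    right <- .split_rec(cn, cand$split_after + 1L, hi, params, cand$p,
                        cand$snr)
    return(rbind(left, right))
  }
  data.frame(lo = lo, hi = hi, boundary_p = boundary_p,
             boundary_snr = boundary_snr)
}

#' Segment one sample's marker track
#'
#' @param track `data.frame` with columns `chrom`, `pos` (strictly increasing
#'   within each chromosome) and `cn` (absolute copy-number estimate per
#'   marker, finite and positive), and optionally `sample`.
#' @param params [segmentation_params()].
#' @param sample Sample identifier recorded in the output (defaults to the
#'   track's `sample` column, else `"sample"`).
#' @return `data.frame` of segments with columns `sample`, `chrom`, `start`,
#'   `end` (0-based half-open; segments tile each chromosome's marker span),
#'   `n_markers`, `mean_cn`, `state`, `boundary_p`, `snr`. Chromosomes with
#'   fewer than `2 * min_markers` markers are emitted as one segment.
#' @export
segment_track <- function(track, params = segmentation_params(),
                          sample = NULL) {
  stopifnot(all(c("chrom", "pos", "cn") %in% names(track)))
  if (is.null(sample)) {
    sample <- if ("sample" %in% names(track)) track$sample[1] else "sample"
  }
  if (any(!is.finite(track$cn)) || any(track$cn <= 0)) {
    stop("marker copy numbers must be finite and positive")
  }
  out <- lapply(unique(track$chrom), function(ch) {
    d <- track[track$chrom == ch, ]
    if (is.unsorted(d$pos, strictly = TRUE)) {
      stop(sprintf("marker positions not strictly increasing on %s", ch))
    }
    n <- nrow(d)
    leaves <- .split_rec(d$cn, 1L, n, params)
    # segment intervals tile [first marker, last marker + 1)
    starts <- d$pos[leaves$lo]
    ends <- ifelse(leaves$hi < n, d$pos[leaves$hi + 1L], d$pos[n] + 1)
    mean_cn <- vapply(seq_len(nrow(leaves)),
                      function(i) mean(d$cn[leaves$lo[i]:leaves$hi[i]]),
                      numeric(1))
    data.frame(sample = sample, chrom = ch, start = starts, end = ends,
               n_markers = leaves$hi - leaves$lo + 1L, mean_cn = mean_cn,
               state = call_state(mean_cn, params),
               boundary_p = leaves$boundary_p, snr = leaves$boundary_snr,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Segment every sample of a cohort
#'
#' @param tracks Named list of per-sample marker tracks (see
#'   [segment_track()]).
#' @param params [segmentation_params()].
#' @return Named list of per-sample segment `data.frame`s.
#' @export
segment_cohort <- function(tracks, params = segmentation_params()) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  out <- lapply(names(tracks), function(s) {
    segment_track(tracks[[s]], params, sample = s)
  })
  names(out) <- names(tracks)
  out
}
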