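# Independent oracles and small fixtures shared across tests.

# exhaustive single-breakpoint search: for every admissible split of cn,
# compute the Welch t via stats::t.test and return the |t|-maximizing
# candidate with its p-value and SNR (pooled within-flank SD).
oracle_best_split <- function(cn, min_markers) {
  n <- length(cn)
  ks <- seq(min_markers, n - min_markers)
  if (length(ks) == 0 || n < 2 * min_markers) return(NULL)
  best <- NULL
  for (k in ks) {
    x <- cn[1:k]; y <- cn[(k + 1):n]
    v1 <- max(var(x), 1e-12); v2 <- max(var(y), 1e-12)
    tt <- (mean(x) - mean(y)) / sqrt(v1 / k + v2 / (n - k))
    if (is.null(best) || abs(tt) > abs(best$t)) {
      df <- (v1 / k + v2 / (n - k))^2 /
        ((v1 / k)^2 / (k - 1) + (v2 / (n - k))^2 / (n - k - 1))
      pooled <- sqrt(((k - 1) * v1 + (n - k - 1) * v2) / (n - 2))
      best <- list(split_after = k, t = tt,
                   p = 2 * pt(-abs(tt), df),
                   snr = abs(mean(x) - mean(y)) / max(pooled, 1e-12))
    }
  }
  best
}

# hypergeometric enrichment tail by brute-force enumeration:
# P(overlap >= k) for |A| drawn from a universe containing |B| marked genes
oracle_hyper_tail <- function(k, size_a, size_b, universe) {
  kk <- k:min(size_a, size_b)
  sum(choose(size_b, kk) * choose(universe - size_b, size_a - kk)) /
    choose(universe, size_a)
}

# unweighted log-rank chi-square by direct observed-minus-expected tally
oracle_logrank_chisq <- function(time, event, in_group1) {
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n1 <- sum(at & in_group1); n0 <- sum(at & !in_group1)
    N <- n1 + n0
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & in_group1)
    O <- O + d1
    E <- E + d * n1 / N
    if (N > 1) V <- V + d * (n1 / N) * (n0 / N) * (N - d) / (N - 1)
  }
  (O - E)^2 / V
}

# hand-evaluated Welch statistic with Welch-Satterthwaite df
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# compact two-chromosome cohort for fast module tests
small_config <- function(seed = 1, ...) {
  cohort_config(
    n_patients = 20,
    chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
    marker_spacing = 20e3,
    cnvr_specs = data.frame(
      chrom = c("chr1", "chr2"),
      start = c(2e6, 4e6), end = c(6e6, 8e6),
      direction = c("amplification", "deletion"),
      carrier_freq = c(0.5, 0.5),
      cn_shift = c(2.5, -1.9),
      stringsAsFactors = FALSE),
    gene_spacing = 500e3,
    driven_fraction = 0.3,
    active_set_size = 3,
    n_decoy_sets = 2,
    seed = seed, ...)
}

# a flat marker track with optional mean steps
make_track <- function(levels, lengths, sd = 0, chrom = "chr1",
                       spacing = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- rep(levels, lengths)
  n <- length(mu)
  data.frame(chrom = chrom, pos = seq(0, by = spacing, length.out = n),
             cn = pmax(mu + rnorm(n, 0, sd), 0.01))
}
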