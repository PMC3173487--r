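# Synthetic paired tumor/normal cohort generator.
#
# Emulates the statistical structure of a paired copy-number + expression
# study: 42 tumor/normal pairs assayed on dense genomic marker tracks,
# recurrent broad amplifications and focal deep deletions at 30-60% carrier
# frequency, a ~12% fraction of CNVR genes whose expression is linearly
# coupled to copy number (a ~22% minority with negative coupling), and
# survival times drawn from an exponential proportional-hazards model on the
# standardized expression of one designated "active" gene set.

# evaluate expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default planted CNVR specification
#'
#' Three broad high-level amplifications (+2.5 copies) and three focal deep
#' deletions (-1.9 copies) at carrier frequencies between 35% and 60%,
#' mirroring the recurrent arm-level gains (1p/5p/7p) and losses (3p/8p/17p)
#' of lung adenocarcinoma, with the most frequent events at ~60%.
#'
#' @return `data.frame` with columns `chrom`, `start`, `end`, `direction`,
#'   `carrier_freq`, `cn_shift`.
#' @export
default_cnvr_specs <- function() {
  data.frame(
    chrom = c("chr1", "chr5", "chr7", "chr3", "chr8", "chr17"),
    start = c(10e6, 15e6, 5e6, 20e6, 8e6, 25e6),
    end   = c(20e6, 25e6, 15e6, 24e6, 12e6, 29e6),
    direction = c("amplification", "amplification", "amplification",
                  "deletion", "deletion", "deletion"),
    carrier_freq = c(0.45, 0.40, 0.60, 0.45, 0.40, 0.60),
    cn_shift = c(2.5, 2.5, 2.5, -1.9, -1.9, -1.9),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic cohort
#'
#' @param n_patients Number of tumor/normal pairs (default 42).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bases.
#' @param marker_spacing Distance between adjacent genomic markers (bases).
#' @param cnvr_specs `data.frame` of planted CNVRs (see
#'   [default_cnvr_specs()]).
#' @param marker_noise_sd SD of per-marker copy-number noise (copy-number
#'   units).
#' @param gene_spacing,gene_length Gene start spacing and gene length (bases);
#'   genes are laid uniformly along every chromosome.
#' @param driven_fraction Fraction of CNVR genes whose expression is coupled
#'   to copy number (default 0.12).
#' @param discordant_fraction Fraction of coupled genes with negative coupling
#'   (default 0.22).
#' @param coupling_effect Coupling strength gamma in expression units per
#'   copy; default 0.8 of the expression noise SD.
#' @param expression_noise_sd SD of per-gene expression noise.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline
#'   log-intensity.
#' @param tumor_effect_sd SD of a copy-number-independent tumor baseline shift
#'   per gene (default 0: expression differences are purely CNV-driven).
#' @param active_set_size Size of the designated survival-active gene set.
#' @param log_hazard Per-gene log-hazard coefficient beta on standardized
#'   expression for the active set.
#' @param baseline_hazard Exponential baseline hazard (events per month).
#' @param censor_min,censor_max Uniform censoring window (months).
#' @param n_decoy_sets Number of random decoy gene sets emitted alongside the
#'   active set.
#' @param carrier_mode `"deterministic"` assigns exactly
#'   \eqn{\lceil f \cdot n \rceil} carriers per CNVR (seed-shuffled), so
#'   frequency thresholds are exact; `"bernoulli"` draws carriers
#'   independently.
#' @param seed Integer seed controlling all randomness.
#' @return A classed list of settings.
#' @export
cohort_config <- function(n_patients = 42,
                          chrom_lengths = c(chr1 = 40e6, chr3 = 40e6,
                                            chr5 = 40e6, chr7 = 40e6,
                                            chr8 = 40e6, chr17 = 40e6),
                          marker_spacing = 25e3,
                          cnvr_specs = default_cnvr_specs(),
                          marker_noise_sd = 0.1,
                          gene_spacing = 250e3, gene_length = 20e3,
                          driven_fraction = 0.12,
                          discordant_fraction = 0.22,
                          coupling_effect = 0.8,
                          expression_noise_sd = 1.0,
                          baseline_mean = 7, baseline_sd = 1,
                          tumor_effect_sd = 0,
                          active_set_size = 7, log_hazard = 0.5,
                          baseline_hazard = 0.015,
                          censor_min = 6, censor_max = 120,
                          n_decoy_sets = 7,
                          carrier_mode = c("deterministic", "bernoulli"),
                          seed = 20110914) {
  carrier_mode <- match.arg(carrier_mode)
  if (n_patients < 2) stop("n_patients must be at least 2")
  if (marker_noise_sd <= 0 || expression_noise_sd <= 0) {
    stop("noise SDs must be positive")
  }
  if (any(cnvr_specs$carrier_freq < 0) || any(cnvr_specs$carrier_freq > 1)) {
    stop("carrier frequencies must lie in [0, 1]")
  }
  if (driven_fraction < 0 || driven_fraction > 1 ||
      discordant_fraction < 0 || discordant_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  if (!all(cnvr_specs$chrom %in% names(chrom_lengths))) {
    stop("cnvr_specs reference unknown chromosomes")
  }
  if (any(cnvr_specs$start >= cnvr_specs$end)) {
    stop("cnvr_specs intervals must have start < end")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic paired cohort
#'
#' Normal-tissue marker copy number is 2 plus noise everywhere; tumor copy
#' number is additionally shifted by the configured amount inside carried
#' CNVRs (estimates floored at 0.01, as near-total loss reads as a small
#' positive value in bulk tissue). Expression is
#' `baseline_g + tumor_effect_g + gamma_g * (CN - 2) + noise` with
#' `gamma_g = 0` for uncoupled genes. Survival times are exponential with
#' rate `baseline_hazard * exp(sum_j beta_j z_ij)` over the active set
#' (z = per-gene standardized tumor expression), censored uniformly.
#' Identical configuration (including seed) gives identical output.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `tumor_tracks`
#'   and `normal_tracks` (named lists of per-sample marker `data.frame`s),
#'   `expression` (genes x samples matrix; columns `<patient>_tumor` /
#'   `<patient>_normal`), `genes` (BED-like `data.frame`), `gene_sets`
#'   (named list; the first set is the survival-active one), `clinical`
#'   (`data.frame` sample/time/event), `truth` (ground truth for recovery
#'   tests) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  .with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cf) {
  n <- cf$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  specs <- cf$cnvr_specs
  chroms <- names(cf$chrom_lengths)

  # marker grid
  marker_pos <- lapply(chroms, function(ch) {
    seq(0, cf$chrom_lengths[[ch]] - 1, by = cf$marker_spacing)
  })
  names(marker_pos) <- chroms

  # gene layout
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- seq(5e3, cf$chrom_lengths[[ch]] - cf$gene_length,
                  by = cf$gene_spacing)
    data.frame(chrom = ch, start = starts, end = starts + cf$gene_length,
               gene = sprintf("%s_g%04d", ch, seq_along(starts)),
               strand = "+", stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL

  # carrier assignment per planted CNVR
  carriers <- matrix(FALSE, nrow = nrow(specs), ncol = n,
                     dimnames = list(NULL, patients))
  for (i in seq_len(nrow(specs))) {
    if (cf$carrier_mode == "deterministic") {
      k <- as.integer(ceiling(specs$carrier_freq[i] * n - 1e-9))
      if (k > 0) carriers[i, sample.int(n, k)] <- TRUE
    } else {
      carriers[i, ] <- stats::runif(n) < specs$carrier_freq[i]
    }
  }

  # true gene-level copy number per patient (tumor); genes assigned to a
  # planted CNVR by any overlap
  true_cn <- matrix(2, nrow = nrow(genes), ncol = n,
                    dimnames = list(genes$gene, patients))
  gene_cnvr <- rep(NA_integer_, nrow(genes))
  for (i in seq_len(nrow(specs))) {
    hit <- genes$chrom == specs$chrom[i] & genes$start < specs$end[i] &
      genes$end > specs$start[i]
    gene_cnvr[hit] <- i
    true_cn[hit, carriers[i, ]] <- true_cn[hit, carriers[i, ]] +
      specs$cn_shift[i]
  }
  true_cn <- pmax(true_cn, 0.01)

  # marker tracks
  tumor_tracks <- vector("list", n)
  normal_tracks <- vector("list", n)
  names(tumor_tracks) <- names(normal_tracks) <- patients
  for (j in seq_len(n)) {
    per_chrom <- lapply(chroms, function(ch) {
      pos <- marker_pos[[ch]]
      mu <- rep(2, length(pos))
      for (i in which(specs$chrom == ch)) {
        if (carriers[i, j]) {
          inside <- pos >= specs$start[i] & pos < specs$end[i]
          mu[inside] <- mu[inside] + specs$cn_shift[i]
        }
      }
      data.frame(chrom = ch, pos = pos,
                 cn_t = pmax(mu + stats::rnorm(length(pos), 0,
                                               cf$marker_noise_sd), 0.01),
                 cn_n = pmax(2 + stats::rnorm(length(pos), 0,
                                              cf$marker_noise_sd), 0.01),
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, per_chrom)
    tumor_tracks[[j]] <- data.frame(chrom = d$chrom, pos = d$pos, cn = d$cn_t,
                                    stringsAsFactors = FALSE)
    normal_tracks[[j]] <- data.frame(chrom = d$chrom, pos = d$pos,
                                     cn = d$cn_n, stringsAsFactors = FALSE)
  }

  # coupled genes among CNVR genes
  cnvr_gene_idx <- which(!is.na(gene_cnvr))
  n_coupled <- round(cf$driven_fraction * length(cnvr_gene_idx))
  coupled_idx <- if (n_coupled > 0) sort(sample(cnvr_gene_idx, n_coupled))
    else integer(0)
  n_neg <- round(cf$discordant_fraction * n_coupled)
  neg_idx <- if (n_neg > 0) sort(sample(coupled_idx, n_neg)) else integer(0)
  gamma <- numeric(nrow(genes))
  gamma[coupled_idx] <- cf$coupling_effect
  gamma[neg_idx] <- -cf$coupling_effect

  # expression: genes x (tumor, normal) columns
  baseline <- stats::rnorm(nrow(genes), cf$baseline_mean, cf$baseline_sd)
  tumor_effect <- if (cf$tumor_effect_sd > 0)
    stats::rnorm(nrow(genes), 0, cf$tumor_effect_sd) else numeric(nrow(genes))
  G <- nrow(genes)
  tum <- baseline + tumor_effect + gamma * (true_cn - 2) +
    matrix(stats::rnorm(G * n, 0, cf$expression_noise_sd), G, n)
  nor <- baseline +
    matrix(stats::rnorm(G * n, 0, cf$expression_noise_sd), G, n)
  expression <- cbind(tum, nor)
  colnames(expression) <- c(paste0(patients, "_tumor"),
                            paste0(patients, "_normal"))
  rownames(expression) <- genes$gene

  # gene sets: active set of positively coupled genes (topped up from the
  # coupled then CNVR pool if needed), plus random decoys
  pos_coupled <- setdiff(coupled_idx, neg_idx)
  pool_pref <- c(pos_coupled, setdiff(coupled_idx, pos_coupled),
                 setdiff(cnvr_gene_idx, coupled_idx))
  active_idx <- pool_pref[seq_len(min(cf$active_set_size, length(pool_pref)))]
  if (length(active_idx) == 0) {
    # no CNVR genes planted: designate an arbitrary active set
    active_idx <- sample.int(G, min(cf$active_set_size, G))
  }
  gene_sets <- list(active_pathway = genes$gene[active_idx])
  for (s in seq_len(cf$n_decoy_sets)) {
    sz <- sample(5:10, 1)
    gene_sets[[sprintf("decoy_%02d", s)]] <- genes$gene[sample.int(G, sz)]
  }
  attr(gene_sets, "descriptions") <- stats::setNames(
    c("survival-active synthetic pathway",
      rep("random decoy set", cf$n_decoy_sets)), names(gene_sets))

  # survival from exponential PH on standardized tumor expression of the
  # active set (population-SD standardization, matching zscore_by_gene)
  beta <- stats::setNames(rep(cf$log_hazard, length(active_idx)),
                          genes$gene[active_idx])
  zt <- tum[active_idx, , drop = FALSE]
  mu_z <- rowMeans(zt)
  sd_z <- sqrt(rowMeans((zt - mu_z)^2))
  z <- (zt - mu_z) / sd_z
  lp <- as.numeric(crossprod(z, beta))
  t_event <- stats::rexp(n, rate = cf$baseline_hazard * exp(lp))
  t_cens <- stats::runif(n, cf$censor_min, cf$censor_max)
  clinical <- data.frame(sample = patients,
                         time = pmin(t_event, t_cens),
                         event = as.integer(t_event <= t_cens),
                         stringsAsFactors = FALSE)

  truth <- list(
    cnvrs = cbind(specs,
                  n_carriers = rowSums(carriers),
                  observed_freq = rowSums(carriers) / n),
    carriers = carriers,
    genes = data.frame(gene = genes$gene,
                       cnvr = ifelse(is.na(gene_cnvr), NA_character_,
                                     paste0(specs$chrom, ":",
                                            specs$direction)[gene_cnvr]),
                       in_cnvr = !is.na(gene_cnvr),
                       coupled = gamma != 0,
                       coupling_sign = sign(gamma),
                       gamma = gamma,
                       beta = ifelse(genes$gene %in% names(beta),
                                     cf$log_hazard, 0),
                       stringsAsFactors = FALSE),
    active_set = genes$gene[active_idx])

  structure(list(tumor_tracks = tumor_tracks, normal_tracks = normal_tracks,
                 expression = expression, genes = genes,
                 gene_sets = gene_sets, clinical = clinical, truth = truth,
                 config = cf),
            class = "synthetic_cohort")
}

#' Summarize the planted ground truth
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @return List with `cnvrs` (per-CNVR carrier counts and frequencies) and
#'   `genes` (counts of CNVR genes, coupled genes and negatively coupled
#'   genes).
#' @export
truth_report <- function(truth) {
  if (is.null(truth) || length(truth) == 0) {
    return(list(cnvrs = data.frame(), genes = data.frame(
      n_cnvr_genes = 0L, n_coupled = 0L, n_negative = 0L)))
  }
  g <- truth$genes
  list(cnvrs = truth$cnvrs,
       genes = data.frame(n_cnvr_genes = sum(g$in_cnvr),
                          n_coupled = sum(g$coupled),
                          n_negative = sum(g$coupling_sign < 0)))
}

#' Extract the tumor expression submatrix with patient column names
#'
#' @param expression Expression matrix with `<patient>_tumor` /
#'   `<patient>_normal` columns.
#' @return Matrix restricted to tumor columns, renamed to patient ids.
#' @export
tumor_matrix <- function(expression) {
  info <- sample_info(colnames(expression))
  m <- expression[, info$tissue == "tumor", drop = FALSE]
  colnames(m) <- info$patient[info$tissue == "tumor"]
  m
}
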