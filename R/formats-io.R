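# Readers/writers for the tabular formats the pipeline touches.
# All internal coordinates are 0-based half-open; SEG is emitted/consumed with
# 1-based inclusive starts as the dialect demands.

#' Read a SEG file of called copy-number segments
#'
#' SEG is the tab-separated exchange format for segmented copy-number data:
#' `Sample, Chromosome, Start, End, Num_Probes, Segment_Mean`, with 1-based
#' inclusive start coordinates and segment means on the log2(tumor/normal)
#' ratio scale. Coordinates are converted to the package's internal 0-based
#' half-open convention and segment means to absolute copy number
#' (`2 * 2^mean`, diploid = 2).
#'
#' @param path Path to a tab-separated SEG file with a header row.
#' @return A named list, one `data.frame` per sample (sorted by chromosome and
#'   start) with columns `sample`, `chrom`, `start`, `end`, `n_markers`,
#'   `seg_mean` (log2 ratio) and `mean_cn` (absolute copy number).
#' @export
read_seg <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 6) stop("SEG file must have at least 6 columns")
  if (nrow(raw) == 0) return(list())
  seg <- data.frame(
    sample = raw[[1]],
    chrom  = raw[[2]],
    start  = suppressWarnings(as.numeric(raw[[3]])),
    end    = suppressWarnings(as.numeric(raw[[4]])),
    n_markers = suppressWarnings(as.numeric(raw[[5]])),
    seg_mean  = suppressWarnings(as.numeric(raw[[6]])),
    stringsAsFactors = FALSE
  )
  bad <- which(!stats::complete.cases(seg) | seg$chrom == "" | seg$sample == "")
  if (length(bad) > 0) {
    stop(sprintf("malformed SEG row at line %d", bad[1] + 1L))
  }
  # 1-based inclusive -> 0-based half-open
  seg$start <- seg$start - 1
  bad <- which(seg$start >= seg$end)
  if (length(bad) > 0) {
    stop(sprintf("SEG row with start >= end at line %d", bad[1] + 1L))
  }
  seg$mean_cn <- 2 * 2^seg$seg_mean
  out <- lapply(split(seg, seg$sample), function(d) {
    d <- d[order(d$chrom, d$start), , drop = FALSE]
    for (ch in unique(d$chrom)) {
      dd <- d[d$chrom == ch, ]
      if (nrow(dd) > 1 && any(dd$start[-1] < dd$end[-nrow(dd)])) {
        stop(sprintf("overlapping segments for sample %s on %s",
                     dd$sample[1], ch))
      }
    }
    rownames(d) <- NULL
    d
  })
  out[order(names(out))]
}

#' Write segments to a SEG file
#'
#' Inverse of [read_seg()]: coordinates are converted back to 1-based
#' inclusive starts and absolute copy numbers to log2 ratios.
#'
#' @param segments A `data.frame` of segments (columns `sample`, `chrom`,
#'   `start`, `end`, `n_markers`, `mean_cn`) or a named list of such frames.
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
  if (is.list(segments) && !is.data.frame(segments)) {
    segments <- do.call(rbind, segments)
  }
  out <- data.frame(
    Sample = segments$sample,
    Chromosome = segments$chrom,
    Start = segments$start + 1,
    End = segments$end,
    Num_Probes = segments$n_markers,
    Segment_Mean = log2(segments$mean_cn / 2)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated gene-set format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of member genes, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT line %d: set '%s' has no members", i, f[1]))
    }
    nm <- f[1]
    if (nm %in% names(sets)) stop(sprintf("duplicate gene-set name '%s'", nm))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop(sprintf("GMT line %d: set '%s' has no members", i, nm))
    }
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors (optionally with a
#'   `descriptions` attribute as produced by [read_gmt()]).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene (or
#' probe) identifiers; remaining cells are log-scale intensities. Duplicate
#' rows for the same gene are collapsed to the probe with the highest mean
#' intensity across samples -- a deterministic rule for many-probes-per-gene
#' platforms.
#'
#' For paired designs, sample columns are named `<patient>_tumor` /
#' `<patient>_normal` (see [sample_info()]).
#'
#' @param path Path to the TSV file.
#' @param collapse Collapsing rule for duplicated gene identifiers; only
#'   `"max_mean"` is implemented.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path, collapse = "max_mean") {
  stopifnot(file.exists(path))
  collapse <- match.arg(collapse, "max_mean")
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(raw[[1]])
  sample_names <- names(raw)[-1]   # before [.data.frame uniquifies them
  vals <- raw[, -1, drop = FALSE]
  names(vals) <- sample_names
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num)) {
    stop(sprintf("non-numeric expression values in column '%s'",
                 names(vals)[which(!num)[1]]))
  }
  mat <- as.matrix(vals)
  if (any(!is.finite(mat))) stop("non-finite expression values")
  if (anyDuplicated(genes)) {
    means <- rowMeans(mat)
    keep <- vapply(split(seq_along(genes), genes), function(idx) {
      idx[which.max(means[idx])]
    }, integer(1))
    keep <- sort(unname(keep))
    mat <- mat[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(mat) <- genes
  info <- sample_info(colnames(mat))
  dup <- duplicated(paste(info$patient, info$tissue))
  if (any(dup)) {
    stop(sprintf("patient %s has more than one %s column",
                 info$patient[dup][1], info$tissue[dup][1]))
  }
  mat
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  out <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse sample identifiers into patient and tissue
#'
#' Columns named `<patient>_tumor` or `<patient>_normal` are split at the last
#' underscore; anything else is treated as a tumor-only sample whose patient
#' identifier is the column name (the layout of the expression-only validation
#' cohorts).
#'
#' @param samples Character vector of sample/column identifiers.
#' @return `data.frame` with columns `sample`, `patient`, `tissue`.
#' @export
sample_info <- function(samples) {
  m <- regmatches(samples, regexec("^(.*)_(tumor|normal)$", samples))
  patient <- vapply(seq_along(samples), function(i) {
    if (length(m[[i]]) == 3) m[[i]][2] else samples[i]
  }, character(1))
  tissue <- vapply(seq_along(samples), function(i) {
    if (length(m[[i]]) == 3) m[[i]][3] else "tumor"
  }, character(1))
  data.frame(sample = samples, patient = patient, tissue = tissue,
             stringsAsFactors = FALSE)
}

#' Read a clinical survival table from TSV
#'
#' @param path TSV with columns `sample`, `time` (months, positive) and
#'   `event` (1 = event observed, 0 = censored); extra columns are kept as
#'   covariates.
#' @return `data.frame` with at least `sample`, `time`, `event`.
#' @export
read_clinical <- function(path) {
  stopifnot(file.exists(path))
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(d))) {
    stop("clinical table must have columns sample, time, event")
  }
  if (!is.numeric(d$time) || any(!is.finite(d$time)) || any(d$time <= 0)) {
    stop("clinical times must be positive numbers")
  }
  if (!all(d$event %in% c(0, 1))) stop("clinical event must be 0 or 1")
  d$sample <- as.character(d$sample)
  d
}

#' Write a clinical table to TSV
#' @param clinical `data.frame` with columns `sample`, `time`, `event`.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene annotations from BED
#'
#' BED with >= 4 columns; the gene name is column 4, strand (if present)
#' column 6. BED coordinates are already 0-based half-open and are kept as-is.
#'
#' @param path Path to a BED file (no header).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `gene`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 4) stop("BED file must have at least 4 columns")
  out <- data.frame(
    chrom = as.character(d[[1]]),
    start = as.numeric(d[[2]]),
    end   = as.numeric(d[[3]]),
    gene  = as.character(d[[4]]),
    strand = if (ncol(d) >= 6) as.character(d[[6]]) else "*",
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) stop("BED interval with start >= end")
  out
}

#' Write gene annotations to BED6
#' @param genes `data.frame` with columns `chrom`, `start`, `end`, `gene` and
#'   optionally `strand`.
#' @param path Output path.
#' @export
write_bed <- function(genes, path) {
  strand <- if ("strand" %in% names(genes)) genes$strand else "*"
  out <- data.frame(genes$chrom, genes$start, genes$end, genes$gene,
                    0L, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges helper: internal 0-based half-open -> 1-based closed
.gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
}
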