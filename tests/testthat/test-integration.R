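# fixture: two genes in one amplification CNVR and one deletion CNVR, with
# hand-laid per-patient segments covering the full state x direction table
.status_fixture <- function() {
  gene_map <- data.frame(
    gene = c("GA", "GD"), cnvr_id = c("amp1", "del1"),
    direction = c("amplification", "deletion"), chrom = "chr1",
    gene_start = c(120, 520), gene_end = c(180, 580),
    stringsAsFactors = FALSE)
  seg <- function(sample, start, end, state) {
    data.frame(sample = sample, chrom = "chr1", start = start, end = end,
               n_markers = 10,
               mean_cn = c(amplified = 3, neutral = 2, deleted = 1.2)[state],
               state = state, boundary_p = NA, snr = NA,
               stringsAsFactors = FALSE)
  }
  segments <- list(
    P1 = rbind(seg("P1", 0, 300, "amplified"), seg("P1", 300, 600, "neutral")),
    P2 = rbind(seg("P2", 0, 300, "neutral"),  seg("P2", 300, 600, "deleted")),
    P3 = rbind(seg("P3", 0, 300, "deleted"),  seg("P3", 300, 600, "amplified")),
    P4 = rbind(seg("P4", 0, 600, "neutral")))
  list(gene_map = gene_map, segments = segments)
}

test_that("copy-number status enumerates the state x direction table", {
  fx <- .status_fixture()
  st <- build_cnv_status(fx$gene_map, fx$segments)
  # amplification-CNVR gene GA
  expect_equal(unname(st[1, c("P1", "P2", "P3", "P4")]),
               c("varied", "neutral", "opposite", "neutral"))
  # deletion-CNVR gene GD
  expect_equal(unname(st[2, c("P1", "P2", "P3", "P4")]),
               c("neutral", "varied", "opposite", "neutral"))
})

test_that("Welch statistics agree with the hand-evaluated formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  o <- oracle_welch(x, y)
  w <- cnvdrive:::.welch(x, y)
  expect_equal(w$t, o$t, tolerance = 1e-12)
  expect_equal(w$p, o$p, tolerance = 1e-12)
  # and with stats::t.test itself
  tt <- t.test(x, y)
  expect_equal(w$t, unname(tt$statistic))
  expect_equal(w$p, tt$p.value)
  # identical groups collapse to t = 0, p = 1
  w0 <- cnvdrive:::.welch(c(1, 1, 1), c(1, 1, 1))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
})

test_that("per-gene tests group tumors and normals by status and mode", {
  fx <- .status_fixture()
  patients <- paste0("P", 1:4)
  expr <- matrix(0, 2, 8,
                 dimnames = list(c("GA", "GD"),
                                 c(paste0(patients, "_tumor"),
                                   paste0(patients, "_normal"))))
  # GA: tumors of P1 high; normals flat
  expr["GA", ] <- c(5, 1, 1, 1, 1.2, 1.1, 0.9, 1.0)
  expr["GD", ] <- c(1, -3, 1, 1, 1.1, 0.9, 1.0, 1.2)
  st <- build_cnv_status(fx$gene_map, fx$segments)
  res <- test_all_genes(expr, st, fx$gene_map, mode = "paired")
  # GA varied = {P1}, neutral = {P2, P4}: one-member group is untestable
  expect_false(res$testable[res$gene == "GA"])
  # direction ties break to "up" on an identical-groups fixture
  expr2 <- expr
  expr2["GA", ] <- c(2, 2, 2, 2, 2, 2, 2, 2)
  st2 <- st
  st2[1, ] <- c("varied", "varied", "neutral", "neutral")
  res2 <- test_all_genes(expr2, st2, fx$gene_map, mode = "paired")
  expect_equal(res2$expr_direction[1], "up")
  expect_equal(res2$t[1], 0)
  expect_equal(res2$p[1], 1)
  # tumor_only mode compares tumor columns of both groups
  res3 <- test_all_genes(expr2, st2, fx$gene_map, mode = "tumor_only")
  expect_equal(res3$n_varied[1], 2)
  expect_equal(res3$n_neutral[1], 2)
})

test_that("Bonferroni bookkeeping matches a brute-force scan", {
  co <- generate_cohort(small_config(seed = 17))
  segs <- segment_cohort(co$tumor_tracks)
  cnvrs <- call_cnvrs(build_frequency_track(segs, length(segs)), 0.30, segs)
  gm <- map_genes(cnvrs, co$genes)
  st <- build_cnv_status(gm, segs)
  res <- test_all_genes(co$expression, st, gm)
  alpha <- attr(res, "alpha_per_test")
  expect_equal(alpha, 0.05 / nrow(gm))
  brute <- sum(res$p < alpha, na.rm = TRUE)
  expect_equal(sum(res$significant), brute)
  # genome-scale threshold: 0.05 over 5,086 genes is at most 1e-5
  expect_lte(0.05 / 5086, 1e-5)
})

test_that("the concordance filter keeps only direction-matched genes", {
  res <- data.frame(
    gene = c("a", "b", "c", "d"),
    direction = c("amplification", "amplification", "deletion", "deletion"),
    expr_direction = c("up", "down", "down", "down"),
    significant = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  res$concordant <- res$significant &
    ((res$direction == "amplification" & res$expr_direction == "up") |
     (res$direction == "deletion" & res$expr_direction == "down"))
  out <- concordance_filter(res)
  expect_equal(out$drivers$gene, c("a", "c"))   # discordant b, non-sig d drop
  expect_equal(out$n_significant, 3)
  expect_equal(out$n_discordant, 1)
  expect_equal(out$concordant_fraction, 2 / 3)
})

test_that("Z-values follow the two-step neutral-sample normalization", {
  gene_map <- data.frame(gene = "G", cnvr_id = "c", direction = "amplification",
                         chrom = "chr1", gene_start = 0, gene_end = 10,
                         stringsAsFactors = FALSE)
  patients <- paste0("P", 1:4)
  st <- matrix("neutral", 1, 4, dimnames = list(NULL, patients))
  st[1, 4] <- "varied"
  # neutral normals P1..P3 hold 1, 2, 3: median 2, sd 1
  expr <- matrix(0, 1, 8,
                 dimnames = list("G", c(paste0(patients, "_tumor"),
                                        paste0(patients, "_normal"))))
  expr[1, 5:7] <- c(1, 2, 3)
  s <- sd(c(1, 2, 3))
  expr[1, 4] <- 2 + s          # a tumor value one divisor above the median
  expr[1, 8] <- 2              # equals the neutral-normal median
  zv <- z_value_normalize(expr, st, gene_map)
  expect_false(zv$flagged[1])
  expect_equal(unname(zv$z[1, "P4_tumor"]), 1)
  expect_equal(unname(zv$z[1, "P4_normal"]), 0)
  # all-constant gene is flagged with z = 0 everywhere
  expr0 <- expr; expr0[1, ] <- 5
  zv0 <- z_value_normalize(expr0, st, gene_map)
  expect_true(zv0$flagged[1])
  expect_true(all(zv0$z == 0))
})

test_that("copy-number/expression correlations match direct evaluation", {
  cn <- c(2, 2.5, 3, 4)
  expect_equal(correlate_cn_expression(cn, 0.5 * cn + 1), 1)
  expect_equal(correlate_cn_expression(cn, -cn), -1)
  e <- c(5, 5.4, 6.1, 7.0)
  hand <- sum((cn - mean(cn)) * (e - mean(e))) /
    sqrt(sum((cn - mean(cn))^2) * sum((e - mean(e))^2))
  expect_equal(correlate_cn_expression(cn, e), hand, tolerance = 1e-12)
  expect_true(is.na(correlate_cn_expression(c(2, 2, 2), c(1, 2, 3))))
  expect_true(is.na(correlate_cn_expression(c(2, 3), c(1, 2))))
})

test_that("gene-level copy number is a length-weighted segment average", {
  genes <- data.frame(chrom = "chr1", start = 50, end = 150, gene = "G",
                      stringsAsFactors = FALSE)
  segs <- data.frame(sample = "S1", chrom = "chr1",
                     start = c(0, 100), end = c(100, 200), n_markers = 10,
                     mean_cn = c(2, 4), state = c("neutral", "amplified"),
                     boundary_p = NA, snr = NA, stringsAsFactors = FALSE)
  cn <- gene_cn_matrix(genes, segs)
  expect_equal(cn["G", "S1"], (50 * 2 + 50 * 4) / 100)
})

test_that("gene-list overlap p equals the brute-force hypergeometric tail", {
  universe <- sprintf("g%03d", 1:100)
  a <- universe[1:10]; b <- universe[6:15]   # overlap 5, 5 each side, 85 rest
  p <- gene_list_overlap(a, b, universe)
  expect_equal(p, oracle_hyper_tail(5, 10, 10, 100), tolerance = 1e-12)
  # A = B = universe: the table is degenerate and no enrichment is possible
  expect_equal(gene_list_overlap(universe, universe, universe), 1)
  # disjoint lists with large expected overlap: one-sided p near 1
  expect_gt(gene_list_overlap(universe[1:40], universe[41:100], universe),
            0.999)
  expect_error(gene_list_overlap(a, b, character(0)), "empty universe")
})
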