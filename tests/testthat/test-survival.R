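test_that("Z-score standardization uses the population-SD convention", {
  m <- matrix(c(1, 2, 3), 1, dimnames = list("G", paste0("P", 1:3)))
  z <- zscore_by_gene(m)
  s <- sqrt(mean((c(1, 2, 3) - 2)^2))          # divisor n
  expect_equal(unname(z[1, ]), (c(1, 2, 3) - 2) / s)
  expect_equal(sqrt(mean(z[1, ]^2)), 1)        # population SD exactly 1
  # location shifts vanish; an already-standardized row is unchanged
  expect_equal(zscore_by_gene(m + 100), z)
  expect_equal(zscore_by_gene(z), z)
  expect_error(zscore_by_gene(m[, 1, drop = FALSE]), "2 patients")
  m2 <- rbind(m, constant = c(5, 5, 5))
  expect_warning(z2 <- zscore_by_gene(m2), "zero-variance")
  expect_equal(rownames(z2), "G")
})

.surv_fixture <- function(n = 120, beta = 0.5, p_genes = 3, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(p_genes * n), p_genes, n,
              dimnames = list(sprintf("g%d", seq_len(p_genes)),
                              sprintf("P%03d", seq_len(n))))
  lp <- colSums(z * beta)
  t_event <- rexp(n, 0.02 * exp(lp))
  t_cens <- runif(n, 5, 100)
  clinical <- data.frame(sample = colnames(z),
                         time = pmin(t_event, t_cens),
                         event = as.integer(t_event <= t_cens),
                         stringsAsFactors = FALSE)
  list(z = z, clinical = clinical)
}

test_that("Cox scores are the coefficient-weighted sums of z-values", {
  fx <- .surv_fixture()
  cs <- cox_score(fx$z, fx$clinical)
  expect_true(cs$converged)
  expect_equal(unname(cs$scores),
               as.numeric(t(fx$z[, fx$clinical$sample]) %*% cs$beta))
  # a zero coefficient vector gives all-zero scores by linearity
  expect_equal(as.numeric(t(fx$z) %*% rep(0, 3)), rep(0, 120))
  # matches the coxph formula interface with Efron ties
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ t(z),
                    data = list(time = fx$clinical$time,
                                event = fx$clinical$event,
                                z = fx$z), ties = "efron"))
  expect_equal(unname(cs$beta), unname(coef(fit)), tolerance = 1e-8)
})

test_that("an unassociated gene has a coefficient near zero", {
  set.seed(99)
  n <- 500
  z <- matrix(rnorm(n), 1, dimnames = list("g1", sprintf("P%03d", 1:n)))
  clinical <- data.frame(sample = colnames(z),
                         time = rexp(n, 0.02), event = 1L,
                         stringsAsFactors = FALSE)
  cs <- cox_score(z, clinical)
  expect_lt(abs(cs$beta), 3 * cs$se)
})

test_that("the median split sends ties and the median to Low Score", {
  g <- median_split(setNames(c(1, 2, 3, 4), paste0("P", 1:4)))
  expect_equal(unname(g), c("Low Score", "Low Score",
                            "High Score", "High Score"))
  g2 <- median_split(setNames(c(1, 2, 2, 4), paste0("P", 1:4)))
  expect_equal(sum(g2 == "High Score"), 1)     # only the 4 clears median 2
  expect_equal(unname(g2["P4"]), "High Score")
  # permutation invariance of the induced partition
  s <- setNames(c(3, 1, 4, 2, 5), paste0("P", 1:5))
  perm <- sample(s)
  expect_equal(sort(names(which(median_split(s) == "High Score"))),
               sort(names(which(median_split(perm) == "High Score"))))
  expect_error(median_split(setNames(rep(1, 5), paste0("P", 1:5))),
               "identical")
  expect_error(median_split(setNames(1:3, paste0("P", 1:3))), "4 patients")
})

test_that("the log-rank test matches the hand-computed tally", {
  clinical <- data.frame(sample = paste0("P", 1:4),
                         time = c(1, 2, 3, 4), event = 1L,
                         stringsAsFactors = FALSE)
  groups <- setNames(c("Low Score", "Low Score", "High Score", "High Score"),
                     clinical$sample)
  lr <- logrank_test(groups, clinical)
  hand <- oracle_logrank_chisq(clinical$time, clinical$event,
                               groups == "High Score")
  expect_equal(lr$chisq, hand, tolerance = 1e-10)
  expect_equal(lr$p, pchisq(hand, 1, lower.tail = FALSE))
  expect_named(lr$km, c("group", "time", "n_risk", "n_event", "surv"))
  # identical survival in both groups: statistic 0, p = 1
  cl2 <- data.frame(sample = paste0("P", 1:8),
                    time = rep(c(2, 5, 9, 11), 2), event = 1L,
                    stringsAsFactors = FALSE)
  g2 <- setNames(rep(c("High Score", "Low Score"), each = 4), cl2$sample)
  lr2 <- logrank_test(g2, cl2)
  expect_equal(lr2$chisq, 0, tolerance = 1e-12)
  expect_equal(lr2$p, 1)
  # all-censored data cannot be tested
  cl3 <- cl2; cl3$event <- 0L
  expect_error(logrank_test(g2, cl3), "no events")
})

test_that("log-rank agrees with the hand tally on random censored data", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    clinical <- data.frame(sample = sprintf("P%02d", 1:n),
                           time = round(rexp(n, 0.1), 1) + 0.1,
                           event = rbinom(n, 1, 0.7),
                           stringsAsFactors = FALSE)
    if (sum(clinical$event) == 0) clinical$event[1] <- 1L
    groups <- setNames(
      ifelse(rbinom(n, 1, 0.5) == 1, "High Score", "Low Score"),
      clinical$sample)
    if (length(unique(groups)) < 2) groups[1:2] <- c("High Score",
                                                     "Low Score")
    lr <- logrank_test(groups, clinical)
    expect_equal(lr$chisq,
                 oracle_logrank_chisq(clinical$time, clinical$event,
                                      groups == "High Score"),
                 tolerance = 1e-8)
  }
})

test_that("empirical p follows the add-one ranking convention", {
  # observed beats every null draw
  expect_equal(empirical_p_value(1e-6, runif(99, 0.01, 1)), 1 / 100)
  # exactly 500 of 999 nulls at or below the observed value
  null <- c(seq(0.001, 0.5, length.out = 500),
            seq(0.61, 0.99, length.out = 499))
  expect_equal(empirical_p_value(0.5, null), 501 / 1000)
  # monotone in the observed p with the null fixed
  obs <- sort(runif(20))
  emp <- vapply(obs, empirical_p_value, numeric(1), null_p = null)
  expect_true(all(diff(emp) >= 0))
})

test_that("gene-set validation is seeded, reproducible and bounded", {
  fx <- .surv_fixture(n = 60, beta = 0.8, p_genes = 2, seed = 3)
  expr <- rbind(fx$z, matrix(rnorm(20 * 60), 20, 60,
                             dimnames = list(sprintf("n%02d", 1:20),
                                             colnames(fx$z))))
  v1 <- validate_gene_set(expr, fx$clinical, c("g1", "g2"),
                          n_iter = 50, seed = 11)
  v2 <- validate_gene_set(expr, fx$clinical, c("g1", "g2"),
                          n_iter = 50, seed = 11)
  expect_identical(v1[setdiff(names(v1), "km")], v2[setdiff(names(v2), "km")])
  expect_gte(v1$empirical_p, 1 / 51)
  expect_lte(v1$empirical_p, 1)
  expect_equal(v1$empirical_p, empirical_p_value(v1$observed_p, v1$null_p))
  # |High| <= |Low| under the tie rule
  expect_lte(sum(v1$groups == "High Score"), sum(v1$groups == "Low Score"))
  expect_error(validate_gene_set(expr, fx$clinical, rownames(expr),
                                 n_iter = 5), "pool")
})

test_that("the default iteration count is one hundred thousand", {
  expect_equal(eval(formals(validate_gene_set)$n_iter), 100000)
})
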