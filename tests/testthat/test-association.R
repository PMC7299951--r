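# Logistic fits, permutation engine, FDR, demographics tests.

test_that("logistic OR on a binary predictor equals the cross-product ratio", {
  d <- expand_2x2(27, 9, 30, 26)
  fit <- fit_logistic(d$y, d$x)
  expect_false(fit$flagged)
  expect_equal(fit$or, (27 * 26) / (9 * 30), tolerance = 1e-6)
  expect_true(fit$ci_low <= fit$or && fit$or <= fit$ci_high)
  # property over random 2x2 tables
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:40, 4, replace = TRUE)
    f <- fit_logistic(expand_2x2(n[1], n[2], n[3], n[4])$y,
                      expand_2x2(n[1], n[2], n[3], n[4])$x)
    expect_equal(f$or, (n[1] * n[4]) / (n[2] * n[3]), tolerance = 1e-6)
  }
})

test_that("symmetric data give beta = 0 and degenerate fits are flagged", {
  f0 <- fit_logistic(c(0, 1, 0, 1), c(1, 1, 0, 0))
  expect_lt(abs(f0$beta), 1e-8)
  expect_equal(f0$or, 1, tolerance = 1e-8)
  sep <- fit_logistic(c(1, 1, 1, 0, 0, 0), c(2, 3, 4, -2, -3, -4))
  expect_true(sep$flagged)
  expect_identical(sep$flag_reason, "separation")
  const <- fit_logistic(c(1, 0, 1, 0), rep(2, 4))
  expect_true(const$flagged)
  expect_identical(const$flag_reason, "constant predictor")
  onecls <- fit_logistic(rep(1, 4), rnorm(4))
  expect_identical(onecls$flag_reason, "single outcome class")
})

test_that("the C++ permutation backend matches glm's Wald inference", {
  set.seed(8)
  for (i in 1:15) {
    n <- sample(40:120, 1)
    X <- cbind(1, rnorm(n), rnorm(n), rbinom(n, 1, 0.5))
    y <- rbinom(n, 1, plogis(0.3 * X[, 2] - 0.2 * X[, 3]))
    if (length(unique(y)) < 2) next
    cw <- qpcrpanel:::cpp_logistic_wald(X, y)
    g <- suppressWarnings(glm(y ~ X - 1, family = binomial()))
    expect_true(isTRUE(cw$ok))
    expect_equal(as.numeric(cw$beta), unname(coef(g)), tolerance = 1e-7)
    expect_equal(as.numeric(cw$p),
                 unname(summary(g)$coefficients[, 4]), tolerance = 1e-5)
  }
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration", {
  # binary exposure, n = 8, 4 cases: the permutation distribution is uniform
  # over the choose(8,4) = 70 distinct label assignments
  x <- c(1, 1, 1, 0, 1, 0, 0, 0)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  wald_p <- function(yp) {
    # independent oracle route: stats::glm, with the engine's failure rule
    sep <- FALSE
    g <- withCallingHandlers(
      glm(yp ~ x, family = binomial()),
      warning = function(w) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep || !g$converged || abs(coef(g)[2]) > 30) return(1)
    summary(g)$coefficients[2, 4]
  }
  p_obs <- wald_p(y)
  combos <- combn(8, 4)
  # same tie rule as the engine: mathematically equal statistics count as
  # ties despite last-bit floating-point differences
  exact <- mean(apply(combos, 2, function(idx) {
    yp <- numeric(8)
    yp[idx] <- 1
    wald_p(yp) <= p_obs + 1e-8 * (p_obs + 1)
  }))
  mc <- permutation_pvalue(y, x, B = 10000, seed = 42)
  expect_lt(abs(mc$p_perm - exact),
            3 * sqrt(exact * (1 - exact) / 10000))
})

test_that("permutation tie rule and smoothing behave as documented", {
  y <- c(1, 0, 1, 0, 1, 0)
  const <- permutation_pvalue(y, rep(1, 6), B = 200, seed = 1)
  expect_identical(const$p_perm, 1)  # statistic tied under every permutation
  sm <- permutation_pvalue(y, c(3, -1, 2, 0, 2.5, -2), B = 99, seed = 3,
                           smooth = TRUE)
  expect_gte(sm$p_perm, 1 / 100)
  expect_error(permutation_pvalue(y, rnorm(6), B = 0), "B must be")
})

test_that("permutation p is invariant to which group is labelled the case", {
  set.seed(21)
  n <- 60
  x <- rnorm(n)
  covs <- data.frame(age = rnorm(n, 20, 3))
  y <- rbinom(n, 1, plogis(0.5 * x))
  a <- permutation_pvalue(y, x, covs, B = 500, seed = 9)
  b <- permutation_pvalue(1 - y, x, covs, B = 500, seed = 9)
  expect_identical(a$p_perm, b$p_perm)
})

test_that("BH adjustment matches an independent step-up oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_equal(fdr_adjust(rep(0.05, 5)), rep(0.05, 5))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  p <- runif(8)
  expect_true(all(fdr_adjust(p) >= p))
})

test_that("gene panel results are well-formed and FDR stays in-family", {
  set.seed(3)
  sc <- generate_cohort(sim_config(seed = 12))
  pan <- gene_panel_test(baseline_z(sc), sc$cohort, "baseline",
                         B = 200, seed = 4)
  expect_s3_class(pan, "gene_panel_result")
  expect_identical(attr(pan, "family"), "baseline")
  expect_identical(pan$gene, colnames(baseline_z(sc)))
  expect_true(all(pan$p_fdr >= pan$p_perm - 1e-12))
  expect_true(all(pan$n_used <= nrow(sc$cohort)))
  expect_true(all(pan$or > 0))
  expect_true(all(pan$ci_low <= pan$or & pan$or <= pan$ci_high))
  # FDR recomputed within the family reproduces the reported column
  expect_equal(pan$p_fdr, fdr_adjust(pan$p_perm), tolerance = 1e-12)
})

test_that("demographics table uses Mann-Whitney and Fisher as appropriate", {
  sc <- generate_cohort(sim_config(seed = 6))
  tab <- cohort_summary(sc$cohort)
  expect_true(all(tab$test[tab$type == "continuous"] == "mann-whitney",
                  na.rm = TRUE))
  expect_true(all(tab$test[tab$type == "categorical"] == "fisher",
                  na.rm = TRUE))
  # no-association and brute-force Fisher checks
  balanced <- data.frame(group = rep(c("converter", "non-converter"),
                                     each = 10),
                         flag = rep(c(1, 0), 10))
  t1 <- cohort_summary(balanced, continuous = character(),
                       categorical = "flag")
  expect_equal(t1$p_value, 1)
  # [[3,0],[0,3]]: only 2 of the 20 equal-margin tables are as extreme
  diag3 <- data.frame(group = rep(c("converter", "non-converter"), each = 3),
                      flag = c(1, 1, 1, 0, 0, 0))
  t2 <- cohort_summary(diag3, continuous = character(),
                       categorical = "flag")
  expect_equal(t2$p_value, 2 / 20, tolerance = 1e-12)
  const <- data.frame(group = rep(c("converter", "non-converter"), 5),
                      flag = rep(1, 10))
  t3 <- cohort_summary(const, continuous = character(), categorical = "flag")
  expect_identical(t3$flag, "constant variable")
  expect_true(is.na(t3$p_value))
})
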