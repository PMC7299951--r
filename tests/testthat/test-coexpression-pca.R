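# Correlation matrix, PCA identities and component-level group tests.

test_that("correlation matrix is symmetric with exact diagnostics", {
  set.seed(30)
  m <- matrix(rnorm(80), 20, 4,
              dimnames = list(sprintf("s%02d", 1:20), paste0("G", 1:4)))
  m[, 4] <- m[, 1]  # duplicated gene
  cm <- correlation_matrix(expr_matrix(m, "zscore"))
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 4))
  expect_equal(cm$r["G1", "G4"], 1, tolerance = 1e-12)
  expect_lt(cm$p["G1", "G4"], 1e-12)
  expect_true(all(abs(cm$r) <= 1 + 1e-12, na.rm = TRUE))
  # constant gene flagged
  m2 <- m
  m2[, 2] <- 3
  cm2 <- correlation_matrix(expr_matrix(m2, "zscore"))
  expect_identical(cm2$flagged, "G2")
  expect_true(is.na(cm2$r["G1", "G2"]))
})

test_that("panel correlation recovers the generator's equicorrelation", {
  set.seed(31)
  mean_r <- mean(replicate(30, {
    sc <- generate_cohort(null_config(seed = sample.int(1e6, 1)))
    cm <- correlation_matrix(baseline_z(sc))$r
    mean(cm[lower.tri(cm)])
  }))
  expect_gte(mean_r, 0.40)
  expect_lte(mean_r, 0.60)
})

test_that("PCA satisfies its algebraic identities", {
  set.seed(32)
  m <- matrix(rnorm(48), 12, 4,
              dimnames = list(sprintf("s%02d", 1:12), paste0("G", 1:4)))
  pc <- run_pca(expr_matrix(m, "zscore"))
  expect_equal(sum(pc$percent_variance), 100, tolerance = 1e-9)
  expect_true(all(diff(pc$percent_variance) <= 1e-12))
  expect_true(all(pc$eigenvalues >= -1e-12))
  expect_equal(sum(pc$eigenvalues), 4, tolerance = 1e-9)  # scaled PCA
  expect_equal(unname(apply(pc$scores, 2, var)), unname(pc$eigenvalues),
               tolerance = 1e-9)
  expect_equal(unname(colSums(pc$contributions)), rep(100, 4),
               tolerance = 1e-6)
  expect_lt(max(abs(colMeans(pc$scores))), 1e-9)
  # reconstruction of the centered/scaled matrix
  sc_m <- scale(m)
  recon <- pc$scores %*% t(pc$loadings)
  expect_lt(max(abs(recon - sc_m)), 1e-9)
  # brute-force eigendecomposition oracle on a 4 x 3 toy
  toy <- matrix(c(1, 2, 3, 4, 2, 1, 4, 3, 5, 5, 6, 8), 4, 3,
                dimnames = list(letters[1:4], c("A", "B", "C")))
  pt <- run_pca(expr_matrix(toy, "zscore"))
  expect_equal(unname(pt$eigenvalues),
               eigen(cor(toy), symmetric = TRUE)$values, tolerance = 1e-9)
})

test_that("rank-1 data put all variance on the first component", {
  x <- rnorm(10)
  m <- cbind(A = x, B = 2 * x + 5)
  rownames(m) <- sprintf("s%02d", 1:10)
  pc <- run_pca(expr_matrix(m, "zscore"))
  expect_equal(unname(pc$percent_variance), c(100, 0), tolerance = 1e-9)
})

test_that("results are invariant to input column order", {
  set.seed(33)
  m <- matrix(rnorm(60), 15, 4,
              dimnames = list(sprintf("s%02d", 1:15), paste0("G", 1:4)))
  p1 <- run_pca(expr_matrix(m, "zscore"))
  p2 <- run_pca(expr_matrix(m[, c(3, 1, 4, 2)], "zscore"))
  expect_equal(unname(p1$eigenvalues), unname(p2$eigenvalues),
               tolerance = 1e-9)
  expect_equal(p1$loadings[paste0("G", 1:4), ],
               p2$loadings[paste0("G", 1:4), ], tolerance = 1e-9)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-9)
})

test_that("sign convention puts the largest loading positive", {
  set.seed(34)
  m <- matrix(rnorm(100), 25, 4,
              dimnames = list(sprintf("s%02d", 1:25), paste0("G", 1:4)))
  pc <- run_pca(expr_matrix(m, "zscore"))
  for (k in seq_along(pc$eigenvalues)) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, k])), k], 0)
  }
})

test_that("a group shift on the shared factor is caught on PC1", {
  set.seed(35)
  hits <- replicate(20, {
    sc <- generate_cohort(sim_config(
      baseline_effects = 1.0, change_effects = 0,
      seed = sample.int(1e6, 1)))
    pca <- run_pca(baseline_z(sc))
    res <- pc_group_test(pca, sc$cohort, n_components = 3, B = 200,
                         seed = sample.int(1e6, 1))
    res$p_perm[res$gene == "PC1"] < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("constant component scores are flagged with p = 1", {
  fake <- structure(list(
    eigenvalues = c(PC1 = 1),
    percent_variance = c(PC1 = 100),
    loadings = matrix(1, 1, 1, dimnames = list("G", "PC1")),
    contributions = matrix(100, 1, 1, dimnames = list("G", "PC1")),
    scores = matrix(2, 30, 1,
                    dimnames = list(sprintf("S%03d", 1:30), "PC1")),
    center = 0, scale = NULL, n_used = 30), class = "pca_result")
  cohort <- data.frame(subject_id = sprintf("S%03d", 1:30),
                       group = rep(c("converter", "non-converter"), 15),
                       age = rnorm(30, 21, 3), sex = "male", cpz_eq = 0)
  res <- pc_group_test(fake, cohort, n_components = 1, B = 50, seed = 1)
  expect_true(res$flagged)
  expect_identical(res$flag_reason, "constant predictor")
  expect_identical(res$p_perm, 1)
})
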