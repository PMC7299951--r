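# Livak arithmetic, reference-group z-scores, calibrator invariance and
# longitudinal change bookkeeping.

toy_ct <- function() {
  data.frame(subject_id = c("a", "b", "c"),
             G1 = c(25, 26, 24), G2 = c(20, 21, 22),
             GAPDH = c(20, 20, 20))
}

test_that("delta-Ct is the per-subject difference to the reference gene", {
  d <- delta_ct(toy_ct())
  expect_equal(unclass(d)["a", "G1"], 5)
  expect_equal(unclass(d)["a", "G2"], 0)
  expect_identical(colnames(d), c("G1", "G2"))
  expect_error(delta_ct(toy_ct(), reference_gene = "ACTB"), "ACTB")
})

test_that("subjects missing the reference gene are dropped with a warning", {
  ct <- toy_ct()
  ct$GAPDH[2] <- NA
  expect_warning(d <- delta_ct(ct), "dropping 1")
  expect_identical(rownames(d), c("a", "c"))
})

test_that("Livak transformation: RQ = 2^-ddCt", {
  d <- delta_ct(toy_ct())
  # fixed calibrator equal to each subject's own dCt row -> RQ = 1
  rq_self <- relative_expression(d, "fixed",
                                 fixed_values = c(G1 = 5, G2 = 0))
  expect_equal(unclass(rq_self)["a", ], c(G1 = 1, G2 = 1))
  # one cycle below the calibrator doubles expression
  rq <- relative_expression(d, "fixed", fixed_values = c(G1 = 6, G2 = 1))
  expect_equal(unname(unclass(rq)["a", "G1"]), 2)
  # dCt = 5 against calibrator 6.5 -> ddCt = -1.5 -> RQ = 2^1.5
  rq2 <- relative_expression(d, "fixed", fixed_values = c(G1 = 6.5, G2 = 0))
  expect_equal(unname(unclass(rq2)["a", "G1"]), 2^1.5, tolerance = 1e-12)
})

test_that("RQ is strictly decreasing in delta-Ct", {
  dct <- expr_matrix(matrix(sort(rnorm(20)), 20, 1,
                            dimnames = list(sprintf("s%02d", 1:20), "G")),
                     "delta_ct")
  rq <- relative_expression(dct, "global_mean")
  expect_true(all(diff(unclass(rq)[, 1]) < 0))
})

test_that("reference-group z-scores have the documented moments", {
  m <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(letters[1:4], "G"))
  x <- expr_matrix(m, "rq")
  g <- c(a = "nc", b = "nc", c = "nc", d = "c")
  z <- zscore_on_reference(x, g, "nc")
  expect_equal(unname(unclass(z)["d", 1]), 2)  # ref mean 2, sd 1
  ref <- unclass(z)[c("a", "b", "c"), 1]
  expect_lt(abs(mean(ref)), 1e-9)
  expect_lt(abs(sd(ref) - 1), 1e-9)
})

test_that("zero reference SD is a hard error naming the gene", {
  m <- matrix(c(1, 1, 1, 5), 4, 1, dimnames = list(letters[1:4], "BADGENE"))
  g <- stats::setNames(c("nc", "nc", "nc", "c"), letters[1:4])
  expect_error(zscore_on_reference(expr_matrix(m, "rq"), g, "nc"), "BADGENE")
})

test_that("z-scores are invariant to the calibrator choice", {
  set.seed(1)
  d <- expr_matrix(matrix(rnorm(60, 6, 1), 20, 3,
                          dimnames = list(sprintf("s%02d", 1:20),
                                          c("G1", "G2", "G3"))),
                   "delta_ct")
  g <- stats::setNames(rep(c("c", "nc"), each = 10), rownames(d))
  zs <- lapply(list(
    relative_expression(d, "reference_group_mean", groups = g,
                        reference_group = "nc"),
    relative_expression(d, "global_mean"),
    relative_expression(d, "fixed",
                        fixed_values = c(G1 = 1, G2 = 2, G3 = 3))
  ), function(rq) unclass(zscore_on_reference(rq, g, "nc")))
  expect_lt(max(abs(zs[[1]] - zs[[2]])), 1e-12)
  expect_lt(max(abs(zs[[1]] - zs[[3]])), 1e-12)
  # and identically on the log2 scale
  zl <- lapply(list(
    relative_expression(d, "global_mean"),
    relative_expression(d, "fixed",
                        fixed_values = c(G1 = 0, G2 = -1, G3 = 4))
  ), function(rq) unclass(zscore_on_reference(log2_rq(rq), g, "nc")))
  expect_lt(max(abs(zl[[1]] - zl[[2]])), 1e-12)
})

test_that("multiplying a gene's RQ by c > 0 leaves z-scores unchanged", {
  set.seed(2)
  rq <- expr_matrix(matrix(2^rnorm(40), 20, 2,
                           dimnames = list(sprintf("s%02d", 1:20),
                                           c("G1", "G2"))), "rq")
  g <- stats::setNames(rep(c("c", "nc"), 10), rownames(rq))
  z1 <- zscore_on_reference(rq, g, "nc")
  scaled <- unclass(rq)
  scaled[, "G1"] <- scaled[, "G1"] * 7.3
  z2 <- zscore_on_reference(expr_matrix(scaled, "rq"), g, "nc")
  expect_equal(unclass(z1), unclass(z2), tolerance = 1e-12)
})

test_that("longitudinal change is complete-case follow-up minus baseline", {
  m0 <- expr_matrix(matrix(c(1, 1, 2), 3, 1,
                           dimnames = list(c("a", "b", "c"), "G")), "rq")
  mf <- expr_matrix(matrix(c(1, 0.5), 2, 1,
                           dimnames = list(c("a", "b"), "G")), "rq")
  chg <- longitudinal_change(m0, mf)
  expect_identical(rownames(chg), c("a", "b"))
  expect_equal(unname(unclass(chg)[, 1]), c(0, -0.5))
  mf_other <- expr_matrix(matrix(1, 1, 1, dimnames = list("zz", "G")), "rq")
  expect_error(longitudinal_change(m0, mf_other), "both time points")
  expect_error(longitudinal_change(m0, log2_rq(mf)), "different scales")
})

test_that("normalized Ct recovers the generator's latent scale", {
  cfg <- null_config(seed = 31)
  sc <- generate_cohort(cfg)
  d <- unclass(delta_ct(sc$ct_m0))
  resid <- d - (rep(cfg$gene_ct_offsets, each = nrow(d)) -
                  sc$truth$latent_m0)
  # residual is technical noise from two assays: sd ~ 0.25 * sqrt(2)
  expect_lt(abs(mean(resid)), 0.1)
  expect_lt(abs(sd(resid) - 0.25 * sqrt(2)), 0.1)
})

test_that("injected negative change effects depress converter changes", {
  ok <- replicate(30, {
    sc <- generate_cohort(sim_config(seed = sample.int(1e6, 1)))
    g <- cohort_groups(sc)
    rq0 <- relative_expression(delta_ct(sc$ct_m0), groups = g)
    rqf <- relative_expression(delta_ct(sc$ct_mf), groups = g)
    chg <- unclass(longitudinal_change(log2_rq(rq0), log2_rq(rqf)))
    grp <- g[rownames(chg)]
    eff <- names(which(sc$truth$change_effects < 0))
    all(colMeans(chg[grp == "converter", eff]) <
          colMeans(chg[grp == "non-converter", eff]))
  })
  expect_gte(mean(ok), 0.9)
})
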