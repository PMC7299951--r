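# Synthetic-cohort generator: emulates a longitudinal ultra-high-risk (UHR)
# case-conversion cohort with a correlated 7-gene qPCR expression panel,
# demographic/clinical covariates, group effects on baseline expression and on
# longitudinal change, and a small DNA-methylation subset.  Every downstream
# stage of the package is testable against the generator's truth record.

PANEL_GENES <- c("YWHAB", "YWHAE", "YWHAG", "YWHAH", "YWHAQ", "YWHAS", "YWHAZ")

#' Simulation configuration for a synthetic UHR conversion cohort
#'
#' Defaults describe the emulated study: 36 converters and 56 non-converters
#' at baseline, group-dependent follow-up retention of 29/36 and 38/56, a
#' seven-gene panel (plus the GAPDH reference gene) with equicorrelated
#' log2-expression (rho = 0.5), baseline case effects of +0.8 SD on five of
#' the seven genes, longitudinal-change effects of -0.6 SD on five genes,
#' covariate and clinical-score distributions matching the reported group
#' means and SDs, and a 25-subject (12/13) methylation subset in which five
#' gene-body CpGs of YWHAG correlate positively (+0.6) and one promoter CpG
#' of YWHAZ negatively (-0.6) with expression.
#'
#' @param n_converters,n_nonconverters group sizes at baseline.
#' @param genes character vector of target gene names.
#' @param reference_gene housekeeping gene used for Ct normalization; must
#'   not be among `genes`.
#' @param intergene_correlation equicorrelation of the *measured*
#'   log2-expression (delta-Ct) panel, in `[0, 1)`; the latent draw is
#'   inflated so the observed values carry this correlation after technical
#'   Ct noise.
#' @param baseline_effects named per-gene standardized mean difference
#'   (converter minus non-converter) of measured baseline log2 expression,
#'   in observed-SD units.
#' @param change_effects named per-gene standardized mean difference of the
#'   measured follow-up-minus-baseline log2-expression change, in
#'   observed-SD units of the change.
#' @param followup_retention probability of follow-up data, either a single
#'   value or a named vector `c(converter = , "non-converter" = )`.
#' @param longitudinal_sd SD (log2 units) of within-subject biological drift
#'   between the two time points.
#' @param ct_noise_sd technical Ct noise SD (cycles), applied independently
#'   to target and reference assays.
#' @param covariate_params,clinical_params,methylation_params nested lists of
#'   generative parameters; see the package vignette. Any element supplied
#'   here overrides the corresponding default.
#' @param seed integer seed; the generator never touches global RNG state.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_converters = 36L,
                       n_nonconverters = 56L,
                       genes = PANEL_GENES,
                       reference_gene = "GAPDH",
                       intergene_correlation = 0.5,
                       baseline_effects = c(YWHAB = 0.8, YWHAE = 0.8,
                                            YWHAG = 0.8, YWHAH = 0,
                                            YWHAQ = 0.8, YWHAS = 0,
                                            YWHAZ = 0.8),
                       change_effects = c(YWHAB = 0, YWHAE = -0.6,
                                          YWHAG = -0.6, YWHAH = -0.6,
                                          YWHAQ = 0, YWHAS = -0.6,
                                          YWHAZ = -0.6),
                       followup_retention = c(converter = 29 / 36,
                                              "non-converter" = 38 / 56),
                       longitudinal_sd = 0.5,
                       ct_noise_sd = 0.25,
                       covariate_params = list(),
                       clinical_params = list(),
                       methylation_params = list(),
                       seed = 1L) {
  if (length(genes) != length(unique(genes)))
    stop_named("gene names must be unique")
  if (reference_gene %in% genes)
    stop_named("reference gene '%s' must not be a target gene", reference_gene)
  if (n_converters + n_nonconverters < 4)
    stop_named("need at least 4 subjects in total")
  if (intergene_correlation < 0 || intergene_correlation >= 1)
    stop_named("intergene_correlation must be in [0, 1)")
  if (length(followup_retention) == 1L)
    followup_retention <- c(converter = unname(followup_retention),
                            "non-converter" = unname(followup_retention))
  if (any(followup_retention < 0 | followup_retention > 1))
    stop_named("followup_retention must be in [0, 1]")
  baseline_effects <- expand_gene_vector(baseline_effects, genes,
                                         "baseline_effects")
  change_effects <- expand_gene_vector(change_effects, genes, "change_effects")

  cov_def <- list(
    age = list(converter = c(mean = 20.0, sd = 2.53),
               "non-converter" = c(mean = 21.8, sd = 3.65), floor = 16),
    male_prop = c(converter = 27 / 36, "non-converter" = 30 / 56),
    tobacco_prop = c(converter = 0.50, "non-converter" = 0.354),
    cannabis_prop = c(converter = 0.375, "non-converter" = 0.205),
    medicated_prop = c(converter = 0.62, "non-converter" = 0.60),
    cpz = c(meanlog = log(200), sdlog = 0.6),
    followup_months = list(converter = c(mean = 9.8, sd = 5.7),
                           "non-converter" = c(mean = 13.7, sd = 4.0),
                           floor = 1)
  )
  clin_def <- list(
    bprs_m0 = list(converter = c(mean = 56.03, sd = 13.88),
                   "non-converter" = c(mean = 54.79, sd = 12.11), floor = 24),
    bprs_mf = list(converter = c(mean = 52.54, sd = 14.00),
                   "non-converter" = c(mean = 44.45, sd = 11.36), floor = 24),
    cgi_m0 = list(converter = c(mean = 4.53, sd = 0.84),
                  "non-converter" = c(mean = 4.59, sd = 0.82), floor = 1),
    cgi_mf = list(converter = c(mean = 4.78, sd = 0.85),
                  "non-converter" = c(mean = 3.74, sd = 1.20), floor = 1),
    panss_neg_mf = list(converter = c(mean = 18, sd = 6),
                        "non-converter" = c(mean = 14, sd = 5), floor = 7),
    caarms_m0 = c(converter = 3.0, "non-converter" = 3.0, sd = 1.2),
    caarms_mf = c(converter = 4.2, "non-converter" = 2.3, sd = 1.2),
    # latent correlation between one gene's baseline expression and the final
    # negative-symptom score (emulated expression/clinical association)
    assoc_gene = genes[[1L]],
    assoc_r = 0.5
  )
  meth_def <- list(
    n_converters = 12L,
    n_nonconverters = 13L,
    cpg_per_gene = stats::setNames(
      rep_len(c(18L, 18L, 18L, 17L, 17L, 17L, 17L), length(genes)), genes),
    promoter_frac = 0.3,
    beta_logit_sd = 0.5,
    effects = data.frame(
      gene = c(rep("YWHAG", 5L), "YWHAZ"),
      region = c(rep("body", 5L), "promoter"),
      index = c(1:5, 1L),
      r = c(rep(0.6, 5L), -0.6),
      stringsAsFactors = FALSE
    )
  )
  cfg <- structure(list(
    n_converters = as.integer(n_converters),
    n_nonconverters = as.integer(n_nonconverters),
    genes = genes,
    reference_gene = reference_gene,
    intergene_correlation = intergene_correlation,
    baseline_effects = baseline_effects,
    change_effects = change_effects,
    followup_retention = followup_retention,
    longitudinal_sd = longitudinal_sd,
    ct_noise_sd = ct_noise_sd,
    ref_ct = c(mean = 20, sd = 1),
    gene_ct_offsets = stats::setNames(
      seq(4, 7, length.out = length(genes)), genes),
    covariate_params = utils::modifyList(cov_def, covariate_params),
    clinical_params = utils::modifyList(clin_def, clinical_params),
    methylation_params = merge_meth_params(meth_def, methylation_params),
    seed = as.integer(seed)
  ), class = "sim_config")
  # equicorrelation matrices with rho in [0,1) are positive definite for any
  # panel size; guard anyway so user-supplied values fail loudly
  ev <- eigen(equicorr_matrix(length(genes), intergene_correlation),
              symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop_named("latent covariance is not positive definite")
  cfg
}

# modifyList would recurse into the `effects` data frame; replace it wholesale
merge_meth_params <- function(def, user) {
  out <- utils::modifyList(def, user[setdiff(names(user), "effects")])
  if ("effects" %in% names(user)) out$effects <- user$effects
  out
}

expand_gene_vector <- function(x, genes, what) {
  if (is.null(names(x))) {
    if (length(x) == 1L) x <- rep(x, length(genes))
    if (length(x) != length(genes))
      stop_named("%s must be named or have one value per gene", what)
    names(x) <- genes
  }
  if (!all(genes %in% names(x)))
    stop_named("%s is missing genes: %s", what,
               paste(setdiff(genes, names(x)), collapse = ", "))
  x[genes]
}

equicorr_matrix <- function(k, rho) {
  m <- matrix(rho, k, k)
  diag(m) <- 1
  m
}

#' Null simulation configuration
#'
#' Paper-scale cohort (36 converters / 56 non-converters, retention 29/36 and
#' 38/56) with every group effect, every expression-clinical association and
#' every CpG-expression correlation set to zero.  Used for type-I-error and
#' calibration checks.
#'
#' @param ... overrides passed on to [sim_config()].
#' @return a `sim_config` object.
#' @export
null_config <- function(...) {
  args <- list(...)
  defaults <- list(
    baseline_effects = 0,
    change_effects = 0,
    clinical_params = list(assoc_r = 0,
                           caarms_mf = c(converter = 3.0,
                                         "non-converter" = 3.0, sd = 1.2)),
    methylation_params = list(effects = data.frame(
      gene = character(), region = character(),
      index = integer(), r = numeric(), stringsAsFactors = FALSE))
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

#' Generate a synthetic cohort
#'
#' Draws a full synthetic data set under a [sim_config()]: per-subject latent
#' log2 expression from a multivariate normal with the configured
#' equicorrelation and group effects, follow-up values with within-subject
#' drift plus the configured change effects, raw Ct values synthesized so
#' that reference-gene normalization (delta-Ct) recovers the latent scale up
#' to technical noise, covariates and clinical scores per group, and a
#' methylation subset whose CpG beta values carry the configured correlations
#' with the matched gene's expression.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `cohort` (sample sheet data frame), `ct_m0` and `ct_mf` (wide Ct
#'   data frames, `ct_mf` restricted to retained subjects), `methylation`
#'   (beta-value data frame) with `cpg_map`, and `truth` (the injected
#'   effects, correlations and bookkeeping needed to score recovery).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  nc <- config$n_converters
  nn <- config$n_nonconverters
  n <- nc + nn
  genes <- config$genes
  G <- length(genes)
  group <- c(rep("converter", nc), rep("non-converter", nn))
  ids <- sprintf("S%03d", seq_len(n))
  conv <- as.numeric(group == "converter")

  cv <- config$covariate_params
  per_group <- function(par, draw) {
    out <- numeric(n)
    for (g in c("converter", "non-converter")) {
      idx <- group == g
      out[idx] <- draw(sum(idx), par, g)
    }
    out
  }
  age <- per_group(cv$age, function(k, p, g)
    rnorm_floor(k, p[[g]]["mean"], p[[g]]["sd"], p$floor))
  male <- per_group(cv$male_prop, function(k, p, g) rbinom(k, 1, p[[g]]))
  tobacco <- per_group(cv$tobacco_prop, function(k, p, g) rbinom(k, 1, p[[g]]))
  cannabis <- per_group(cv$cannabis_prop,
                        function(k, p, g) rbinom(k, 1, p[[g]]))
  medicated <- per_group(cv$medicated_prop,
                         function(k, p, g) rbinom(k, 1, p[[g]]))
  cpz <- ifelse(medicated == 1,
                rlnorm(n, cv$cpz["meanlog"], cv$cpz["sdlog"]), 0)
  followup <- per_group(cv$followup_months, function(k, p, g)
    rnorm_floor(k, p[[g]]["mean"], p[[g]]["sd"], p$floor))

  # Configured equicorrelation and effect sizes are contracts on the
  # *measured* scale (delta-Ct / log2 expression, technical noise included).
  # Normalized expression is -dCt = L + eps_ref - eps_target, so its
  # within-group variance is sd_L^2 + 2 sd_ct^2 and its correlation is
  # diluted by the same factor; the latent panel is therefore drawn with an
  # inflated correlation and effects are injected in observed-SD units.
  noise_var <- 2 * config$ct_noise_sd^2
  sd_obs <- sqrt(1 + noise_var)
  # the reference-gene noise is shared by all targets of a subject and so
  # contributes +sd_ct^2 covariance to every pair; subtract it here
  rho_lat <- config$intergene_correlation * (1 + noise_var) -
    config$ct_noise_sd^2
  if (rho_lat >= 1 || rho_lat <= -1 / (G - 1))
    stop_named(paste0("intergene_correlation %.3f is unattainable on the ",
                      "observed scale with ct_noise_sd = %.3f"),
               config$intergene_correlation, config$ct_noise_sd)
  R <- chol(equicorr_matrix(G, rho_lat))
  L0 <- matrix(rnorm(n * G), n, G) %*% R +
    outer(conv, config$baseline_effects * sd_obs)
  colnames(L0) <- genes

  # follow-up retention (missing-at-random within group)
  retained <- per_group(config$followup_retention,
                        function(k, p, g) rbinom(k, 1, p[[g]])) == 1
  flags <- character(0)
  for (g in c("converter", "non-converter")) {
    if (sum(retained[group == g]) < 2) {
      flags <- c(flags, sprintf("fewer than 2 follow-up subjects in group %s", g))
      warning(sprintf("retention left <2 follow-up subjects in group %s", g),
              call. = FALSE)
    }
  }
  # observed change (log2RQ_MF - log2RQ_M0) has variance
  # longitudinal_sd^2 + 4 sd_ct^2: drift plus noise at both time points
  sd_chg_obs <- sqrt(config$longitudinal_sd^2 + 4 * config$ct_noise_sd^2)
  LF <- L0 + matrix(rnorm(n * G, 0, config$longitudinal_sd), n, G) +
    outer(conv, config$change_effects * sd_chg_obs)

  synth_ct <- function(L, subjects) {
    k <- length(subjects)
    ref_base <- rnorm(k, config$ref_ct["mean"], config$ref_ct["sd"])
    ct <- ref_base + rep(config$gene_ct_offsets, each = k) -
      L[subjects, , drop = FALSE] +
      matrix(rnorm(k * G, 0, config$ct_noise_sd), k, G)
    colnames(ct) <- genes
    out <- data.frame(subject_id = ids[subjects], ct,
                      check.names = FALSE, stringsAsFactors = FALSE)
    out[[config$reference_gene]] <-
      ref_base + rnorm(k, 0, config$ct_noise_sd)
    out
  }
  ct_m0 <- synth_ct(L0, seq_len(n))
  ct_mf <- synth_ct(LF, which(retained))

  # clinical scores
  cl <- config$clinical_params
  draw_score <- function(par) per_group(par, function(k, p, g)
    rnorm_floor(k, p[[g]]["mean"], p[[g]]["sd"], p$floor))
  bprs_m0 <- draw_score(cl$bprs_m0)
  bprs_mf <- draw_score(cl$bprs_mf)
  cgi_m0 <- pmin(draw_score(cl$cgi_m0), 7)
  cgi_mf <- pmin(draw_score(cl$cgi_mf), 7)

  # final negative-symptom score correlated with one gene's baseline latent
  r <- cl$assoc_r
  zg <- as.numeric(scale(L0[, cl$assoc_gene]))
  eps <- rnorm(n)
  lat <- r * zg + sqrt(max(0, 1 - r^2)) * eps
  panss_neg_mf <- numeric(n)
  for (g in c("converter", "non-converter")) {
    idx <- group == g
    p <- cl$panss_neg_mf[[g]]
    panss_neg_mf[idx] <- pmax(p["mean"] + p["sd"] * lat[idx],
                              cl$panss_neg_mf$floor)
  }

  caarms_items <- function(par) {
    out <- matrix(0L, n, 8L)
    colnames(out) <- c(paste0("r", 1:4), paste0("f", 1:4))
    for (g in c("converter", "non-converter")) {
      idx <- group == g
      out[idx, ] <- rscore_int(sum(idx) * 8L, par[[g]], par["sd"])
    }
    out
  }
  ca_m0 <- caarms_items(cl$caarms_m0)
  ca_mf <- caarms_items(cl$caarms_mf)

  cohort <- data.frame(
    subject_id = ids, group = group, age = age,
    sex = ifelse(male == 1, "male", "female"),
    cpz_eq = cpz, medicated = medicated,
    followup_months = followup,
    tobacco = tobacco, cannabis = cannabis,
    has_m0 = TRUE, has_mf = retained,
    bprs_m0 = bprs_m0, bprs_mf = ifelse(retained, bprs_mf, NA_real_),
    cgi_m0 = cgi_m0, cgi_mf = ifelse(retained, cgi_mf, NA_real_),
    panss_neg_mf = ifelse(retained, panss_neg_mf, NA_real_),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (j in colnames(ca_m0)) cohort[[paste0("caarms_", j, "_m0")]] <- ca_m0[, j]
  for (j in colnames(ca_mf))
    cohort[[paste0("caarms_", j, "_mf")]] <-
      ifelse(retained, ca_mf[, j], NA_integer_)
  cohort$caarms_m0 <- caarms_composite(ca_m0[, 1:4], ca_m0[, 5:8])
  cohort$caarms_mf <- ifelse(retained,
                             caarms_composite(ca_mf[, 1:4], ca_mf[, 5:8]),
                             NA_integer_)

  meth <- generate_methylation(config, ids, group, retained, L0)

  truth <- list(
    # standardized mean differences on the measured (delta-Ct) scale
    baseline_effects = config$baseline_effects,
    change_effects = config$change_effects,
    injected_log2_shift = config$baseline_effects * sd_obs,
    injected_change_shift = config$change_effects * sd_chg_obs,
    intergene_correlation = config$intergene_correlation,
    latent_correlation = rho_lat,
    assoc_gene = cl$assoc_gene,
    assoc_r = r,
    cpg_truth = meth$cpg_truth,
    retention = config$followup_retention,
    n = c(converter = nc, "non-converter" = nn),
    n_followup = c(converter = sum(retained[group == "converter"]),
                   "non-converter" = sum(retained[group == "non-converter"])),
    latent_m0 = L0,
    flags = flags,
    seed = config$seed
  )
  structure(list(cohort = cohort, ct_m0 = ct_m0, ct_mf = ct_mf,
                 methylation = meth$betas, cpg_map = meth$map,
                 truth = truth),
            class = "synthetic_cohort")
}

# Deterministic CpG map plus beta values for the methylation subset.  Betas
# are logit-normal: logit(beta) = mu_cpg + s * (r * z_expr + sqrt(1-r^2) eps),
# so the configured correlation (and in particular its sign) propagates to
# the beta scale.
generate_methylation <- function(config, ids, group, retained, L0) {
  mp <- config$methylation_params
  genes <- config$genes
  counts <- mp$cpg_per_gene[genes]
  map <- do.call(rbind, lapply(genes, function(g) {
    k <- counts[[g]]
    n_prom <- max(1L, round(mp$promoter_frac * k))
    region <- c(rep("promoter", n_prom), rep("body", k - n_prom))
    data.frame(cpg_id = sprintf("cg_%s_%03d", g, seq_len(k)),
               gene = g, region = region,
               region_index = c(seq_len(n_prom), seq_len(k - n_prom)),
               stringsAsFactors = FALSE)
  }))
  true_r <- stats::setNames(rep(0, nrow(map)), map$cpg_id)
  eff <- mp$effects
  if (nrow(eff) > 0) {
    for (i in seq_len(nrow(eff))) {
      hit <- map$gene == eff$gene[i] & map$region == eff$region[i] &
        map$region_index == eff$index[i]
      if (!any(hit))
        stop_named("methylation effect %d refers to a CpG not in the map", i)
      true_r[map$cpg_id[hit]] <- eff$r[i]
    }
  }

  # subset: subjects with both time points, stated converter/non-converter split
  take <- function(g, k) {
    pool <- which(group == g & retained)
    if (length(pool) < k) {
      warning(sprintf("methylation subset truncated for group %s", g),
              call. = FALSE)
      k <- length(pool)
    }
    sort(sample(pool, k))
  }
  sel <- c(take("converter", mp$n_converters),
           take("non-converter", mp$n_nonconverters))
  ns <- length(sel)
  zexpr <- scale(L0[sel, , drop = FALSE])
  mu <- rnorm(nrow(map), -0.5, 1.0)  # per-CpG baseline methylation (logit)
  betas <- matrix(NA_real_, ns, nrow(map))
  for (j in seq_len(nrow(map))) {
    r <- true_r[[j]]
    x <- zexpr[, map$gene[j]]
    m <- r * x + sqrt(max(0, 1 - r^2)) * rnorm(ns)
    betas[, j] <- plogis(mu[j] + mp$beta_logit_sd * m)
  }
  colnames(betas) <- map$cpg_id
  list(
    betas = data.frame(subject_id = ids[sel], betas,
                       check.names = FALSE, stringsAsFactors = FALSE),
    map = map[, c("cpg_id", "gene", "region")],
    cpg_truth = data.frame(map[, c("cpg_id", "gene", "region")],
                           true_r = unname(true_r),
                           stringsAsFactors = FALSE)
  )
}

#' Write a synthetic cohort as the pipeline's delimited input files
#'
#' Writes `sample_sheet.csv`, `ct_m0.csv`, `ct_mf.csv` and, when a
#' methylation subset is present, `methylation.csv` and `cpg_map.csv` into
#' `dir`, in the schemas [read_inputs()] expects.
#'
#' @param x a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort_files <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sample_sheet = file.path(dir, "sample_sheet.csv"),
    ct_m0 = file.path(dir, "ct_m0.csv"),
    ct_mf = file.path(dir, "ct_mf.csv")
  )
  write.csv(x$cohort, paths["sample_sheet"], row.names = FALSE)
  write.csv(x$ct_m0, paths["ct_m0"], row.names = FALSE)
  write.csv(x$ct_mf, paths["ct_mf"], row.names = FALSE)
  if (!is.null(x$methylation)) {
    paths <- c(paths,
               methylation = file.path(dir, "methylation.csv"),
               cpg_map = file.path(dir, "cpg_map.csv"))
    write.csv(x$methylation, paths["methylation"], row.names = FALSE)
    write.csv(x$cpg_map, paths["cpg_map"], row.names = FALSE)
  }
  invisible(paths)
}
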