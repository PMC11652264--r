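# Bivariate piecewise latent growth model: per trait a childhood intercept
# and slope (parent-report waves) and a preadolescence intercept and
# adolescence slope (self-report waves), knotted at age 9 where the rater
# switches. The age-9 parent and age-9 self means are free to differ; no
# equality constraints cross the knot.

#' Piecewise slope/intercept loading matrix
#'
#' Intercept loadings are 1 within a segment; slope loadings are wave age
#' minus the segment anchor age, so the anchor wave loads exactly 0. Under
#' the default nominal ages the childhood slope loadings are (0, 3, 5) and
#' the adolescence slope loadings (0, 2, 7).
#'
#' @param wave_ages Ages of the six waves (3 parent, 3 self).
#' @param anchors Anchor ages of the two segments.
#' @return 12 x 8 matrix (waves for both traits x growth factors).
#' @export
piecewise_loadings <- function(wave_ages = c(4, 7, 9, 9, 11, 16),
                               anchors = c(4, 9)) {
  stopifnot(length(wave_ages) == 6, length(anchors) == 2)
  seg1 <- wave_ages[1:3]; seg2 <- wave_ages[4:6]
  if (!anchors[1] %in% seg1 || !anchors[2] %in% seg2) {
    stop("each anchor must equal one of its segment's wave ages ",
         "(slope loadings must include an exact 0)")
  }
  block <- cbind(I_c = c(rep(1, 3), rep(0, 3)),
                 S_c = c(seg1 - anchors[1], rep(0, 3)),
                 I_p = c(rep(0, 3), rep(1, 3)),
                 S_a = c(rep(0, 3), seg2 - anchors[2]))
  Lam <- rbind(cbind(block, matrix(0, 6, 4)),
               cbind(matrix(0, 6, 4), block))
  sch <- default_schema(wave_ages)
  dimnames(Lam) <- list(sch$waves$wave_id, FACTORS)
  Lam
}

#' Build the bivariate piecewise latent growth spec
#'
#' Twelve observed wave scores load on eight growth factors with the
#' piecewise pattern; factor means, variances and covariances are free, as
#' are all wave residual variances, the cross-trait residual covariance at
#' each wave, and the parent-self residual covariance at the knot age for
#' each trait (8 residual covariances; 64 free parameters in total).
#'
#' @param schema A [default_schema()] (supplies wave ids).
#' @param wave_ages,anchors Passed to [piecewise_loadings()].
#' @param groups Group labels for multi-group use.
#' @return A [sem_spec()].
#' @export
build_piecewise_lgc <- function(schema = default_schema(),
                                wave_ages = schema$wave_ages,
                                anchors = c(4, 9), groups = "all") {
  Lam <- piecewise_loadings(wave_ages, anchors)
  waves <- rownames(Lam)
  sp <- sem_spec(waves, FACTORS, groups)
  nz <- which(Lam != 0, arr.ind = TRUE)
  sp <- sem_par(sp, "lambda", waves[nz[, 1]], FACTORS[nz[, 2]],
                value = Lam[nz], free = FALSE)
  sp <- sem_par(sp, "alpha", FACTORS, value = c(2, 0, 2, 0, 2, 0, 2, 0),
                free = TRUE)
  sp <- sem_par(sp, "psi", FACTORS, FACTORS,
                value = c(1.5, 0.05, 1.5, 0.05, 1.5, 0.05, 1.5, 0.05),
                free = TRUE, lower = 1e-6)
  pr <- utils::combn(FACTORS, 2)
  sp <- sem_par(sp, "psi", pr[1, ], pr[2, ], value = 0, free = TRUE)
  sp <- sem_par(sp, "theta", waves, waves, value = 1.2, free = TRUE,
                lower = 1e-6)
  for (i in 1:6) {   # cross-trait residual covariance per wave
    sp <- sem_par(sp, "theta", waves[i], waves[i + 6], value = 0, free = TRUE)
  }
  knot <- which(wave_ages == anchors[2])
  for (off in c(0, 6)) {   # parent-self at the knot age, per trait
    sp <- sem_par(sp, "theta", waves[knot[1] + off], waves[knot[2] + off],
                  value = 0, free = TRUE)
  }
  sp
}

#' Extend the growth spec with an alcohol outcome regression
#'
#' Adds the (age-residualized) outcome as an observed variable regressed on
#' all eight growth factors and on the covariates; covariates are exogenous
#' observed variables free to covary with the factors and each other, which
#' also makes them auxiliary correlates for the missing-data model.
#'
#' @param spec A [build_piecewise_lgc()] spec (its groups are kept).
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate column names.
#' @return The extended [sem_spec()].
#' @export
add_outcome <- function(spec, outcome, covariates = character()) {
  waves <- spec$observed
  exo <- covariates
  obs <- c(waves, outcome, exo)
  lat <- c(spec$latent, paste0("f_", c(outcome, exo)))
  sp <- sem_spec(obs, lat, spec$groups)
  sp$params <- spec$params            # inherit the growth parameterization
  fy <- paste0("f_", outcome)
  sp <- sem_par(sp, "lambda", c(outcome, exo), paste0("f_", c(outcome, exo)),
                value = 1, free = FALSE)
  sp <- sem_par(sp, "beta", fy, FACTORS, value = 0, free = TRUE)
  sp <- sem_par(sp, "alpha", fy, value = 0, free = TRUE)
  sp <- sem_par(sp, "psi", fy, fy, value = 1, free = TRUE, lower = 1e-6)
  for (x in exo) {
    fx <- paste0("f_", x)
    sp <- sem_par(sp, "beta", fy, fx, value = 0, free = TRUE)
    sp <- sem_par(sp, "alpha", fx, value = 0, free = TRUE)
    sp <- sem_par(sp, "psi", fx, fx, value = 1, free = TRUE, lower = 1e-6)
    sp <- sem_par(sp, "psi", rep(fx, 8), FACTORS, value = 0, free = TRUE)
  }
  if (length(exo) > 1) {
    pr <- utils::combn(paste0("f_", exo), 2)
    sp <- sem_par(sp, "psi", pr[1, ], pr[2, ], value = 0, free = TRUE)
  }
  sp
}

# individual-level analysis frame: one row per twin, preprocessed outcome,
# numeric covariates (sex coded female = 1), plus family_id for clustering.
analysis_frame <- function(dataset, covariates = character(),
                           preprocess = TRUE) {
  ds <- if (preprocess) preprocess_alcohol(dataset) else dataset
  long <- stack_twins(as.data.frame(ds))
  if ("sex" %in% names(long)) {
    long$sex_num <- as.numeric(long$sex == "female")
  }
  long
}

#' Latent covariance and standardized coefficients of a fitted outcome model
#'
#' @param fit A `twinpaths_fit` of an [add_outcome()] spec.
#' @param group Group whose moments to use.
#' @return Data frame of outcome regressions with raw and standardized
#'   estimates and 95% confidence intervals (robust when a sandwich
#'   covariance is attached).
#' @export
standardized_paths <- function(fit, group = fit$model$groups[1]) {
  spec <- fit$model$spec
  mats <- fit$model$fill(fit$estimates[fit$model$labels])[[group]]
  m <- length(spec$latent)
  Tm <- solve(diag(m) - mats$beta)
  Psi_lat <- Tm %*% mats$psi %*% t(Tm)
  dimnames(Psi_lat) <- list(spec$latent, spec$latent)
  beta_rows <- spec$params[spec$params$free & spec$params$matrix == "beta", ]
  fy <- unique(beta_rows$row)[1]      # the regressed (outcome) latent
  locs <- beta_rows[beta_rows$row == fy & beta_rows$group == group, ]
  V <- if (!is.null(fit$vcov_robust)) fit$vcov_robust else fit$vcov
  out <- do.call(rbind, lapply(seq_len(nrow(locs)), function(i) {
    lab <- locs$label[i]; pred <- locs$col[i]
    b <- fit$estimates[[lab]]
    se <- if (is.null(V)) NA_real_ else sqrt(V[lab, lab])
    ratio <- sqrt(Psi_lat[pred, pred] / Psi_lat[fy, fy])
    data.frame(predictor = pred, label = lab, estimate = b, se = se,
               beta_std = b * ratio,
               ci_lower_std = (b - 1.96 * se) * ratio,
               ci_upper_std = (b + 1.96 * se) * ratio,
               z = b / se, p = 2 * stats::pnorm(-abs(b / se)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fit the joint growth + alcohol regression model
#'
#' One-step estimation: the piecewise growth structure and the outcome
#' regression are fitted simultaneously by FIML on individual twins, with
#' family-cluster-robust standard errors.
#'
#' @param dataset A wide `twin_dataset`.
#' @param outcome One of `"audit_total"`, `"audit_consumption"`,
#'   `"audit_problem"` (preprocessed internally: age residualization, log
#'   transform of Problem).
#' @param covariates Covariate columns of the stacked frame (use
#'   `"sex_num"` for sex, `"ses"` for SES).
#' @param wave_ages,anchors Growth model geometry.
#' @param spec Optional pre-built spec (e.g. a pruned one); must match
#'   `outcome` and `covariates`.
#' @param preprocess Apply [preprocess_alcohol()] first? Set FALSE when the
#'   dataset is already age-residualized.
#' @param ... Passed to [fit_fiml()].
#' @return A `twinpaths_fit` with `$vcov_robust` attached and
#'   `$standardized` (the [standardized_paths()] table).
#' @export
fit_outcome_model <- function(dataset, outcome = "audit_total",
                              covariates = c("sex_num", "ses"),
                              wave_ages = c(4, 7, 9, 9, 11, 16),
                              anchors = c(4, 9), spec = NULL,
                              preprocess = TRUE, ...) {
  long <- analysis_frame(dataset, covariates, preprocess = preprocess)
  if (all(is.na(long[[outcome]]))) stop("outcome column entirely missing")
  if (is.null(spec)) {
    spec <- add_outcome(build_piecewise_lgc(wave_ages = wave_ages,
                                            anchors = anchors),
                        outcome, covariates)
  }
  fit <- fit_sem(spec, long, ...)
  if (!is.null(fit$vcov)) {
    fit <- with_robust_vcov(fit, long$family_id)
  }
  fit$standardized <- standardized_paths(fit)
  fit
}

#' Fix nonsignificant covariances to zero, guarding overall fit
#'
#' Covariances (factor covariances and residual covariances) whose robust-SE
#' z-test is nonsignificant are fixed to zero jointly; the pruned model is
#' kept only if a chi-square difference test against the full model is
#' nonsignificant, otherwise covariances are restored one at a time by
#' largest likelihood gain until it is.
#'
#' @param fit A converged fit of `spec` with (robust) standard errors.
#' @param spec The spec that produced `fit`.
#' @param data,group Data (and optional group column) used for refitting.
#' @param alpha Significance level.
#' @param ... Passed to [fit_sem()].
#' @return List: `spec`, `fit` (pruned, refitted), `dropped`, `restored`,
#'   `lr` (final test against the full fit).
#' @export
prune_nonsignificant_covariances <- function(fit, spec, data, group = NULL,
                                             alpha = 0.05, ...) {
  pt <- fit_parameters(fit)
  cand <- unique(c(spec_labels(spec, "psi", diagonal = FALSE),
                   spec_labels(spec, "theta", diagonal = FALSE)))
  pt <- pt[pt$label %in% cand, ]
  nonsig <- pt$label[!is.na(pt$p) & pt$p >= alpha]
  if (length(nonsig) == 0) {
    return(list(spec = spec, fit = fit, dropped = character(),
                restored = character(), lr = list(chisq = 0, df = 0, p = 1)))
  }
  fix_labels <- function(sp, labels) {
    hit <- !is.na(sp$params$label) & sp$params$label %in% labels
    sp$params$free[hit] <- FALSE
    sp$params$value[hit] <- 0
    sp$params$label[hit] <- NA_character_
    sp
  }
  dropped <- nonsig
  restored <- character()
  repeat {
    sp2 <- fix_labels(spec, dropped)
    fit2 <- fit_sem(sp2, data, group = group,
                    start = warm_start(compile_spec(sp2), fit$estimates), ...)
    fit <- improve_reference(fit2, fit, data, group, ...)
    lr <- lr_test(fit2, fit)
    if (lr$p >= alpha || length(dropped) == 0) {
      return(list(spec = sp2, fit = fit2, dropped = dropped,
                  restored = restored, lr = lr))
    }
    gains <- vapply(dropped, function(lb) {
      sp3 <- fix_labels(spec, setdiff(dropped, lb))
      f3 <- fit_sem(sp3, data, group = group, se = FALSE,
                    start = warm_start(compile_spec(sp3), fit$estimates), ...)
      f3$loglik - fit2$loglik
    }, numeric(1))
    best <- names(gains)[which.max(gains)]
    restored <- c(restored, best)
    dropped <- setdiff(dropped, best)
  }
}

#' Ordered multi-group sex-difference pipeline
#'
#' Fits the joint growth + outcome model separately for females and males,
#' then constrains parameters equal across the sexes in the fixed order:
#' (1) everything involving covariates except the outcome-on-covariate
#' coefficients; (2) growth-factor means; (3) factor variances; (4) factor
#' covariances; (5) wave residual variances and covariances. Each step is
#' tested by a chi-square difference test against the previously accepted
#' model; a significant step triggers an exact modification search that
#' frees the offending constraints one at a time. Wald tests then compare
#' every outcome-on-factor and outcome-on-covariate coefficient between the
#' sexes (cluster-robust covariance); coefficients with nonsignificant Wald
#' tests are equated, and finally the outcome intercept and residual
#' variance are equated if a difference test allows.
#'
#' @param dataset A wide `twin_dataset` with a `sex_t*` columns.
#' @param outcome,covariates As in [fit_outcome_model()] (sex must NOT be a
#'   covariate here; it defines the groups).
#' @param alpha Significance level used throughout.
#' @param wave_ages,anchors Growth geometry.
#' @param preprocess Apply [preprocess_alcohol()] first?
#' @param ... Passed to the underlying fits.
#' @return List: `steps` (per-step tests and freed labels), `wald` (per
#'   coefficient), `equated_coefficients`, `intercept_residual`, `fit`
#'   (final), `spec`.
#' @export
sex_difference_pipeline <- function(dataset, outcome = "audit_total",
                                    covariates = "ses", alpha = 0.05,
                                    wave_ages = c(4, 7, 9, 9, 11, 16),
                                    anchors = c(4, 9), preprocess = TRUE,
                                    ...) {
  long <- analysis_frame(dataset, covariates, preprocess = preprocess)
  long$sex_group <- long$sex
  if (any(!stats::complete.cases(long$sex))) long <- long[!is.na(long$sex), ]
  for (g in c("female", "male")) {
    if (all(is.na(long[[outcome]][long$sex_group == g]))) {
      stop("group '", g, "' has no outcome data")
    }
  }
  spec <- add_outcome(build_piecewise_lgc(wave_ages = wave_ages,
                                          anchors = anchors,
                                          groups = c("female", "male")),
                      outcome, covariates)
  fy <- paste0("f_", outcome)
  base <- function(labels) unique(sub("\\.(female|male)$", "", labels))
  cov_lat <- paste0("f_", covariates)
  steps <- list(
    covariates = base(c(spec_labels(spec, "psi", row = cov_lat),
                        spec_labels(spec, "psi", col = cov_lat),
                        spec_labels(spec, "alpha", row = cov_lat))),
    factor_means = base(spec_labels(spec, "alpha", row = FACTORS)),
    factor_variances = base(spec_labels(spec, "psi", row = FACTORS,
                                        col = FACTORS, diagonal = TRUE)),
    factor_covariances = base(spec_labels(spec, "psi", row = FACTORS,
                                          col = FACTORS, diagonal = FALSE)),
    residuals = base(spec_labels(spec, "theta"))
  )
  # The fully free two-group model has no cross-group constraints, so its
  # ML solution separates exactly into two single-group fits (seeded by a
  # pooled fit); the joint k ~ 170 optimization would need thousands of
  # quasi-Newton iterations for the same answer.
  pooled_spec <- add_outcome(build_piecewise_lgc(wave_ages = wave_ages,
                                                 anchors = anchors),
                             outcome, covariates)
  pooled_fit <- fit_sem(pooled_spec, long, se = FALSE, iter_max = 3000, ...)
  comp_pooled <- compile_spec(pooled_spec)
  group_fits <- lapply(c("female", "male"), function(g) {
    fit_sem(pooled_spec, long[long$sex_group == g, , drop = FALSE],
            se = FALSE, iter_max = 3000,
            start = warm_start(comp_pooled, pooled_fit$estimates), ...)
  })
  names(group_fits) <- c("female", "male")
  comp_free <- compile_spec(spec)
  est_free <- unlist(lapply(c("female", "male"), function(g)
    stats::setNames(group_fits[[g]]$estimates,
                    paste0(names(group_fits[[g]]$estimates), ".", g))))
  est_free <- est_free[comp_free$labels]
  fit_free <- structure(list(
    estimates = est_free,
    loglik = group_fits$female$loglik + group_fits$male$loglik,
    k = length(est_free),
    AIC = -2 * (group_fits$female$loglik + group_fits$male$loglik) +
      2 * length(est_free),
    vcov = NULL, model = comp_free,
    convergence = list(
      converged = group_fits$female$convergence$converged &&
        group_fits$male$convergence$converged,
      grad_scaled = max(group_fits$female$convergence$grad_scaled,
                        group_fits$male$convergence$grad_scaled),
      iterations = group_fits$female$convergence$iterations +
        group_fits$male$convergence$iterations,
      boundary = character())), class = "twinpaths_fit")
  accepted_spec <- spec
  accepted_fit <- fit_free
  step_rows <- list()
  for (nm in names(steps)) {
    labs <- steps[[nm]]
    sp_c <- equate_across_groups(accepted_spec, labs)
    fit_c <- fit_sem(sp_c, long, group = "sex_group", se = FALSE,
                     start = warm_start(compile_spec(sp_c),
                                        accepted_fit$estimates), ...)
    accepted_fit <- improve_reference(fit_c, accepted_fit, long, "sex_group",
                                      ...)
    lr <- lr_test(fit_c, accepted_fit)
    freed <- character()
    if (lr$p < alpha) {
      ms <- modification_search(sp_c, long, "sex_group", labs, accepted_fit,
                                alpha = alpha, fit = fit_c, ...)
      sp_c <- ms$spec; fit_c <- ms$fit
      freed <- ms$log$freed
      lr <- lr_test(fit_c, accepted_fit)
    }
    step_rows[[nm]] <- data.frame(step = nm, chisq = lr$chisq, df = lr$df,
                                  p = lr$p, freed = paste(freed, collapse = ";"),
                                  stringsAsFactors = FALSE)
    accepted_spec <- sp_c
    accepted_fit <- fit_c
  }
  # Wald tests need standard errors: refit the accepted model with SEs and
  # a family-cluster-robust covariance
  fit_se <- fit_sem(accepted_spec, long, group = "sex_group", se = TRUE,
                    start = warm_start(compile_spec(accepted_spec),
                                       accepted_fit$estimates), ...)
  fit_se <- with_robust_vcov(fit_se, long$family_id)
  V <- fit_se$vcov_robust
  coef_bases <- base(spec_labels(accepted_spec, "beta", row = fy))
  wald <- do.call(rbind, lapply(coef_bases, function(b) {
    lf <- paste0(b, ".female"); lm <- paste0(b, ".male")
    if (!all(c(lf, lm) %in% names(fit_se$estimates))) return(NULL)
    w <- wald_equality(fit_se$estimates[[lf]], sqrt(V[lf, lf]),
                       fit_se$estimates[[lm]], sqrt(V[lm, lm]), V[lf, lm])
    data.frame(coefficient = b, b_female = fit_se$estimates[[lf]],
               b_male = fit_se$estimates[[lm]], W = w$W, p = w$p,
               stringsAsFactors = FALSE)
  }))
  equated <- wald$coefficient[wald$p >= alpha]
  if (length(equated)) {
    accepted_spec <- equate_across_groups(accepted_spec, equated)
    accepted_fit <- fit_sem(accepted_spec, long, group = "sex_group",
                            se = FALSE,
                            start = warm_start(compile_spec(accepted_spec),
                                               accepted_fit$estimates), ...)
  }
  # finally try equating the outcome intercept and residual variance
  ir_labels <- base(c(spec_labels(accepted_spec, "alpha", row = fy),
                      spec_labels(accepted_spec, "psi", row = fy, col = fy)))
  sp_ir <- equate_across_groups(accepted_spec, ir_labels)
  fit_ir <- fit_sem(sp_ir, long, group = "sex_group", se = FALSE,
                    start = warm_start(compile_spec(sp_ir),
                                       accepted_fit$estimates), ...)
  accepted_fit <- improve_reference(fit_ir, accepted_fit, long, "sex_group",
                                    ...)
  lr_ir <- lr_test(fit_ir, accepted_fit)
  ir_ok <- lr_ir$p >= alpha
  if (ir_ok) { accepted_spec <- sp_ir; accepted_fit <- fit_ir }
  list(steps = do.call(rbind, step_rows), wald = wald,
       equated_coefficients = equated,
       intercept_residual = c(lr_ir, list(equated = ir_ok)),
       fit = accepted_fit, spec = accepted_spec, fit_se = fit_se)
}
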