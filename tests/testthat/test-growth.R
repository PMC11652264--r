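test_that("piecewise loadings follow age minus anchor", {
  L <- piecewise_loadings()
  expect_equal(unname(L[1:3, "em_Sc"]), c(0, 3, 5))
  expect_equal(unname(L[4:6, "em_Sa"]), c(0, 2, 7))
  expect_equal(unname(L[7:9, "cd_Sc"]), c(0, 3, 5))
  expect_equal(unname(L[10:12, "cd_Sa"]), c(0, 2, 7))
  # each wave loads on exactly one intercept and one slope of its own trait
  expect_true(all(rowSums(L != 0) <= 2))
  expect_true(all(L[1:6, 5:8] == 0), all(L[7:12, 1:4] == 0))
  # custom ages shift the slope loadings
  L2 <- piecewise_loadings(c(4, 7.2, 9, 9, 11.5, 16.3))
  expect_equal(unname(L2[1:3, "em_Sc"]), c(0, 3.2, 5))
  expect_error(piecewise_loadings(anchors = c(5, 9)), "anchor")
  expect_error(piecewise_loadings(anchors = c(4, 10)), "anchor")
})

test_that("the full bivariate growth spec frees 64 parameters in four blocks", {
  sp <- build_piecewise_lgc()
  labs <- list(
    means = spec_labels(sp, "alpha"),
    facvar = spec_labels(sp, "psi", diagonal = TRUE),
    faccov = spec_labels(sp, "psi", diagonal = FALSE),
    resvar = spec_labels(sp, "theta", diagonal = TRUE),
    rescov = spec_labels(sp, "theta", diagonal = FALSE)
  )
  expect_length(labs$means, 8)
  expect_length(labs$facvar, 8)
  expect_length(labs$faccov, 28)
  expect_length(labs$resvar, 12)
  # 6 cross-trait same-wave + 2 parent-self at the knot age
  expect_length(labs$rescov, 8)
  expect_length(unique(unlist(labs)), 64)
  # the two age-9 waves are distinct variables with free residual link
  expect_true("theta_cd_s9_cd_p9" %in% labs$rescov ||
                "theta_cd_p9_cd_s9" %in% labs$rescov)
  # no equality constraints bridge the parent and self segments
  parent_labs <- spec_labels(sp, "theta", row = c("em_p4", "em_p7", "em_p9"))
  self_labs <- spec_labels(sp, "theta", row = c("em_s11", "em_s16"))
  expect_length(intersect(parent_labs, self_labs), 0)
})

test_that("growth fit recovers factor means and matches sample wave means", {
  cfg <- sim_config(n_pairs = c(MZ = 500, DZss = 400, DZos = 400), seed = 21)
  sim <- simulate_dataset(cfg)
  long <- analysis_frame(sim$data, preprocess = FALSE)
  fit <- fit_sem(build_piecewise_lgc(), long, starts = 1)
  expect_true(fit$convergence$converged)
  fit <- with_robust_vcov(fit, long$family_id)
  al <- paste0("alpha_", FACTORS)
  truth <- cfg$factor_means + 0.5 * cfg$sex_effects$factor_shift_female
  se <- sqrt(diag(fit$vcov_robust)[al])
  expect_true(all(abs(fit$estimates[al] - truth) < 4 * se))
  # implied wave means reproduce the observed means within 3 SE
  mom <- implied_moments(fit$model$spec, fit$estimates)
  for (w in names(mom$mu)) {
    x <- long[[w]]
    expect_lt(abs(mom$mu[[w]] - mean(x, na.rm = TRUE)),
              3 * sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))) + 0.02)
  }
})

test_that("outcome regression recovers effects; standardization is exact", {
  cfg <- sim_config(n_pairs = c(MZ = 600, DZss = 500, DZos = 500), seed = 22)
  sim <- simulate_dataset(cfg)
  fit <- fit_outcome_model(sim$data, "audit_total", c("sex_num", "ses"),
                           starts = 1, iter_max = 3000)
  expect_true(fit$convergence$converged)
  std <- fit$standardized
  # the generating standardized effects: -0.08 on em_Ip, 0.30 on cd_Sa,
  # scaled by the AUDIT map (liability is rescaled by total_sd; ratios hold)
  b_cd <- std[std$predictor == "cd_Sa", ]
  expect_gt(b_cd$beta_std, 0.1)
  expect_lt(b_cd$p, 0.05)
  null_preds <- std[std$predictor %in% c("em_Ic", "cd_Ic"), ]
  expect_true(all(null_preds$p > 0.001))
  # standardization identity from the fitted moments
  mats <- spec_matrices(fit$model$spec, fit$estimates)
  Tm <- solve(diag(ncol(mats$beta)) - mats$beta)
  Psi_lat <- Tm %*% mats$psi %*% t(Tm)
  rownames(Psi_lat) <- colnames(Psi_lat) <- fit$model$spec$latent
  for (i in seq_len(nrow(std))) {
    ratio <- sqrt(Psi_lat[std$predictor[i], std$predictor[i]] /
                    Psi_lat["f_audit_total", "f_audit_total"])
    expect_equal(std$beta_std[i], std$estimate[i] * ratio, tolerance = 1e-8)
  }
  expect_error(
    fit_outcome_model(local({
      d <- as.data.frame(sim$data)
      d$audit_total_t1 <- NA_real_; d$audit_total_t2 <- NA_real_
      twin_dataset(d, validate = FALSE)
    }), "audit_total", "ses"), "entirely missing")
})

test_that("one-step and two-step outcome estimates agree when well separated", {
  cfg <- sim_config(
    n_pairs = c(MZ = 700, DZss = 600, DZos = 600), seed = 23,
    residual_vars = list(emotional = rep(0.5, 6), conduct = rep(0.5, 6)),
    missingness = list(intercepts = rep(-20, 7), coef_female = rep(0, 7),
                       coef_ses = rep(0, 7)))
  sim <- simulate_dataset(cfg)
  fit <- fit_outcome_model(sim$data, "audit_total", c("sex_num", "ses"),
                           starts = 1, iter_max = 3000)
  one_step <- fit$standardized
  scores <- compute_factor_scores(fit, sim$data, predictors = FACTORS,
                                  outcome = "audit_total",
                                  residualize_sex = FALSE)
  long <- data.frame(
    y = c(scores$audit_total_t1, scores$audit_total_t2),
    do.call(rbind, lapply(1:2, function(tw)
      setNames(scores[paste0(FACTORS, "_t", tw)], FACTORS))))
  two_step <- coef(lm(y ~ ., data = long))[FACTORS]
  # the strong, well-separated effect agrees within 20%; the weak effect
  # agrees in sign but shows the documented factor-score attenuation
  for (f in c("em_Ip", "cd_Sa")) {
    b1 <- one_step$estimate[one_step$predictor == f]
    expect_equal(sign(two_step[[f]]), sign(b1))
  }
  b_strong <- one_step$estimate[one_step$predictor == "cd_Sa"]
  expect_lt(abs(two_step[["cd_Sa"]] - b_strong) / abs(b_strong), 0.2)
})

test_that("pruning drops a true-zero covariance and keeps overall fit", {
  sp <- toy_growth_spec(psi_is = 0)      # generating covariance is zero
  m <- implied_moments(sp)
  Y <- draw_mvn(4000, m$mu, m$Sigma, seed = 10)
  colnames(Y) <- c("y1", "y2", "y3")
  d <- as.data.frame(Y)
  fit <- fit_sem(sp, d, starts = 1)
  pr <- prune_nonsignificant_covariances(fit, sp, d, starts = 1)
  expect_true("psi_S_I" %in% pr$dropped)
  expect_gte(pr$lr$p, 0.05)
  expect_lte(pr$fit$AIC, fit$AIC)
  # nothing nonsignificant: spec returned unchanged
  sp2 <- toy_growth_spec(psi_is = 0.25)
  m2 <- implied_moments(sp2)
  Y2 <- draw_mvn(6000, m2$mu, m2$Sigma, seed = 12)
  colnames(Y2) <- c("y1", "y2", "y3")
  fit2 <- fit_sem(sp2, as.data.frame(Y2), starts = 1)
  pr2 <- prune_nonsignificant_covariances(fit2, sp2, as.data.frame(Y2),
                                          starts = 1)
  expect_length(pr2$dropped, 0)
  expect_identical(pr2$fit$loglik, fit2$loglik)
})
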