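test_that("implied moments reproduce hand-computed structures", {
  # zero loadings: Sigma = Theta, mu = nu
  sp <- sem_spec(c("a", "b"), "f")
  sp <- sem_par(sp, "theta", c("a", "b"), c("a", "b"), value = c(2, 3))
  sp <- sem_par(sp, "nu", c("a", "b"), value = c(-1, 4))
  sp <- sem_par(sp, "psi", "f", "f", value = 1)
  m <- implied_moments(sp)
  expect_equal(unname(m$Sigma), diag(c(2, 3)))
  expect_equal(unname(m$mu), c(-1, 4))

  # single factor, unit loadings: compound symmetry psi*J + theta*I
  sp <- sem_spec(paste0("y", 1:4), "f")
  sp <- sem_par(sp, "lambda", paste0("y", 1:4), "f", value = 1)
  sp <- sem_par(sp, "psi", "f", "f", value = 0.7)
  sp <- sem_par(sp, "theta", paste0("y", 1:4), paste0("y", 1:4), value = 0.3)
  m <- implied_moments(sp)
  expect_equal(unname(m$Sigma), 0.7 * matrix(1, 4, 4) + 0.3 * diag(4))

  # 3-wave growth: entry-wise matrix-product oracle
  sp <- toy_growth_spec()
  m <- implied_moments(sp)
  L <- cbind(1, c(0, 1, 2))
  P <- matrix(c(1, 0.2, 0.2, 0.1), 2)
  expect_equal(unname(m$Sigma), L %*% P %*% t(L) + diag(0.5, 3),
               tolerance = 1e-12)
  expect_equal(unname(m$mu), drop(L %*% c(1, 0.3)))
})

test_that("FIML equals brute-force marginal normal densities", {
  expect_equal(fiml_loglik(0, matrix(1), matrix(0)), -0.5 * log(2 * pi),
               tolerance = 1e-9)
  expect_equal(round(fiml_loglik(0, matrix(1), matrix(0)), 6), -0.918939)

  m <- implied_moments(toy_growth_spec())
  Y <- draw_mvn(40, m$mu, m$Sigma, seed = 5)
  # complete data: direct density oracle
  direct <- sum(mvtnorm::dmvnorm(Y, m$mu, m$Sigma, log = TRUE))
  expect_lt(abs(fiml_loglik(m$mu, m$Sigma, Y) - direct), 1e-10 * abs(direct))
  # bivariate margin: dropping the second value gives the first margin
  r <- c(0.3, NA, 1.2)
  expect_equal(fiml_loglik(m$mu, m$Sigma, matrix(r, 1)),
               mvtnorm::dmvnorm(r[c(1, 3)], m$mu[c(1, 3)],
                                m$Sigma[c(1, 3), c(1, 3)], log = TRUE))
  # all-missing rows contribute zero; row order is irrelevant
  Ym <- Y; Ym[sample(120, 30)] <- NA
  base <- fiml_loglik(m$mu, m$Sigma, Ym)
  expect_equal(fiml_loglik(m$mu, m$Sigma, rbind(Ym, NA)), base)
  expect_equal(fiml_loglik(m$mu, m$Sigma, Ym[rev(seq_len(40)), ]), base,
               tolerance = 1e-12)
  # non-PD submatrix is an infeasible point, not an exception
  expect_identical(fiml_loglik(c(0, 0), matrix(c(1, 2, 2, 1), 2),
                               matrix(c(0, 0), 1)), -Inf)
})

test_that("the saturated fit attains the closed-form maximum", {
  m <- implied_moments(toy_growth_spec())
  Y <- draw_mvn(300, m$mu, m$Sigma, seed = 6)
  colnames(Y) <- c("y1", "y2", "y3")
  f <- fit_sem(saturated_spec(colnames(Y), as.data.frame(Y)),
               as.data.frame(Y), starts = 1, se = FALSE)
  target <- saturated_loglik(Y)
  expect_true(f$convergence$converged)
  expect_lt(abs(f$loglik - target) / abs(target), 1e-6)
})

test_that("fitting recovers a growth model and is a fixed point on refit", {
  sp <- toy_growth_spec()
  m <- implied_moments(sp)
  Y <- draw_mvn(5000, m$mu, m$Sigma, seed = 8)
  colnames(Y) <- c("y1", "y2", "y3")
  Y[sample(length(Y), round(0.3 * length(Y)))] <- NA   # 30% MCAR
  f <- fit_sem(sp, as.data.frame(Y), starts = 1)
  expect_true(f$convergence$converged)
  truth <- c(psi_I_I = 1, psi_S_S = 0.1, psi_S_I = 0.2, theta_y1_y1 = 0.5,
             theta_y2_y2 = 0.5, theta_y3_y3 = 0.5, alpha_I = 1, alpha_S = 0.3)
  se <- sqrt(diag(f$vcov))[names(truth)]
  expect_true(all(abs(f$estimates[names(truth)] - truth) < 4 * se))
  # AIC identity holds exactly
  expect_identical(f$AIC, -2 * f$loglik + 2 * f$k)
  # refit from the solution: likelihood reproduced to 1e-8
  f2 <- fit_sem(sp, as.data.frame(Y), starts = 1, start = f$estimates,
                se = FALSE)
  expect_lt(abs(f2$loglik - f$loglik), 1e-8 * max(1, abs(f$loglik)))
})

test_that("errors: missing columns, empty variables, bad groups", {
  sp <- toy_growth_spec()
  expect_error(fit_sem(sp, data.frame(y1 = 1, y2 = 2)), "lacks columns")
  d <- data.frame(y1 = c(1, 2), y2 = c(2, 1), y3 = NA_real_)
  expect_error(fit_sem(sp, d), "no observed values for: y3")
})

test_that("cluster-robust covariance matches closed forms", {
  # intercept-only model, singleton clusters: robust SE ~ sd/sqrt(n)
  sp <- sem_spec("x", "fx")
  sp <- sem_par(sp, "lambda", "x", "fx", value = 1)
  sp <- sem_par(sp, "psi", "fx", "fx", value = 1, free = TRUE, lower = 1e-8)
  sp <- sem_par(sp, "alpha", "fx", value = 0, free = TRUE)
  set.seed(21)
  x <- rnorm(600, 2, 1.4)
  f <- fit_sem(sp, data.frame(x = x), starts = 1)
  V <- cluster_robust_vcov(f, seq_along(x))
  sd_ml <- sqrt(mean((x - mean(x))^2))
  expect_equal(sqrt(V["alpha_fx", "alpha_fx"]), sd_ml / sqrt(600),
               tolerance = 0.02)
  # sandwich closed form for the mean: sum((x - xbar)^2)/ (n^2 * sigma^4) ...
  # reduces to empirical variance / n; compare to naive as well
  expect_equal(V["alpha_fx", "alpha_fx"], f$vcov["alpha_fx", "alpha_fx"],
               tolerance = 0.05)
  # duplicating every row into 2-row clusters doubles the sandwich variance
  x2 <- rep(x, each = 2)
  f2 <- fit_sem(sp, data.frame(x = x2), starts = 1)
  Vdup <- cluster_robust_vcov(f2, rep(seq_along(x), each = 2))
  Vsing <- cluster_robust_vcov(f2, seq_along(x2))
  expect_equal(Vdup["alpha_fx", "alpha_fx"] /
                 Vsing["alpha_fx", "alpha_fx"], 2, tolerance = 0.01)
  expect_warning(cluster_robust_vcov(f, rep(1, 600)), "fewer clusters")
})

test_that("likelihood-ratio and Wald tests follow their closed forms", {
  sp <- toy_growth_spec()
  m <- implied_moments(sp)
  Y <- draw_mvn(400, m$mu, m$Sigma, seed = 9)
  colnames(Y) <- c("y1", "y2", "y3")
  d <- as.data.frame(Y)
  f_full <- fit_sem(sp, d, starts = 1, se = FALSE)
  expect_equal(lr_test(f_full, f_full), list(chisq = 0, df = 0, p = 1))
  # restricted: fix the intercept-slope covariance to zero
  spr <- sp
  hit <- !is.na(spr$params$label) & spr$params$label == "psi_S_I"
  spr$params$free[hit] <- FALSE; spr$params$value[hit] <- 0
  spr$params$label[hit] <- NA
  f_res <- fit_sem(spr, d, starts = 1, se = FALSE)
  lr <- lr_test(f_res, f_full)
  expect_equal(lr$df, 1)
  expect_gte(lr$chisq, 0)
  # non-nested detection: restricted frees a location the "full" fixes
  expect_error(lr_test(f_full, f_res), "not nested|more free parameters")

  expect_equal(wald_equality(0.4, 0.1, 0.4, 0.1)$W, 0)
  expect_equal(wald_equality(0.4, 0.1, 0.4, 0.1)$p, 1)
  expect_equal(wald_equality(0.5, 0.1, 0, 0.1)$W, 12.5)
  expect_error(wald_equality(1, 0.1, 0, 0.1, cov12 = 0.02), "nonpositive")
})

test_that("Wald and LR agree asymptotically on an equality constraint", {
  # two groups sharing a regression slope; test equality both ways
  mk_spec <- function(equal) {
    sp <- sem_spec(c("x", "y"), c("fx", "fy"), groups = c("g1", "g2"))
    sp <- sem_par(sp, "lambda", c("x", "y"), c("fx", "fy"), value = 1)
    sp <- sem_par(sp, "psi", "fx", "fx", value = 1, free = TRUE, lower = 1e-8)
    sp <- sem_par(sp, "psi", "fy", "fy", value = 1, free = TRUE, lower = 1e-8)
    sp <- sem_par(sp, "alpha", c("fx", "fy"), value = 0, free = TRUE)
    if (equal) {
      sp <- sem_par(sp, "beta", "fy", "fx", value = 0.2, free = TRUE,
                    label = "b")
    } else {
      sp <- sem_par(sp, "beta", "fy", "fx", value = 0.2, free = TRUE)
    }
    sp
  }
  set.seed(33)
  n <- 5000
  d <- do.call(rbind, lapply(c("g1", "g2"), function(g) {
    x <- rnorm(n)
    data.frame(g = g, x = x, y = 0.25 * x + rnorm(n))
  }))
  f_free <- fit_sem(mk_spec(FALSE), d, group = "g", starts = 1)
  f_eq <- fit_sem(mk_spec(TRUE), d, group = "g", starts = 1, se = FALSE)
  lr <- lr_test(f_eq, f_free)
  V <- f_free$vcov
  w <- wald_equality(f_free$estimates[["beta_fy_fx.g1"]],
                     sqrt(V["beta_fy_fx.g1", "beta_fy_fx.g1"]),
                     f_free$estimates[["beta_fy_fx.g2"]],
                     sqrt(V["beta_fy_fx.g2", "beta_fy_fx.g2"]),
                     V["beta_fy_fx.g1", "beta_fy_fx.g2"])
  expect_lt(abs(w$p - lr$p), 0.02)
})

test_that("modification search is empty when the constrained model fits", {
  sp_eq <- sem_spec(c("x"), c("fx"), groups = c("g1", "g2"))
  sp_eq <- sem_par(sp_eq, "lambda", "x", "fx", value = 1)
  sp_eq <- sem_par(sp_eq, "psi", "fx", "fx", value = 1, free = TRUE,
                   lower = 1e-8, label = "v")
  sp_eq <- sem_par(sp_eq, "alpha", "fx", value = 0, free = TRUE, label = "mu")
  sp_free <- free_across_groups(sp_eq, c("v", "mu"))
  set.seed(4)
  d <- data.frame(g = rep(c("g1", "g2"), each = 400), x = rnorm(800))
  ref <- fit_sem(sp_free, d, group = "g", starts = 1, se = FALSE)
  ms <- modification_search(sp_eq, d, "g", c("v", "mu"), ref)
  expect_equal(nrow(ms$log), 0)
  expect_gte(ms$p, 0.05)
})

test_that("fits export to JSON and CSV", {
  m <- implied_moments(toy_growth_spec())
  Y <- draw_mvn(150, m$mu, m$Sigma, seed = 44)
  colnames(Y) <- c("y1", "y2", "y3")
  f <- fit_sem(toy_growth_spec(), as.data.frame(Y), starts = 1)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  tab <- export_fit(f, jp, cp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$AIC, f$AIC, tolerance = 1e-12)
  expect_equal(nrow(utils::read.csv(cp)), f$k)
  expect_equal(tab$estimate, unname(f$estimates))
})

test_that("specs serialize to YAML and back without loss", {
  sp <- toy_growth_spec()
  path <- tempfile(fileext = ".yaml")
  spec_to_yaml(sp, path)
  sp2 <- spec_from_yaml(path)
  expect_equal(sp2$observed, sp$observed)
  expect_equal(sp2$latent, sp$latent)
  expect_equal(sp2$params$value, sp$params$value)
  expect_equal(sp2$params$label, sp$params$label)
  m1 <- implied_moments(sp); m2 <- implied_moments(sp2)
  expect_equal(m1$Sigma, m2$Sigma)
})
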