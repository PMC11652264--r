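test_that("ACE component draws respect the twin correlation structure", {
  A <- matrix(c(0.5, 0.1, 0.1, 0.4), 2)
  C <- diag(c(0.3, 0.2)); E <- diag(c(0.2, 0.4))
  mz <- simulate_ace_components(500, "MZ", A, C, E, seed = 1)
  expect_identical(mz$A1, mz$A2)          # MZ genetic components identical
  expect_identical(mz$C1, mz$C2)
  expect_false(identical(mz$E1, mz$E2))

  # univariate DZ: cross-twin covariance = 0.5 A + C = 0.55
  n <- 20000
  dz <- simulate_ace_components(n, "DZss", matrix(0.5), matrix(0.3),
                                matrix(0.2), seed = 2)
  p1 <- dz$A1 + dz$C1 + dz$E1
  p2 <- dz$A2 + dz$C2 + dz$E2
  cc <- cov(p1, p2)[1, 1]
  se <- sqrt((1 * 1 + 0.55^2) / n)        # var(P) = 1 by construction
  expect_lt(abs(cc - 0.55), 3 * se)

  # E-only: within-pair phenotypic correlation vanishes
  eo <- simulate_ace_components(n, "MZ", matrix(0), matrix(0), matrix(1),
                                seed = 3)
  expect_lt(abs(cor(eo$E1, eo$E2)[1, 1]), 3 / sqrt(n))

  expect_error(
    simulate_ace_components(10, "MZ", matrix(c(1, 2, 2, 1), 2),
                            diag(2), diag(2), seed = 1),
    "positive semi-definite")
})

test_that("simulation is bit-identical under the same config and seed", {
  cfg <- sim_config(n_pairs = c(MZ = 40, DZss = 30, DZos = 30), seed = 99)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$data, s2$data)
  f1 <- tempfile(); f2 <- tempfile()
  write_twin_table(s1$data, f1); write_twin_table(s2$data, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_dataset(sim_config(n_pairs = c(MZ = 40, DZss = 30, DZos = 30),
                                    seed = 100))
  expect_false(identical(s1$data$em_p4_t1, s3$data$em_p4_t1))
})

test_that("empirical moments of a large cohort match the closed-form oracle", {
  cfg <- sim_config(n_pairs = c(MZ = 22000, DZss = 18000, DZos = 10000),
                    seed = 31,
                    missingness = list(intercepts = rep(-20, 7),
                                       coef_female = rep(0, 7),
                                       coef_ses = rep(0, 7)))
  sim <- simulate_dataset(cfg)
  io <- implied_observed_moments(cfg)
  long <- stack_twins(as.data.frame(sim$data))
  for (sx in c("male", "female")) {
    Ys <- as.matrix(long[long$sex == sx, io$vars])
    n <- nrow(Ys)
    dm <- abs(colMeans(Ys) - io$mu[[sx]]) / (sqrt(diag(io$within)) / sqrt(n))
    expect_lt(max(dm), 4)
  }
  # within-twin covariance, pooled across sexes (covariance is sex-invariant)
  Y <- as.matrix(long[, io$vars])
  mu_by_sex <- io$mu[ifelse(long$sex == "female", "female", "male")]
  Yc <- Y - do.call(rbind, mu_by_sex)
  S <- crossprod(Yc) / nrow(Yc)
  n <- nrow(Yc)
  for (i in seq_along(io$vars)) for (j in i:length(io$vars)) {
    expect_lt(abs(S[i, j] - io$within[i, j]),
              4 * cov_se(io$within, i, j, n) + 1e-12)
  }
  # cross-twin blocks per zygosity (same-sex pairs; centered per sex)
  d <- as.data.frame(sim$data)
  for (zyg in c("MZ", "DZss")) {
    rows <- d$zyg == zyg
    ctr <- function(tw) {
      M <- as.matrix(d[rows, paste0(io$vars, "_t", tw)])
      mu <- do.call(rbind, io$mu[ifelse(d$sex_t1[rows] == "female",
                                        "female", "male")])
      M - mu
    }
    X <- crossprod(ctr(1), ctr(2)) / sum(rows)
    target <- io$cross[[if (zyg == "MZ") "MZ" else "DZ"]]
    npair <- sum(rows)
    for (i in seq_along(io$vars)) for (j in seq_along(io$vars)) {
      se <- sqrt((io$within[i, i] * io$within[j, j] + target[i, j]^2) / npair)
      expect_lt(abs(X[i, j] - target[i, j]), 4 * se + 1e-12)
    }
  }
})

test_that("missingness is MAR: independent of the true score given sex and SES", {
  cfg <- sim_config(n_pairs = c(MZ = 8000, DZss = 4000, DZos = 4000), seed = 17)
  sim <- simulate_dataset(cfg)
  obs <- stack_twins(as.data.frame(sim$data))
  tru <- stack_twins(as.data.frame(sim$truth$complete))
  for (col in c("em_s16", "audit_total")) {
    mis <- as.numeric(is.na(obs[[col]]))
    g <- glm(mis ~ tru[[col]] + factor(tru$sex) + tru$ses, family = binomial)
    z <- coef(summary(g))[2, "z value"]
    expect_lt(abs(z), 4)
    # and SES genuinely predicts missingness
    z_ses <- coef(summary(g))["tru$ses", "z value"]
    expect_lt(z_ses, -4)
  }
})

test_that("degenerate configs behave as advertised", {
  # no residual noise, A-only factors: waves are deterministic in the factors
  cfg <- sim_config(
    n_pairs = c(MZ = 50, DZss = 10, DZos = 10), seed = 3,
    ace_shares = c(a = 1, c = 0, e = 0),
    residual_vars = list(emotional = rep(1e-12, 6), conduct = rep(1e-12, 6)),
    missingness = list(intercepts = rep(-20, 7), coef_female = rep(0, 7),
                       coef_ses = rep(0, 7)))
  sim <- simulate_dataset(cfg)
  expect_false(anyNA(as.data.frame(sim$data)[, -(1:2)]))
  eta <- sim$truth$latent$MZ$eta1
  Lam <- piecewise_loadings()
  waves <- as.matrix(as.data.frame(sim$data)[sim$data$zyg == "MZ",
                                             paste0(rownames(Lam), "_t1")])
  expect_lt(max(abs(waves - eta %*% t(Lam))), 1e-4)
  # outcome model with neither direct paths nor correlated ACE errors out
  cfg2 <- sim_config(n_pairs = c(MZ = 5, DZss = 5, DZos = 5), seed = 1,
                     outcome = list(type = "direct",
                                    beta_std = rep(0, 8),
                                    ace_cross = list(A = rep(0, 8),
                                                     C = rep(0, 8),
                                                     E = rep(0, 8)),
                                    resid_shares = c(a = .4, c = .1, e = .5)))
  expect_error(simulate_dataset(cfg2), "outcome model empty")
})

test_that("censored rounding clips onto the reporting scales", {
  cfg <- sim_config(n_pairs = c(MZ = 200, DZss = 50, DZos = 50), seed = 8)
  sim <- simulate_dataset(cfg)
  r <- as.data.frame(round_to_scale(sim$data))
  expect_true(all(r$em_p4_t1 >= 0 & r$em_p4_t1 <= 10, na.rm = TRUE))
  expect_true(all(r$audit_total_t1 >= 0 & r$audit_total_t1 <= 40, na.rm = TRUE))
})
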