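test_that("implied pair covariance matches closed forms", {
  stu <- ace_structure("P", "y", "direct",
                       values = list(L_A = sqrt(0.5), L_C = sqrt(0.3),
                                     L_E = sqrt(0.2), u = c(1, 0, 1) * 0.7))
  S_mz <- implied_pair_cov(stu, "MZ")
  S_dz <- implied_pair_cov(stu, "DZ")
  expect_equal(S_mz["P_t1", "P_t1"], 1)
  expect_equal(S_mz["P_t1", "P_t2"], 0.8)   # a2 + c2
  expect_equal(S_dz["P_t1", "P_t2"], 0.55)  # 0.5 a2 + c2

  # an E-only direct path never crosses twins
  st_e <- ace_structure("P", "y", "direct",
                        values = list(L_A = matrix(0), L_C = matrix(0),
                                      L_E = matrix(1), b = 0.5,
                                      u = c(0.1, 0.1, 0.5)))
  expect_equal(implied_pair_cov(st_e, "MZ")["P_t1", "y_t2"], 0)
  expect_equal(implied_pair_cov(st_e, "DZ")["P_t1", "y_t2"], 0)
})

test_that("pair covariance equals the path-tracing oracle for k <= 3", {
  for (k in 1:3) for (s in 1:3) {
    st <- random_ace_structure(k, seed = 100 * k + s)
    for (zyg in c("MZ", "DZ")) {
      expect_lt(max(abs(implied_pair_cov(st, zyg) - trace_pair_cov(st, zyg))),
                1e-10)
    }
  }
})

test_that("MZ-DZ cross-twin contrast equals half the A contribution", {
  for (s in 1:5) {
    st <- random_ace_structure(2, seed = 400 + s)
    mz <- implied_pair_cov(st, "MZ")[1:3, 4:6]
    dz <- implied_pair_cov(st, "DZ")[1:3, 4:6]
    # pure-A twin: zero out C and E to isolate the A-implied cross block
    stA <- st
    stA$values$L_C[] <- 0; stA$values$L_E[] <- 0
    stA$values$w_C[] <- 0; stA$values$w_E[] <- 0
    stA$values$u[2:3] <- 0
    a_cross <- implied_pair_cov(stA, "MZ")[1:3, 4:6]
    expect_lt(max(abs((mz - dz) - 0.5 * a_cross)), 1e-12)
    # where the A contribution is positive, MZ dominates DZ
    pos <- a_cross > 0
    expect_true(all(mz[pos] >= dz[pos]))
  }
})

test_that("regression scores follow the formula and its noiseless limit", {
  # hand-computed 3-variable toy: score = alpha + Psi L' Sigma^-1 (y - mu)
  mats <- list(lambda = cbind(F = c(1, 0.8, 0.6)), beta = matrix(0, 1, 1),
               psi = matrix(2), theta = diag(c(0.5, 0.4, 0.3)),
               alpha = matrix(1.5), nu = matrix(0, 3, 1))
  rownames(mats$lambda) <- paste0("y", 1:3)
  y <- c(2.3, 1.4, 0.9)
  L <- mats$lambda
  Sg <- L %*% mats$psi %*% t(L) + mats$theta
  mu <- drop(L %*% mats$alpha)
  by_hand <- 1.5 + drop(mats$psi %*% t(L) %*% solve(Sg) %*% (y - mu))
  sc <- twinpaths:::regression_scores(mats, matrix(y, 1))
  expect_equal(unname(drop(sc)), by_hand, tolerance = 1e-12)
  # missing second indicator: marginal formula
  o <- c(1, 3)
  by_hand2 <- 1.5 + drop(mats$psi %*% t(L[o, , drop = FALSE]) %*%
                           solve(Sg[o, o]) %*% (y[o] - mu[o]))
  sc2 <- twinpaths:::regression_scores(mats, matrix(c(y[1], NA, y[3]), 1))
  expect_equal(unname(drop(sc2)), by_hand2, tolerance = 1e-12)
  # noiseless limit: theta -> 0 reproduces the factor exactly
  mats0 <- mats; mats0$theta <- diag(1e-10, 3)
  eta <- 1.5 + sqrt(2) * 0.7
  y0 <- drop(L %*% eta)
  expect_equal(unname(drop(twinpaths:::regression_scores(mats0, matrix(y0, 1)))),
               eta, tolerance = 1e-5)
})

test_that("factor scores track the true factors and shed sex variance", {
  cfg <- sim_config(n_pairs = c(MZ = 800, DZss = 700, DZos = 700), seed = 41)
  sim <- simulate_dataset(cfg)
  long <- analysis_frame(sim$data, preprocess = FALSE)
  fit <- fit_sem(build_piecewise_lgc(), long, starts = 1)
  sc <- compute_factor_scores(fit, sim$data, predictors = c("em_Ip", "cd_Sa"),
                              outcome = "audit_total", preprocess = TRUE)
  # correlation with the generating factors (MZ block, twin 1); thresholds
  # frozen at the first computed reliabilities of the default world:
  # intercept scores ~0.75-0.80, slope scores ~0.39-0.46
  tru <- sim$truth$latent$MZ$eta1
  sMZ <- sc[startsWith(sc$family_id, "MZ"), ]
  expect_gt(cor(sMZ$em_Ip_t1, tru[, "em_Ip"], use = "complete.obs"), 0.7)
  expect_gt(cor(sMZ$cd_Sa_t1, tru[, "cd_Sa"], use = "complete.obs"), 0.35)
  # sex residualization: residual correlation with sex below 1e-10
  sx <- c(as.numeric(sc$sex_t1 == "female"), as.numeric(sc$sex_t2 == "female"))
  for (v in c("em_Ip", "cd_Sa", "audit_total")) {
    x <- c(sc[[paste0(v, "_t1")]], sc[[paste0(v, "_t2")]])
    ok <- !is.na(x)
    expect_lt(abs(cov(x[ok], sx[ok])), 1e-10)
  }
  # a twin with no indicators for a trait gets NA scores for that trait
  d2 <- as.data.frame(sim$data)
  d2[1, paste0(c("em_p4", "em_p7", "em_p9", "em_s9", "em_s11", "em_s16"),
               "_t1")] <- NA
  sc2 <- compute_factor_scores(fit, twin_dataset(d2, validate = FALSE),
                               predictors = c("em_Ip", "cd_Sa"),
                               outcome = "audit_total",
                               residualize_sex = FALSE)
  expect_true(is.na(sc2$em_Ip_t1[sc2$family_id == d2$family_id[1]]))
  expect_false(is.na(sc2$cd_Sa_t1[sc2$family_id == d2$family_id[1]]))
})

test_that("fit_ace recovers a direct-path structure and flags boundaries", {
  truth <- ace_structure(
    c("em_Ip", "cd_Sa"), "y", c("direct", "direct"),
    values = list(L_A = matrix(c(0.63, 0.2, 0, 0.6), 2),
                  L_C = diag(c(0.45, 0.45)), L_E = diag(c(0.63, 0.66)),
                  b = c(-0.08, 0.30), u = c(0.62, 0.31, 0.70)))
  tab <- simulate_ace_pairs(truth, c(MZ = 4000, DZ = 4000), seed = 51)
  template <- ace_structure(c("em_Ip", "cd_Sa"), "y", c("direct", "direct"))
  f <- fit_ace(template, tab)
  expect_true(f$convergence$converged)
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(f$estimates[["b_em_Ip"]] + 0.08), 3 * se[["b_em_Ip"]])
  expect_lt(abs(f$estimates[["b_cd_Sa"]] - 0.30), 3 * se[["b_cd_Sa"]])
  # standardized shares sum to one
  expect_equal(unname(rowSums(f$ace$shares)), rep(1, 3), tolerance = 1e-8)
  # missing co-twin rows are handled through the FIML patterns
  tab2 <- tab
  tab2[seq(1, 400), c("em_Ip_t2", "cd_Sa_t2", "y_t2")] <- NA
  f2 <- fit_ace(template, tab2, se = FALSE)
  expect_true(f2$convergence$converged)

  # A = 0 world: genetic parameters pile at the boundary
  nul <- ace_structure("P", "y", "direct",
                       values = list(L_A = matrix(0), L_C = matrix(sqrt(0.5)),
                                     L_E = matrix(sqrt(0.5)), b = 0.3,
                                     u = c(0, sqrt(0.3), sqrt(0.6))))
  tabn <- simulate_ace_pairs(nul, c(MZ = 3000, DZ = 3000), seed = 52)
  fn <- fit_ace(ace_structure("P", "y", "direct"), tabn, se = FALSE)
  expect_lt(fn$ace$shares["P", "a2"], 0.05)   # A share piles near zero
  # a saturated Cholesky reproduces the sample MZ covariance closely
  chol2 <- ace_structure(c("em_Ip", "cd_Sa"), "y", "correlated")
  fc <- fit_ace(chol2, tab, se = FALSE)
  Smz_hat <- fc$model$moments(fc$estimates)$MZ$Sigma
  mz_rows <- tab$zyg == "MZ"
  Smz_emp <- cov(tab[mz_rows, -1])
  n <- sum(mz_rows)
  for (i in 1:6) for (j in i:6) {
    expect_lt(abs(Smz_hat[i, j] - Smz_emp[i, j]),
              4 * cov_se(Smz_emp, i, j, n) + 0.01)
  }
})

test_that("the direct model is nested in the Cholesky and AIC self-delta is 0", {
  st_d <- ace_structure(c("P1", "P2"), "y", "direct",
                        values = list(b = c(0.2, -0.1)))
  tab <- simulate_ace_pairs(st_d, c(MZ = 1500, DZ = 1500), seed = 61)
  f_dir <- fit_ace(ace_structure(c("P1", "P2"), "y", "direct"), tab,
                   se = FALSE)
  f_cho <- fit_ace(ace_structure(c("P1", "P2"), "y", "correlated"), tab,
                   se = FALSE)
  expect_lte(f_dir$loglik, f_cho$loglik + 1e-6)
  search <- structure_search(tab, c("P1", "P2"), "y")
  expect_equal(search$table$dAIC[search$table$name == "chol"], 0)
  expect_true(all(c("chol", "direct") %in% search$table$name))
})

test_that("identification is checked before fitting", {
  st <- ace_structure("P", "y", "correlated")
  md <- twinpaths:::ace_model(st)
  md$groups <- "MZ"   # single zygosity: A and C are confounded
  mom1 <- md$moments
  md$moments <- function(theta) mom1(theta)["MZ"]
  expect_error(twinpaths:::check_identified(md), "not identified")
})

test_that("sex differences in direct paths: empty report and detection", {
  st_c <- ace_structure("P", "y", "correlated")
  expect_equal(sex_difference_direct_paths(st_c, NULL)$note, "no direct paths")

  # five-group simulation with male/female direct paths
  sim5 <- function(b_m, b_f, seed) {
    vals <- function(b) list(L_A = matrix(0.65), L_C = matrix(0.45),
                             L_E = matrix(0.6), b = b,
                             u = c(0.6, 0.3, 0.65))
    st_m <- ace_structure("P", "y", "direct", values = vals(b_m))
    st_f <- ace_structure("P", "y", "direct", values = vals(b_f))
    parts <- list(
      MZ_m = simulate_ace_pairs(st_m, c(MZ = 1000), seed),
      MZ_f = simulate_ace_pairs(st_f, c(MZ = 1000), seed + 1),
      DZ_m = simulate_ace_pairs(st_m, c(DZ = 1000), seed + 2),
      DZ_f = simulate_ace_pairs(st_f, c(DZ = 1000), seed + 3))
    sexes <- c(MZ_m = "male", MZ_f = "female", DZ_m = "male", DZ_f = "female")
    out <- do.call(rbind, lapply(names(parts), function(nm) {
      d <- parts[[nm]]
      d$sex_t1 <- sexes[[nm]]; d$sex_t2 <- sexes[[nm]]
      d
    }))
    # opposite-sex DZ pairs: twin 1 male with b_m, twin 2 female with b_f
    os <- with_local_seed <- NULL
    st_os <- st_m
    Sos <- twinpaths:::ace_blocks_pair(st_m$values, 0.5, b1 = b_m, b2 = b_f)
    Sfull <- rbind(cbind(Sos$within1, Sos$cross),
                   cbind(t(Sos$cross), Sos$within2))
    set.seed(seed + 4)
    Y <- draw_mvn(1000, rep(0, 4), Sfull, seed + 4)
    colnames(Y) <- c("P_t1", "y_t1", "P_t2", "y_t2")
    osd <- data.frame(zyg = "DZos", Y, sex_t1 = "male", sex_t2 = "female",
                      stringsAsFactors = FALSE)
    rbind(out, osd)
  }
  st_fit <- ace_structure("P", "y", "direct")
  rep_diff <- sex_difference_direct_paths(st_fit, sim5(-0.35, 0.1, 71))
  expect_lt(rep_diff$lr$p, 0.05)
  expect_equal(rep_diff$lr$df, 1)
  expect_lt(rep_diff$paths$b_male, rep_diff$paths$b_female)
  rep_null <- sex_difference_direct_paths(st_fit, sim5(0.2, 0.2, 72),
                                          se = FALSE)
  expect_gt(rep_null$lr$p, 0.01)
})
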