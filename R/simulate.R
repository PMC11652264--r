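# Synthetic MZ/DZ twin cohorts with the statistical structure the analysis
# assumes: ACE-decomposed piecewise growth factors, a rater switch at age 9,
# an early-adult alcohol outcome generated under direct phenotypic paths
# and/or correlated ACE influences, and MAR missingness driven by sex and a
# family SES covariate.

FACTORS <- c("em_Ic", "em_Sc", "em_Ip", "em_Sa",
             "cd_Ic", "cd_Sc", "cd_Ip", "cd_Sa")

default_factor_corr <- function() {
  within <- matrix(c(
    1.00, -0.25, 0.45, 0.10,
    -0.25, 1.00, 0.20, 0.10,
    0.45, 0.20, 1.00, -0.20,
    0.10, 0.10, -0.20, 1.00), 4, 4)
  cross <- matrix(0.15, 4, 4)
  diag(cross) <- c(0.40, 0.25, 0.40, 0.30)  # same-factor cross-trait overlap
  R <- rbind(cbind(within, cross), cbind(t(cross), within))
  dimnames(R) <- list(FACTORS, FACTORS)
  R
}

#' Ground-truth configuration for the twin-cohort generator
#'
#' Returns the full parameterization of the simulated world; every argument
#' overrides one piece. Defaults emulate the structure and magnitudes of a
#' large UK twin cohort followed from age 4 to 22: SDQ-scale problem scores
#' (factor means and variances on the 0-10 metric), heavy missingness at the
#' age-9 and age-22 waves, ACE variance shares of 0.4/0.2/0.4 on the growth
#' factors, a unit-variance age-residualized alcohol liability with ACE
#' shares 0.4/0.1/0.5, and a direct-path outcome model with a standardized
#' effect of -0.08 from the preadolescent emotional intercept and 0.30 from
#' the adolescent conduct slope.
#'
#' @param n_pairs Named integer vector: pairs per zygosity group
#'   (`MZ`, `DZss`, `DZos`).
#' @param factor_means Length-8 vector of growth-factor means (order
#'   `em_Ic, em_Sc, em_Ip, em_Sa, cd_Ic, cd_Sc, cd_Ip, cd_Sa`).
#' @param factor_sds Length-8 vector of factor standard deviations.
#' @param factor_corr 8 x 8 factor correlation matrix.
#' @param ace_shares Length-3 proportions (a2, c2, e2) applied to the factor
#'   covariance; summing to 1.
#' @param wave_ages Ages of the six problem waves.
#' @param anchors Segment anchor ages (childhood, preadolescence knot).
#' @param residual_vars List with `emotional` and `conduct` length-6 wave
#'   residual variances.
#' @param residual_corr_same_age Cross-trait residual correlation at each wave.
#' @param residual_corr_parent_self Parent-self residual correlation at age 9
#'   (per trait).
#' @param outcome Outcome-model description: `type` ("direct", "correlated"
#'   or "hybrid"), `beta_std` (length-8 standardized direct effects),
#'   `ace_cross` (length-8 vectors `A`, `C`, `E` of covariances between the
#'   outcome's ACE components and the factor ACE components) and
#'   `resid_shares` (ACE split of the outcome's unique variance).
#' @param sex_effects List: `factor_shift_female` (mean shifts added for
#'   females), `outcome_shift_female`, and optional `beta_std_male` /
#'   `beta_std_female` overriding `beta_std` per sex.
#' @param missingness List per-wave logistic models for the missing-data
#'   indicator: `intercepts` (length 7: six problem waves then alcohol),
#'   `coef_female`, `coef_ses`.
#' @param audit_scale Linear map from the unit liability to the three AUDIT
#'   columns (`total_mean`, `total_sd`, `age_slope`, ...).
#' @param seed Integer seed.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_pairs = c(MZ = 3400, DZss = 3300, DZos = 3300),
                       factor_means = c(2.05, -0.05, 3.20, -0.07,
                                        2.10, -0.16, 2.20, -0.08),
                       factor_sds = c(1.30, 0.18, 1.60, 0.20,
                                      1.10, 0.16, 1.30, 0.16),
                       factor_corr = default_factor_corr(),
                       ace_shares = c(a = 0.4, c = 0.2, e = 0.4),
                       wave_ages = c(4, 7, 9, 9, 11, 16),
                       anchors = c(4, 9),
                       residual_vars = list(
                         emotional = c(1.5, 1.4, 1.3, 2.0, 1.8, 1.6),
                         conduct = c(1.2, 1.1, 1.0, 1.5, 1.3, 1.1)),
                       residual_corr_same_age = 0.25,
                       residual_corr_parent_self = 0.30,
                       outcome = list(
                         type = "direct",
                         beta_std = c(em_Ic = 0, em_Sc = 0, em_Ip = -0.08,
                                      em_Sa = 0, cd_Ic = 0, cd_Sc = 0,
                                      cd_Ip = 0, cd_Sa = 0.30),
                         ace_cross = list(A = rep(0, 8), C = rep(0, 8),
                                          E = rep(0, 8)),
                         resid_shares = c(a = 0.4, c = 0.1, e = 0.5)),
                       sex_effects = list(
                         factor_shift_female = c(0.15, 0.01, 0.30, 0.02,
                                                 -0.15, -0.02, -0.25, -0.01),
                         outcome_shift_female = -0.20,
                         beta_std_male = NULL, beta_std_female = NULL),
                       missingness = list(
                         intercepts = stats::qlogis(
                           c(0.10, 0.12, 0.55, 0.30, 0.40, 0.50)[c(1, 2, 3, 3, 4, 5, 6)]),
                         coef_female = c(0, 0, 0, 0, 0, 0, -0.3),
                         coef_ses = rep(-0.3, 7)),
                       audit_scale = list(total_mean = 8.3, total_sd = 4.9,
                                          age_slope = 0.30,
                                          consumption_mean = 6.0,
                                          consumption_sd = 2.4,
                                          problem_scale = 0.55,
                                          problem_shift = 0.60,
                                          age_mean = 22.85, age_sd = 0.88),
                       seed = 20240626) {
  n_pairs <- unlist(n_pairs)     # YAML configs deliver named lists
  stopifnot(all(c("MZ", "DZss", "DZos") %in% names(n_pairs)),
            length(factor_means) == 8, length(factor_sds) == 8,
            all(factor_sds > 0), abs(sum(ace_shares) - 1) < 1e-8,
            all(ace_shares >= 0), length(wave_ages) == 6,
            anchors[1] == wave_ages[1], anchors[2] %in% wave_ages)
  names(factor_means) <- names(factor_sds) <- FACTORS
  Tcov <- diag(factor_sds) %*% factor_corr %*% diag(factor_sds)
  dimnames(Tcov) <- list(FACTORS, FACTORS)
  b_std <- outcome$beta_std
  if (is.null(names(b_std))) names(b_std) <- FACTORS
  b_raw <- b_std / factor_sds          # outcome liability has unit variance
  cross <- outcome$ace_cross
  explained <- drop(t(b_raw) %*% Tcov %*% b_raw) +
    2 * sum(b_raw * (cross$A + cross$C + cross$E))
  u_tot <- 1 - explained
  if (u_tot <= 0.05) stop("outcome effects leave <5% unique variance; rescale")
  cfg <- list(
    n_pairs = n_pairs, factor_means = factor_means, factor_sds = factor_sds,
    factor_corr = factor_corr, Tcov = Tcov, ace_shares = ace_shares,
    A = ace_shares[["a"]] * Tcov, C = ace_shares[["c"]] * Tcov,
    E = ace_shares[["e"]] * Tcov,
    wave_ages = wave_ages, anchors = anchors, residual_vars = residual_vars,
    residual_corr_same_age = residual_corr_same_age,
    residual_corr_parent_self = residual_corr_parent_self,
    outcome = outcome, b_raw = b_raw, u_tot = u_tot,
    u_ace = u_tot * outcome$resid_shares / sum(outcome$resid_shares),
    sex_effects = sex_effects, missingness = missingness,
    audit_scale = audit_scale, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

ace_matrix_9 <- function(M8, cross, unique_var) {
  out <- rbind(cbind(M8, cross), c(cross, unique_var))
  dimnames(out) <- list(c(FACTORS, "y_u"), c(FACTORS, "y_u"))
  out
}

# 9-variate A, C, E covariance blocks over (8 factors, outcome-unique part)
ace_blocks <- function(cfg) {
  cr <- cfg$outcome$ace_cross
  list(A = ace_matrix_9(cfg$A, cr$A, cfg$u_ace[["a"]]),
       C = ace_matrix_9(cfg$C, cr$C, cfg$u_ace[["c"]]),
       E = ace_matrix_9(cfg$E, cr$E, cfg$u_ace[["e"]]))
}

validate_sim_config <- function(cfg) {
  bl <- ace_blocks(cfg)
  for (nm in names(bl)) {
    ev <- eigen(bl[[nm]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      stop(nm, " covariance block is not positive semi-definite")
    }
  }
  tot <- diag(bl$A) + diag(bl$C) + diag(bl$E)
  if (any(tot <= 0)) stop("zero total variance for some variable")
  pm <- stats::plogis(cfg$missingness$intercepts)
  if (any(pm <= 0 | pm >= 1)) stop("missingness probabilities must be in (0,1)")
  invisible(TRUE)
}

mvn_draw <- function(n, Sigma) {
  d <- nrow(Sigma)
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  ev$values[ev$values < 0] <- 0
  L <- ev$vectors %*% diag(sqrt(ev$values), d)
  matrix(stats::rnorm(n * d), n, d) %*% t(L)
}

#' Draw per-twin latent ACE components
#'
#' Additive-genetic components are identical within MZ pairs; within DZ
#' pairs the second twin's component is `0.5 * A1 + sqrt(0.75) * A'` with
#' `A'` an independent draw from the same covariance, giving the required
#' within-pair genetic correlation of 0.5. Shared-environment components are
#' identical within every pair; nonshared components are independent.
#'
#' @param n_pairs Number of pairs.
#' @param zygosity `"MZ"` or `"DZ"` (either DZ code accepted).
#' @param A,C,E Covariance matrices of the three components.
#' @param seed Optional seed (NULL: use the current RNG stream).
#' @return List of matrices `A1, A2, C1, C2, E1, E2` (pairs x variables).
#' @export
simulate_ace_components <- function(n_pairs, zygosity, A, C, E, seed = NULL) {
  for (M in list(A, C, E)) {
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1e-12)) {
      stop("component covariance matrix is not positive semi-definite")
    }
  }
  draw <- function() {
    A1 <- mvn_draw(n_pairs, A)
    A2 <- if (startsWith(zygosity, "MZ")) A1
          else 0.5 * A1 + sqrt(0.75) * mvn_draw(n_pairs, A)
    C1 <- mvn_draw(n_pairs, C)
    list(A1 = A1, A2 = A2, C1 = C1, C2 = C1,
         E1 = mvn_draw(n_pairs, E), E2 = mvn_draw(n_pairs, E))
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

sex_beta <- function(cfg, sex) {
  se <- cfg$sex_effects
  b_std <- if (sex == "female" && !is.null(se$beta_std_female)) se$beta_std_female
           else if (sex == "male" && !is.null(se$beta_std_male)) se$beta_std_male
           else cfg$outcome$beta_std
  b_std / cfg$factor_sds
}

#' Simulate a twin cohort and its ground-truth manifest
#'
#' Generates a wide pair-per-row [twin_dataset] under the configured world:
#' growth factors are ACE-decomposed draws plus sex-specific mean shifts;
#' the twelve observed wave scores are the piecewise loading pattern applied
#' to the factors plus correlated residuals; the alcohol liability follows
#' the configured outcome model; AUDIT columns are monotone maps of the
#' liability (Problem intentionally zero-inflated and right-skewed);
#' missingness is imposed afterwards via the logistic MAR model on sex and
#' SES. The same config and seed reproduce the output bit-identically.
#'
#' @param config A [sim_config()].
#' @param keep_complete Also return the pre-deletion (complete) data and the
#'   latent truth per pair? Default TRUE (used by tests).
#' @return List: `data` (a `twin_dataset`), `truth` (ground-truth manifest:
#'   the config, implied observed moments per zygosity/sex stratum, and —
#'   when `keep_complete` — the complete data and latent draws).
#' @export
simulate_dataset <- function(config, keep_complete = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (all(cfg$b_raw == 0) && all(unlist(cfg$outcome$ace_cross) == 0)) {
    stop("outcome model empty: no direct paths and no correlated ACE links")
  }
  out <- with_local_seed(cfg$seed, {
    bl <- ace_blocks(cfg)
    Lam <- piecewise_loadings(cfg$wave_ages, cfg$anchors)
    Rmat <- residual_cov(cfg)
    sch <- default_schema(cfg$wave_ages)
    groups <- list()
    fam0 <- 0
    for (zyg in c("MZ", "DZss", "DZos")) {
      n <- cfg$n_pairs[[zyg]]
      comp <- simulate_ace_components(n, zyg, bl$A, bl$C, bl$E)
      if (zyg == "DZos") {
        first_male <- stats::runif(n) < 0.5
        sex1 <- ifelse(first_male, "male", "female")
        sex2 <- ifelse(first_male, "female", "male")
      } else {
        s <- ifelse(stats::runif(n) < 0.5, "male", "female")
        sex1 <- sex2 <- s
      }
      ses <- stats::rnorm(n)
      age22 <- cfg$audit_scale$age_mean + cfg$audit_scale$age_sd * stats::rnorm(n)
      twin_block <- function(Acomp, Ccomp, Ecomp, sex) {
        lat <- Acomp + Ccomp + Ecomp              # n x 9 (factors + y unique)
        shift <- outer(sex == "female", cfg$sex_effects$factor_shift_female)
        eta <- sweep(lat[, 1:8, drop = FALSE], 2, cfg$factor_means, "+") + shift
        colnames(eta) <- FACTORS
        resid <- mvn_draw(n, Rmat)
        waves <- eta %*% t(Lam) + resid
        b_m <- sex_beta(cfg, "male"); b_f <- sex_beta(cfg, "female")
        b <- outer(sex == "female", b_f - b_m) +
          matrix(b_m, length(sex), 8, byrow = TRUE)
        y <- rowSums(eta * b) + lat[, 9] +
          ifelse(sex == "female", cfg$sex_effects$outcome_shift_female, 0)
        as_au <- cfg$audit_scale
        audit_total <- as_au$total_mean + as_au$total_sd * y +
          as_au$age_slope * (age22 - as_au$age_mean)
        audit_cons <- as_au$consumption_mean + as_au$consumption_sd *
          (0.9 * y + sqrt(1 - 0.81) * stats::rnorm(n))
        audit_prob <- expm1(pmax(as_au$problem_scale * y + as_au$problem_shift, 0))
        list(eta = eta, waves = waves, y = y, audit_total = audit_total,
             audit_consumption = audit_cons, audit_problem = audit_prob)
      }
      t1 <- twin_block(comp$A1, comp$C1, comp$E1, sex1)
      t2 <- twin_block(comp$A2, comp$C2, comp$E2, sex2)
      wave_ids <- sch$waves$wave_id
      df <- data.frame(family_id = sprintf("%s_%05d", zyg, fam0 + seq_len(n)),
                       zyg = zyg, ses = ses, stringsAsFactors = FALSE)
      fam0 <- fam0 + n
      for (tw in 1:2) {
        tb <- if (tw == 1) t1 else t2
        sx <- if (tw == 1) sex1 else sex2
        df[[paste0("sex_t", tw)]] <- sx
        df[[paste0("age22_t", tw)]] <- age22
        W <- tb$waves
        colnames(W) <- paste0(wave_ids, "_t", tw)
        df <- cbind(df, W)
        for (v in c("audit_total", "audit_consumption", "audit_problem")) {
          df[[paste0(v, "_t", tw)]] <- tb[[v]]
        }
      }
      groups[[zyg]] <- list(df = df, eta1 = t1$eta, eta2 = t2$eta,
                            y1 = t1$y, y2 = t2$y)
    }
    df <- do.call(rbind, lapply(groups, function(g) g$df))
    rownames(df) <- NULL
    complete <- df
    # MAR missingness: one logistic model per wave block, applied per twin
    mis <- cfg$missingness
    for (i in 1:7) {
      cols <- if (i <= 6) {
        sch_w <- default_schema(cfg$wave_ages)$waves
        sch_w$wave_id[c(i, i + 6)]
      } else c("audit_total", "audit_consumption", "audit_problem")
      for (tw in 1:2) {
        lin <- mis$intercepts[i] +
          mis$coef_female[i] * (df[[paste0("sex_t", tw)]] == "female") +
          mis$coef_ses[i] * df$ses
        drop_row <- stats::runif(nrow(df)) < stats::plogis(lin)
        for (cl in paste0(cols, "_t", tw)) df[[cl]][drop_row] <- NA
      }
    }
    truth <- list(
      config = cfg,
      implied = implied_observed_moments(cfg),
      latent = if (keep_complete) lapply(groups, function(g)
        list(eta1 = g$eta1, eta2 = g$eta2, y1 = g$y1, y2 = g$y2)),
      complete = if (keep_complete) twin_dataset(complete, validate = FALSE)
    )
    list(data = twin_dataset(df, validate = FALSE), truth = truth)
  })
  out
}

residual_cov <- function(cfg) {
  v <- c(cfg$residual_vars$emotional, cfg$residual_vars$conduct)
  R <- diag(v)
  for (i in 1:6) {   # cross-trait, same wave
    R[i, i + 6] <- R[i + 6, i] <-
      cfg$residual_corr_same_age * sqrt(v[i] * v[i + 6])
  }
  knot <- which(cfg$wave_ages == cfg$anchors[2])
  stopifnot(length(knot) == 2)   # parent and self wave at the knot age
  for (off in c(0, 6)) {         # parent-self at the knot, per trait
    i <- knot[1] + off; j <- knot[2] + off
    R[i, j] <- R[j, i] <- cfg$residual_corr_parent_self * sqrt(v[i] * v[j])
  }
  R
}

#' Closed-form implied moments of the generated observables
#'
#' Exact means and covariances of the twelve wave scores and the (linear)
#' AUDIT-Total column, per sex, with within-twin and cross-twin blocks per
#' zygosity. Serves as the analytic oracle for all recovery tests; the
#' Consumption and Problem columns are monotone transforms of the same
#' liability and are not covered.
#'
#' @param config A [sim_config()].
#' @return List with `vars` (13 names), `mu` (per sex), `within` (13 x 13
#'   covariance, sex-invariant), and `cross` (per zygosity r = 1, 0.5).
#' @export
implied_observed_moments <- function(config) {
  cfg <- config
  bl <- ace_blocks(cfg)
  Lam <- piecewise_loadings(cfg$wave_ages, cfg$anchors)
  Rmat <- residual_cov(cfg)
  b <- cfg$b_raw
  s_all <- cfg$outcome$ace_cross$A + cfg$outcome$ace_cross$C +
    cfg$outcome$ace_cross$E
  Tc <- cfg$Tcov
  u_tot <- cfg$u_tot
  nine_within <- rbind(
    cbind(Tc, Tc %*% b + s_all),
    c(t(b) %*% Tc + s_all, drop(t(b) %*% Tc %*% b) + 2 * sum(b * s_all) + u_tot))
  nine_cross <- function(r) {
    Bx <- r * cfg$A + cfg$C
    sx <- r * cfg$outcome$ace_cross$A + cfg$outcome$ace_cross$C
    uy <- r * cfg$u_ace[["a"]] + cfg$u_ace[["c"]]
    rbind(cbind(Bx, Bx %*% b + sx),
          c(t(b) %*% Bx + sx,
            drop(t(b) %*% Bx %*% b) + 2 * sum(b * sx) + uy))
  }
  au <- cfg$audit_scale
  Map13 <- rbind(cbind(Lam, 0), c(rep(0, 8), au$total_sd))
  age_var <- au$age_sd^2
  age_add <- matrix(0, 13, 13); age_add[13, 13] <- au$age_slope^2 * age_var
  within <- Map13 %*% nine_within %*% t(Map13) +
    rbind(cbind(Rmat, 0), 0) + age_add
  cross <- lapply(c(MZ = 1, DZ = 0.5), function(r)
    Map13 %*% nine_cross(r) %*% t(Map13) + age_add)
  mu_sex <- function(sex) {
    shift <- if (sex == "female") cfg$sex_effects$factor_shift_female else 0 * cfg$factor_means
    eta_m <- cfg$factor_means + shift
    y_m <- sum(sex_beta(cfg, sex) * eta_m) +
      if (sex == "female") cfg$sex_effects$outcome_shift_female else 0
    c(drop(Lam %*% eta_m), au$total_mean + au$total_sd * y_m)
  }
  vars <- c(default_schema(cfg$wave_ages)$waves$wave_id, "audit_total")
  wn <- function(M) { dimnames(M) <- list(vars, vars); M }
  list(vars = vars,
       mu = list(male = stats::setNames(mu_sex("male"), vars),
                 female = stats::setNames(mu_sex("female"), vars)),
       within = wn(within),
       cross = lapply(cross, wn))
}

#' Censored rounding onto the reporting scales
#'
#' Optional post-processor mimicking the bounded integer scales of the
#' questionnaires: wave scores are rounded to halves and clipped to
#' \[0, 10\]; AUDIT columns are clipped to their ranges.
#'
#' @param dataset A `twin_dataset`.
#' @return The dataset with censored-rounded measurement columns.
#' @export
round_to_scale <- function(dataset) {
  df <- as.data.frame(dataset)
  sch <- default_schema()
  for (w in sch$waves$wave_id) for (tw in 1:2) {
    cl <- paste0(w, "_t", tw)
    if (cl %in% names(df)) df[[cl]] <- pmin(pmax(round(df[[cl]] * 2) / 2, 0), 10)
  }
  lims <- c(audit_total = 40, audit_consumption = 12, audit_problem = 28)
  for (v in names(lims)) for (tw in 1:2) {
    cl <- paste0(v, "_t", tw)
    if (cl %in% names(df)) df[[cl]] <- pmin(pmax(df[[cl]], 0), lims[[v]])
  }
  twin_dataset(df, validate = FALSE)
}
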