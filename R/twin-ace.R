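# Twin ACE models over factor scores and an alcohol outcome.
#
# Variables are ordered (P_1 ... P_k, y). The predictor block always has a
# full trivariate Cholesky per component (L_A, L_C, L_E). Each predictor's
# link to the outcome is either a DIRECT phenotypic path b_j (its A/C/E
# reach y only through the phenotype) or a CORRELATED-ACE link (free
# loadings of y on that predictor's Cholesky latents w_Aj, w_Cj, w_Ej). The
# outcome keeps unique components (a_u, c_u, e_u). The all-correlated model
# is the correlated-factor solution of the (k+1)-variate Cholesky; the
# all-direct model is the phenotypic-transmission model.

#' Define a twin ACE transmission structure
#'
#' @param predictors Character vector of predictor (factor score) names.
#' @param outcome Outcome name.
#' @param modes Character vector, one of `"direct"` / `"correlated"` per
#'   predictor (recycled).
#' @param values Optional list of parameter values (`L_A`, `L_C`, `L_E`
#'   lower-triangular k x k; `b`, `w_A`, `w_C`, `w_E` length-k vectors;
#'   `u = c(a_u, c_u, e_u)`; `means` length k+1). Entries inconsistent with
#'   `modes` (b for a correlated predictor, w for a direct one) must be 0.
#' @return An `ace_structure`.
#' @export
ace_structure <- function(predictors, outcome = "y",
                          modes = "correlated", values = NULL) {
  k <- length(predictors)
  modes <- rep_len(modes, k)
  stopifnot(all(modes %in% c("direct", "correlated")), k >= 1)
  v <- list(
    L_A = diag(0.5, k), L_C = diag(0.4, k), L_E = diag(0.6, k),
    b = numeric(k), w_A = numeric(k), w_C = numeric(k), w_E = numeric(k),
    u = c(a_u = 0.5, c_u = 0.3, e_u = 0.6), means = numeric(k + 1)
  )
  if (!is.null(values)) v[names(values)] <- values
  v$L_A <- as.matrix(v$L_A); v$L_C <- as.matrix(v$L_C); v$L_E <- as.matrix(v$L_E)
  stopifnot(all(v$b[modes == "correlated"] == 0),
            all(v$w_A[modes == "direct"] == 0),
            all(v$w_C[modes == "direct"] == 0),
            all(v$w_E[modes == "direct"] == 0))
  structure(list(predictors = predictors, outcome = outcome, k = k,
                 modes = modes, values = v),
            class = "ace_structure")
}

#' @export
print.ace_structure <- function(x, ...) {
  cat("ace_structure:", x$k, "predictor(s) ->", x$outcome, "\n")
  cat("  modes:", paste(paste0(x$predictors, "=",
                               substr(x$modes, 1, 1)), collapse = ", "), "\n")
  invisible(x)
}

structure_code <- function(st) paste(toupper(substr(st$modes, 1, 1)),
                                     collapse = "")

# within/cross covariance blocks for one pair; b1/b2 allow sex-specific
# direct paths within a pair
ace_blocks_pair <- function(v, r, b1 = v$b, b2 = v$b) {
  SigA <- tcrossprod(v$L_A); SigC <- tcrossprod(v$L_C); SigE <- tcrossprod(v$L_E)
  SigP <- SigA + SigC + SigE
  s_w <- drop(v$L_A %*% v$w_A + v$L_C %*% v$w_C + v$L_E %*% v$w_E)
  s_x <- drop(r * v$L_A %*% v$w_A + v$L_C %*% v$w_C)
  SigX <- r * SigA + SigC
  u_w <- sum(v$u^2)
  u_x <- r * v$u[1]^2 + v$u[2]^2
  wss_w <- sum(v$w_A^2) + sum(v$w_C^2) + sum(v$w_E^2)
  wss_x <- r * sum(v$w_A^2) + sum(v$w_C^2)
  within <- function(b) {
    rbind(cbind(SigP, SigP %*% b + s_w),
          c(drop(t(b) %*% SigP) + s_w,
            drop(t(b) %*% SigP %*% b) + 2 * sum(b * s_w) + wss_w + u_w))
  }
  cross <- rbind(
    cbind(SigX, SigX %*% b2 + s_x),
    c(drop(t(b1) %*% SigX) + s_x,
      drop(t(b1) %*% SigX %*% b2) + sum(b1 * s_x) + sum(b2 * s_x) +
        wss_x + u_x))
  list(within1 = within(b1), within2 = within(b2), cross = cross)
}

#' Implied covariance of a twin pair's variables
#'
#' Full `2(k+1) x 2(k+1)` covariance in the order
#' `(P1..Pk, y)` twin 1, then twin 2. The cross-twin block carries the
#' genetic correlation r = 1 (MZ) or 0.5 (DZ) on every A contribution;
#' E contributes only within twins; direct paths propagate predictor A and
#' C (never E) into cross-twin predictor-outcome covariances.
#'
#' @param structure An [ace_structure()] with values.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return Covariance matrix with named rows/cols (`_t1` / `_t2` suffixes).
#' @export
implied_pair_cov <- function(structure, zygosity) {
  r <- if (startsWith(zygosity, "MZ")) 1 else 0.5
  bl <- ace_blocks_pair(structure$values, r)
  S <- rbind(cbind(bl$within1, bl$cross),
             cbind(t(bl$cross), bl$within2))
  vars <- c(structure$predictors, structure$outcome)
  nm <- c(paste0(vars, "_t1"), paste0(vars, "_t2"))
  dimnames(S) <- list(nm, nm)
  S
}

# ---- free-parameter layout and the engine model ---------------------------

ace_model <- function(structure, sex_specific = FALSE) {
  st <- structure; k <- st$k; v <- st$values
  vars <- c(st$predictors, st$outcome)
  labs <- c(); th0 <- c(); lo <- c(); hi <- c()
  add <- function(lab, val, lower = -Inf) {
    labs <<- c(labs, lab); th0 <<- c(th0, val)
    lo <<- c(lo, rep(lower, length(lab))); hi <<- c(hi, rep(Inf, length(lab)))
  }
  for (comp in c("A", "C", "E")) {
    L <- v[[paste0("L_", comp)]]
    for (i in seq_len(k)) for (j in seq_len(i)) {
      add(sprintf("l%s_%d_%d", comp, i, j), L[i, j],
          lower = if (i == j) 0 else -Inf)
    }
  }
  bsex <- function(lab) if (sex_specific) paste0(lab, c(".male", ".female")) else lab
  for (j in seq_len(k)) {
    if (st$modes[j] == "direct") {
      for (lb in bsex(paste0("b_", st$predictors[j]))) add(lb, v$b[j])
    } else {
      add(paste0("wA_", st$predictors[j]), v$w_A[j])
      add(paste0("wC_", st$predictors[j]), v$w_C[j])
      add(paste0("wE_", st$predictors[j]), v$w_E[j])
    }
  }
  add(c("u_a", "u_c"), v$u[1:2], lower = 0)
  add("u_e", v$u[3], lower = 1e-6)
  add(paste0("mu_", vars), v$means)
  names(th0) <- labs

  unpack <- function(theta) {
    vv <- v
    for (comp in c("A", "C", "E")) {
      L <- matrix(0, k, k)
      for (i in seq_len(k)) for (j in seq_len(i)) {
        L[i, j] <- theta[[sprintf("l%s_%d_%d", comp, i, j)]]
      }
      vv[[paste0("L_", comp)]] <- L
    }
    b <- function(sex) {
      out <- numeric(k)
      for (j in seq_len(k)) if (st$modes[j] == "direct") {
        lb <- if (sex_specific) paste0("b_", st$predictors[j], ".", sex)
              else paste0("b_", st$predictors[j])
        out[j] <- theta[[lb]]
      }
      out
    }
    for (j in seq_len(k)) if (st$modes[j] == "correlated") {
      vv$w_A[j] <- theta[[paste0("wA_", st$predictors[j])]]
      vv$w_C[j] <- theta[[paste0("wC_", st$predictors[j])]]
      vv$w_E[j] <- theta[[paste0("wE_", st$predictors[j])]]
    }
    vv$u <- c(theta[["u_a"]], theta[["u_c"]], theta[["u_e"]])
    vv$means <- theta[paste0("mu_", vars)]
    list(v = vv, b_male = b("male"), b_female = b("female"),
         b = b("male"))   # b() ignores sex when !sex_specific
  }

  groups <- if (sex_specific) c("MZ_male", "MZ_female", "DZ_male",
                                "DZ_female", "DZ_os") else c("MZ", "DZ")
  pair_sigma <- function(vv, r, b1, b2) {
    bl <- ace_blocks_pair(vv, r, b1, b2)
    rbind(cbind(bl$within1, bl$cross), cbind(t(bl$cross), bl$within2))
  }
  moments <- function(theta) {
    names(theta) <- labs
    up <- unpack(theta)
    mu <- rep(unname(up$v$means), 2)
    out <- lapply(groups, function(g) {
      r <- if (startsWith(g, "MZ")) 1 else 0.5
      bb <- switch(g,
                   MZ = , DZ = list(up$b, up$b),
                   MZ_male = , DZ_male = list(up$b_male, up$b_male),
                   MZ_female = , DZ_female = list(up$b_female, up$b_female),
                   DZ_os = list(up$b_male, up$b_female))  # twin 1 = male
      Sig <- pair_sigma(up$v, r, bb[[1]], bb[[2]])
      list(mu = mu, Sigma = (Sig + t(Sig)) / 2)
    })
    names(out) <- groups
    out
  }
  out <- list(theta0 = th0, lower = lo, upper = hi, labels = labs,
              groups = groups,
              observed = c(paste0(vars, "_t1"), paste0(vars, "_t2")),
              moments = moments, dmoments = NULL, unpack = unpack,
              ace_structure = st, sex_specific = sex_specific)
  class(out) <- "fiml_model"
  out
}

# local identification: rank of the moment Jacobian at the start values
check_identified <- function(model) {
  th <- model$theta0
  th[th == 0] <- 0.1   # avoid structural zeros masking rank
  dm <- model_dmoments(model, th)
  J <- do.call(cbind, lapply(model$groups, function(g)
    cbind(dm[[g]]$dMu, dm[[g]]$dSig)))
  r <- qr(J)$rank
  if (r < length(th)) {
    stop("structure not identified: moment Jacobian rank ", r, " < ",
         length(th), " free parameters")
  }
  invisible(TRUE)
}

#' Fit a twin ACE structure to pair-level data
#'
#' FIML over pair rows (a missing co-twin is handled through the
#' missingness pattern) with MZ and DZ groups; same-sex and opposite-sex DZ
#' pairs are pooled after sex residualization. Pairs are the independent
#' sampling unit, so naive information-based standard errors apply.
#'
#' @param structure An [ace_structure()] template (its values are start
#'   hints only).
#' @param table Pair-per-row data frame with columns `<var>_t1`, `<var>_t2`
#'   for every structure variable and a `zyg` column (MZ / DZss / DZos).
#' @param se,starts,... Passed to [fit_fiml()].
#' @return A `twinpaths_fit` with `$ace` (the fitted structure values,
#'   standardized variance shares and standardized direct paths).
#' @export
fit_ace <- function(structure, table, se = TRUE, starts = 1, ...) {
  df <- as.data.frame(table)
  df$zyg2 <- ifelse(startsWith(as.character(df$zyg), "MZ"), "MZ", "DZ")
  if (length(unique(df$zyg2)) < 2) stop("need both MZ and DZ pairs")
  model <- ace_model(structure)
  # moment-based starts: split each variable's variance evenly over A/C/E
  vars <- c(structure$predictors, structure$outcome)
  sds <- vapply(vars, function(v)
    stats::sd(c(df[[paste0(v, "_t1")]], df[[paste0(v, "_t2")]]), na.rm = TRUE),
    numeric(1))
  mus <- vapply(vars, function(v)
    mean(c(df[[paste0(v, "_t1")]], df[[paste0(v, "_t2")]]), na.rm = TRUE),
    numeric(1))
  th <- model$theta0
  for (comp in c("A", "C", "E")) {
    for (i in seq_len(structure$k)) {
      th[[sprintf("l%s_%d_%d", comp, i, i)]] <- sds[i] / sqrt(3)
    }
  }
  th[["u_a"]] <- th[["u_c"]] <- th[["u_e"]] <- sds[length(sds)] / sqrt(3)
  th[paste0("mu_", vars)] <- mus
  check_identified(model)
  fit <- fit_fiml(model, df, group = "zyg2", start = th, se = se,
                  starts = starts, ...)
  fit$ace <- summarize_ace(fit)
  fit
}

# standardized variance shares and paths of a fitted ACE model
summarize_ace <- function(fit) {
  model <- fit$model
  st <- model$ace_structure
  up <- model$unpack(fit$estimates)
  v <- up$v; b <- up$b
  SigA <- tcrossprod(v$L_A); SigC <- tcrossprod(v$L_C); SigE <- tcrossprod(v$L_E)
  SigP <- SigA + SigC + SigE
  tot_y <- ace_blocks_pair(v, 1, b, b)$within1[st$k + 1, st$k + 1]
  yA <- drop(t(b) %*% SigA %*% b) + 2 * sum(b * (v$L_A %*% v$w_A)) +
    sum(v$w_A^2) + v$u[1]^2
  yC <- drop(t(b) %*% SigC %*% b) + 2 * sum(b * (v$L_C %*% v$w_C)) +
    sum(v$w_C^2) + v$u[2]^2
  yE <- drop(t(b) %*% SigE %*% b) + 2 * sum(b * (v$L_E %*% v$w_E)) +
    sum(v$w_E^2) + v$u[3]^2
  shares <- rbind(
    cbind(a2 = diag(SigA) / diag(SigP), c2 = diag(SigC) / diag(SigP),
          e2 = diag(SigE) / diag(SigP)),
    y = c(yA, yC, yE) / tot_y)
  rownames(shares) <- c(st$predictors, st$outcome)
  b_std <- b * sqrt(diag(SigP)) / sqrt(tot_y)
  names(b_std) <- st$predictors
  list(values = v, shares = shares, b = b, b_std = b_std,
       modes = st$modes, total_var = c(diag(SigP), tot_y))
}

#' AIC search over transmission structures
#'
#' Fits the full correlated-factor Cholesky and the all-direct-paths model;
#' if the direct model is not already AIC-best, also fits every hybrid in
#' the direct/correlated lattice (exhaustive for the small k used here).
#' Non-converged members are excluded with a logged reason. Ties break
#' toward fewer parameters, then lexicographic structure code.
#'
#' @param table Pair-per-row factor-score table (see [fit_ace()]).
#' @param predictors,outcome Variable names in `table`.
#' @param ... Passed to [fit_ace()].
#' @return List: `table` (structure code, k, AIC, dAIC vs Cholesky,
#'   converged), `selected` (code), `fit` (best fit), `fits` (all).
#' @export
structure_search <- function(table, predictors, outcome, ...) {
  k <- length(predictors)
  stopifnot(k >= 1)
  codes_all <- apply(expand.grid(rep(list(c("correlated", "direct")), k)),
                     1, identity, simplify = FALSE)
  modes_of <- function(code) vapply(code, identity, character(1))
  fit_one <- function(modes) {
    st <- ace_structure(predictors, outcome, modes)
    tryCatch(fit_ace(st, table, se = FALSE, ...), error = function(e) e)
  }
  res <- list()
  res[["chol"]] <- list(modes = rep("correlated", k))
  res[["direct"]] <- list(modes = rep("direct", k))
  fits <- list()
  for (nm in names(res)) fits[[nm]] <- fit_one(res[[nm]]$modes)
  aic_of <- function(f) if (inherits(f, "twinpaths_fit") &&
                              f$convergence$converged) f$AIC else NA_real_
  hybrids_needed <- k > 1 &&
    (is.na(aic_of(fits$direct)) || is.na(aic_of(fits$chol)) ||
       aic_of(fits$direct) > aic_of(fits$chol))
  if (hybrids_needed) {
    for (code in codes_all) {
      modes <- modes_of(code)
      nm <- paste(toupper(substr(modes, 1, 1)), collapse = "")
      if (all(modes == "correlated") || all(modes == "direct")) next
      fits[[nm]] <- fit_one(modes)
    }
  }
  rows <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    ok <- inherits(f, "twinpaths_fit") && f$convergence$converged
    modes <- if (nm == "chol") rep("correlated", k)
             else if (nm == "direct") rep("direct", k)
             else c("correlated", "direct")[match(strsplit(nm, "")[[1]],
                                                  c("C", "D"))]
    data.frame(code = paste(toupper(substr(modes, 1, 1)), collapse = ""),
               name = nm, k_params = if (ok) f$k else NA_integer_,
               AIC = if (ok) f$AIC else NA_real_, converged = ok,
               reason = if (ok) "" else
                 if (inherits(f, "twinpaths_fit")) "not converged"
                 else conditionMessage(f),
               stringsAsFactors = FALSE)
  }))
  ref <- rows$AIC[rows$name == "chol"]
  rows$dAIC <- rows$AIC - ref
  ok <- rows[rows$converged, ]
  if (nrow(ok) == 0) stop("no structure converged")
  ok <- ok[order(ok$AIC, ok$k_params, ok$code), ]
  sel <- ok$name[1]
  list(table = rows[order(rows$AIC), ], selected_code = ok$code[1],
       selected = fits[[sel]]$model$ace_structure, fit = fits[[sel]],
       fits = fits)
}

#' Sex differences in direct paths
#'
#' Refits the selected structure with five groups (MZ male, MZ female, DZ
#' male, DZ female, DZ opposite-sex), direct paths indexed by each twin's
#' own sex and all ACE parameters equated across sexes, and tests whether
#' the sex-specific paths can be constrained equal by a chi-square
#' difference test, with per-path Wald comparisons.
#'
#' @param structure The selected [ace_structure()] (needs >= 1 direct path).
#' @param table Pair table with `zyg`, `sex_t1`, `sex_t2` and variables; in
#'   opposite-sex pairs twins are reordered male-first internally.
#' @param se Standard errors for the free (sex-specific) fit; without them
#'   the per-path Wald columns are NA and only the joint LR test is
#'   reported.
#' @param ... Passed to [fit_fiml()].
#' @return List: `lr` (equal vs free), `paths` (per-path estimates by sex,
#'   Wald W and p), `fit_free`, `fit_equal`; or an empty report when the
#'   structure has no direct path.
#' @export
sex_difference_direct_paths <- function(structure, table, se = TRUE, ...) {
  if (!any(structure$modes == "direct")) {
    return(list(lr = NULL, paths = NULL, note = "no direct paths"))
  }
  df <- as.data.frame(table)
  vars <- c(structure$predictors, structure$outcome)
  os <- startsWith(as.character(df$zyg), "DZo") |
    (!is.na(df$sex_t1) & !is.na(df$sex_t2) & df$sex_t1 != df$sex_t2)
  swap <- os & df$sex_t1 == "female"
  for (v in c(vars, "sex", "age22")) {
    c1 <- paste0(v, "_t1"); c2 <- paste0(v, "_t2")
    if (!all(c(c1, c2) %in% names(df))) next
    tmp <- df[[c1]][swap]; df[[c1]][swap] <- df[[c2]][swap]
    df[[c2]][swap] <- tmp
  }
  mz <- startsWith(as.character(df$zyg), "MZ")
  df$group5 <- ifelse(os, "DZ_os",
                      paste0(ifelse(mz, "MZ", "DZ"), "_", df$sex_t1))
  model_free <- ace_model(structure, sex_specific = TRUE)
  fit_free <- fit_fiml(model_free, df, group = "group5", starts = 1, se = se,
                       ...)
  # equal-b model: plain two-sex-pooled parameterization on the same groups
  model_eq <- ace_model(structure, sex_specific = FALSE)
  model_eq$groups <- model_free$groups
  mom_eq <- model_eq$moments
  model_eq$moments <- function(theta) {
    two <- mom_eq(theta)
    out <- lapply(model_free$groups, function(g)
      two[[if (startsWith(g, "MZ")) "MZ" else "DZ"]])
    names(out) <- model_free$groups
    out
  }
  fit_eq <- fit_fiml(model_eq, df, group = "group5", starts = 1, se = FALSE, ...)
  lr <- list(chisq = max(0, 2 * (fit_free$loglik - fit_eq$loglik)),
             df = fit_free$k - fit_eq$k)
  lr$p <- stats::pchisq(lr$chisq, lr$df, lower.tail = FALSE)
  V <- fit_free$vcov
  paths <- do.call(rbind, lapply(structure$predictors[structure$modes == "direct"],
                                 function(pr) {
    lm_ <- paste0("b_", pr, ".male"); lf_ <- paste0("b_", pr, ".female")
    w <- if (!is.null(V)) wald_equality(
      fit_free$estimates[[lm_]], sqrt(V[lm_, lm_]),
      fit_free$estimates[[lf_]], sqrt(V[lf_, lf_]), V[lm_, lf_])
      else list(W = NA_real_, p = NA_real_)
    data.frame(predictor = pr, b_male = fit_free$estimates[[lm_]],
               b_female = fit_free$estimates[[lf_]],
               se_male = if (!is.null(V)) sqrt(V[lm_, lm_]) else NA_real_,
               se_female = if (!is.null(V)) sqrt(V[lf_, lf_]) else NA_real_,
               W = w$W, p = w$p, stringsAsFactors = FALSE)
  }))
  list(lr = lr, paths = paths, fit_free = fit_free, fit_equal = fit_eq)
}

#' Simulate pair-level data from an ACE structure
#'
#' Draws twin pairs directly from the structure's implied pair covariance;
#' used for calibration and recovery experiments.
#'
#' @param structure An [ace_structure()] with true values.
#' @param n_pairs Named vector `c(MZ = ..., DZ = ...)`.
#' @param seed Seed (NULL: current stream).
#' @return Pair-per-row data frame with a `zyg` column.
#' @export
simulate_ace_pairs <- function(structure, n_pairs = c(MZ = 1000, DZ = 1000),
                               seed = NULL) {
  draw <- function() {
    out <- lapply(names(n_pairs), function(z) {
      S <- implied_pair_cov(structure, z)
      Y <- mvn_draw(n_pairs[[z]], S)
      Y <- sweep(Y, 2, rep(structure$values$means, 2), "+")
      colnames(Y) <- colnames(S)
      data.frame(zyg = z, Y, stringsAsFactors = FALSE, check.names = FALSE)
    })
    do.call(rbind, out)
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# Regression-method factor scores from model matrices, pattern-wise over
# arbitrary missingness. Y columns must match Lambda's rows.
regression_scores <- function(mats, Y) {
  m <- ncol(mats$lambda)
  Tm <- solve(diag(m) - mats$beta)
  LT <- mats$lambda %*% Tm
  Psi_lat <- Tm %*% mats$psi %*% t(Tm)
  Sigma <- LT %*% mats$psi %*% t(LT) + mats$theta
  mu <- drop(mats$nu + LT %*% mats$alpha)
  alpha_tot <- drop(Tm %*% mats$alpha)
  C_eta_y <- Psi_lat %*% t(LT)
  st <- pattern_stats(Y)
  scores <- matrix(NA_real_, nrow(Y), m,
                   dimnames = list(NULL, colnames(mats$lambda)))
  for (pt in st$patterns) {
    o <- pt$obs
    W <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
    R <- sweep(Y[pt$rows, o, drop = FALSE], 2, mu[o])
    sc <- R %*% (W %*% t(C_eta_y[, o, drop = FALSE]))
    scores[pt$rows, ] <- sweep(sc, 2, alpha_tot, "+")
  }
  scores
}

#' Regression-method factor scores and the twin score table
#'
#' Computes regression-method factor scores from a fitted growth(+outcome)
#' model — `score = alpha + Psi_lat Lambda' Sigma^-1 (y_obs - mu)` on each
#' row's observed sub-pattern — keeps the requested predictors, re-attaches
#' the preprocessed outcome, pivots back to one row per pair, and residualizes
#' every score and outcome column on sex.
#'
#' @param growth_fit A single-group `twinpaths_fit` from
#'   [fit_outcome_model()] (or a plain growth fit).
#' @param dataset The wide `twin_dataset` the fit used.
#' @param predictors Factor names to retain (the significant predictors);
#'   default all eight.
#' @param outcome Outcome column to carry along.
#' @param residualize_sex Residualize all columns on sex? Default TRUE.
#' @param preprocess Apply [preprocess_alcohol()] first?
#' @return Pair-per-row data frame: `family_id`, `zyg`, `sex_t*`,
#'   `<factor>_t*` scores and `<outcome>_t*`.
#' @export
compute_factor_scores <- function(growth_fit, dataset,
                                  predictors = FACTORS,
                                  outcome = "audit_total",
                                  residualize_sex = TRUE,
                                  preprocess = TRUE) {
  if (!growth_fit$convergence$converged) {
    warning("factor scores from a non-converged growth fit")
  }
  spec <- growth_fit$model$spec
  g <- growth_fit$model$groups[1]
  mats <- growth_fit$model$fill(growth_fit$estimates[growth_fit$model$labels])[[g]]
  long <- analysis_frame(dataset, covariates = character(),
                         preprocess = preprocess)
  Y <- as.matrix(long[, spec$observed, drop = FALSE])
  # score from the growth indicators only: variables that are the single
  # indicator of their own latent (the outcome and covariates) would leak
  # the outcome into the scores and are masked out
  lam <- mats$lambda
  ident_lat <- colnames(lam)[colSums(lam != 0) == 1]
  ident_obs <- rownames(lam)[rowSums(lam[, ident_lat, drop = FALSE] != 0) > 0]
  Y[, intersect(colnames(Y), ident_obs)] <- NA
  scores <- regression_scores(mats, Y)
  # a trait with no observed indicator gives no information: score -> NA
  trait_obs <- list(em = grep("^em_", spec$observed),
                    cd = grep("^cd_", spec$observed))
  for (tr in names(trait_obs)) {
    none <- rowSums(!is.na(Y[, trait_obs[[tr]], drop = FALSE])) == 0
    scores[none, grep(paste0("^", tr, "_"), colnames(scores))] <- NA
  }
  keep <- intersect(predictors, colnames(scores))
  out_long <- data.frame(long[, c("family_id", "zyg", "twin", "sex")],
                         scores[, keep, drop = FALSE],
                         outcome = long[[outcome]],
                         stringsAsFactors = FALSE)
  names(out_long)[names(out_long) == "outcome"] <- outcome
  if (residualize_sex) {
    sx <- as.numeric(out_long$sex == "female")
    for (v in c(keep, outcome)) {
      ok <- !is.na(out_long[[v]]) & !is.na(sx)
      if (sum(ok) > 2 && length(unique(sx[ok])) > 1) {
        f <- stats::lm.fit(cbind(1, sx[ok]), out_long[[v]][ok])
        out_long[[v]][ok] <- f$residuals
      } else if (sum(ok) > 0) {
        out_long[[v]][ok] <- out_long[[v]][ok] - mean(out_long[[v]][ok])
      }
    }
  }
  wide <- NULL
  for (tw in 1:2) {
    part <- out_long[out_long$twin == tw,
                     c("family_id", "zyg", "sex", keep, outcome)]
    names(part)[-(1:2)] <- paste0(c("sex", keep, outcome), "_t", tw)
    wide <- if (is.null(wide)) part else
      merge(wide, part[, -2], by = "family_id", sort = FALSE)
  }
  wide[order(wide$family_id), , drop = FALSE]
}
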