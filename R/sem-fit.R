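# Pattern-wise FIML machinery.
#
# Rows are grouped by missingness pattern; each pattern contributes through
# its sufficient statistics (n, mean, ML scatter), so a likelihood evaluation
# costs O(#patterns), independent of n.

pattern_stats <- function(Y) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  obs <- !is.na(Y)
  key <- do.call(paste0, as.data.frame(obs * 1L))
  idx <- split(seq_len(nrow(Y)), key)
  pats <- list()
  for (rows in idx) {
    o <- which(obs[rows[1], ])
    if (length(o) == 0) next
    Yo <- Y[rows, o, drop = FALSE]
    n <- length(rows)
    m <- colMeans(Yo)
    C <- sweep(Yo, 2, m)
    pats[[length(pats) + 1]] <- list(obs = o, n = n, mean = m,
                                     S = crossprod(C) / n, rows = rows)
  }
  list(patterns = pats, Y = Y, n = nrow(Y))
}

# log-likelihood of one group's patterns under (mu, Sigma); -Inf if any
# observed sub-matrix is not positive definite.
ll_patterns <- function(mu, Sigma, pats) {
  ll <- 0
  for (pt in pats) {
    o <- pt$obs
    ch <- tryCatch(chol(Sigma[o, o, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch) || any(diag(ch) < 1e-12)) return(-Inf)
    W <- chol2inv(ch)
    d <- pt$mean - mu[o]
    ll <- ll - 0.5 * pt$n *
      (length(o) * log(2 * pi) + 2 * sum(log(diag(ch))) +
         sum(W * pt$S) + drop(crossprod(d, W %*% d)))
  }
  ll
}

#' Full-information ML log-likelihood
#'
#' Sum over rows of the multivariate-normal log-density of each row's
#' observed subvector under the marginal of (mu, Sigma) restricted to its
#' observed coordinates. Rows with nothing observed contribute 0. Rows are
#' grouped by missingness pattern so each pattern's sub-matrix is factorized
#' once.
#'
#' @param mu Mean vector.
#' @param Sigma Covariance matrix.
#' @param data Matrix or data frame of rows (NA = missing).
#' @return Scalar log-likelihood; `-Inf` if some observed sub-matrix is not
#'   positive definite.
#' @export
fiml_loglik <- function(mu, Sigma, data) {
  st <- pattern_stats(as.matrix(data))
  ll_patterns(mu, Sigma, st$patterns)
}

# gradient of the total loglik at theta given per-group pattern stats.
grad_patterns <- function(model, theta, stats_by_group, mom = NULL,
                          dmom = NULL) {
  if (is.null(mom)) mom <- model$moments(theta)
  if (is.null(dmom)) dmom <- model_dmoments(model, theta, mom)
  k <- length(theta)
  g <- numeric(k)
  p <- length(model$observed)
  for (grp in names(stats_by_group)) {
    mu <- mom[[grp]]$mu; Sigma <- mom[[grp]]$Sigma
    dMu <- dmom[[grp]]$dMu; dSig <- dmom[[grp]]$dSig
    for (pt in stats_by_group[[grp]]$patterns) {
      o <- pt$obs
      W <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
      d <- pt$mean - mu[o]
      Wd <- W %*% d
      G <- W %*% (pt$S + tcrossprod(d)) %*% W - W
      # pad into full p / p x p so the k x p^2 array is used without copies
      Gfull <- matrix(0, p, p); Gfull[o, o] <- G
      mfull <- numeric(p); mfull[o] <- Wd
      g <- g + 0.5 * pt$n * drop(dSig %*% as.vector(Gfull)) +
        pt$n * drop(dMu %*% mfull)
    }
  }
  g
}

model_dmoments <- function(model, theta, mom = NULL) {
  if (!is.null(model$dmoments)) return(model$dmoments(theta, mom))
  # generic central finite differences on the moment functions
  k <- length(theta)
  p <- length(model$observed)
  out <- lapply(model$groups, function(g)
    list(dMu = matrix(0, k, p), dSig = matrix(0, k, p * p)))
  names(out) <- model$groups
  for (j in seq_len(k)) {
    h <- 1e-6 * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    mp <- model$moments(tp); mm <- model$moments(tm)
    for (g in model$groups) {
      out[[g]]$dMu[j, ] <- (mp[[g]]$mu - mm[[g]]$mu) / (2 * h)
      out[[g]]$dSig[j, ] <- as.vector(mp[[g]]$Sigma - mm[[g]]$Sigma) / (2 * h)
    }
  }
  out
}

# Expected (Fisher) information of the FIML log-likelihood at theta:
# sum over patterns of n * [dMu' W dMu + 1/2 dSig' (W x W) dSig] on the
# observed coordinates.
expected_info <- function(model, theta, stats_by_group, mom = NULL,
                          dmom = NULL) {
  if (is.null(mom)) mom <- model$moments(theta)
  if (is.null(dmom)) dmom <- model_dmoments(model, theta, mom)
  k <- length(theta)
  p <- length(model$observed)
  I <- matrix(0, k, k)
  for (grp in names(stats_by_group)) {
    Sigma <- mom[[grp]]$Sigma
    dMu <- dmom[[grp]]$dMu; dSig <- dmom[[grp]]$dSig
    for (pt in stats_by_group[[grp]]$patterns) {
      o <- pt$obs; po <- length(o)
      W <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
      dMu_o <- dMu[, o, drop = FALSE]
      lin <- as.vector(outer(o, (o - 1L) * p, "+"))
      dSo <- dSig[, lin, drop = FALSE]
      R <- matrix(0, k, po * po)
      for (j in seq_len(k)) {
        M <- matrix(dSo[j, ], po, po)
        R[j, ] <- as.vector(W %*% M %*% W)
      }
      I <- I + pt$n * (dMu_o %*% W %*% t(dMu_o)) +
        0.5 * pt$n * tcrossprod(dSo, R)
    }
  }
  (I + t(I)) / 2
}

# Jacobian of a gradient function by central differences: the Hessian of
# the underlying objective.
numeric_hessian <- function(grad_fn, theta, h_rel = 1e-5) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- h_rel * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (grad_fn(tp) - grad_fn(tm)) / (2 * h)
  }
  (H + t(H)) / 2
}

# deterministic local RNG that leaves the caller's stream untouched
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(list = ".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(code)
}

#' Fit a model by full-information maximum likelihood
#'
#' Maximizes the pattern-wise FIML log-likelihood over the free parameters by
#' bounded quasi-Newton (`nlminb`) with semi-analytic gradients. Works for
#' any object implementing the internal moment-model interface; use
#' [fit_sem()] for `sem_spec` models.
#'
#' @param model A compiled moment model (e.g. from an internal
#'   `compile_spec()` call).
#' @param data Data frame or matrix containing the model's observed columns.
#' @param group Optional name of the column of `data` holding group labels
#'   (must match the model's groups); NULL for single-group models.
#' @param start Optional named start vector overriding the model's.
#' @param starts Number of optimizer starts; starts beyond the first are
#'   jittered deterministically (default 3). The best converged solution is
#'   kept.
#' @param se Compute the observed-information covariance of the estimates?
#'   Default TRUE; set FALSE in simulation loops that only need the
#'   likelihood.
#' @param seed Seed for the deterministic start jitter.
#' @param iter_max Maximum optimizer iterations per start.
#' @param grad_tol Scaled-gradient convergence tolerance.
#' @return A `twinpaths_fit` object: estimates, loglik, `k`, `AIC`
#'   (= -2 loglik + 2k exactly), naive covariance, convergence diagnostics
#'   and per-pattern bookkeeping.
#' @export
fit_fiml <- function(model, data, group = NULL, start = NULL, starts = 3,
                     se = TRUE, seed = 1, iter_max = 1000, grad_tol = 1e-5) {
  data <- as.data.frame(data)
  miss_cols <- setdiff(model$observed, names(data))
  if (length(miss_cols)) stop("data lacks columns: ", paste(miss_cols, collapse = ", "))
  if (is.null(group)) {
    if (length(model$groups) != 1) stop("multi-group model needs `group`")
    grp_idx <- rep(model$groups, nrow(data))
  } else {
    grp_idx <- as.character(data[[group]])
    if (!all(grp_idx %in% model$groups)) {
      stop("group column contains labels not in the model: ",
           paste(setdiff(unique(grp_idx), model$groups), collapse = ", "))
    }
  }
  stats_by_group <- list()
  for (g in model$groups) {
    rows <- which(grp_idx == g)
    stats_by_group[[g]] <- pattern_stats(data[rows, model$observed, drop = FALSE])
    stats_by_group[[g]]$row_ids <- rows
  }
  never_seen <- vapply(model$observed, function(v)
    all(is.na(data[[v]])), logical(1))
  if (any(never_seen)) {
    stop("no observed values for: ",
         paste(model$observed[never_seen], collapse = ", "))
  }

  theta0 <- if (is.null(start)) model$theta0 else start[model$labels]
  k <- length(theta0)
  penalty <- 1e10
  nll <- function(th) {
    mom <- tryCatch(model$moments(th), error = function(e) NULL)
    if (is.null(mom)) return(penalty)
    ll <- sum(vapply(model$groups, function(g)
      ll_patterns(mom[[g]]$mu, mom[[g]]$Sigma, stats_by_group[[g]]$patterns),
      numeric(1)))
    if (!is.finite(ll)) penalty else -ll
  }
  ngr <- function(th) {
    mom <- tryCatch(model$moments(th), error = function(e) NULL)
    if (is.null(mom)) return(numeric(k))
    ok <- all(vapply(model$groups, function(g)
      is.finite(ll_patterns(mom[[g]]$mu, mom[[g]]$Sigma,
                            stats_by_group[[g]]$patterns)), logical(1)))
    if (!ok) return(numeric(k))
    -grad_patterns(model, th, stats_by_group, mom)
  }

  clamp <- function(th) pmin(pmax(th, model$lower + 1e-10), model$upper)
  grad_ok <- function(th, g) {
    max(abs(g) * pmax(abs(th), 1)) / max(1, abs(nll(th))) < grad_tol
  }
  # quasi-Newton optimizers need O(k) iterations to learn curvature; for
  # larger models a Fisher-scoring polish (expected information, refreshed
  # every few steps) reaches the optimum from warm starts in a handful of
  # iterations, after which nlminb is often unnecessary
  polish <- function(th, max_iter = 80, ll_tol = 2e-3) {
    Iraw <- NULL
    mu <- 1e-3                           # Levenberg-Marquardt damping
    iters <- 0
    stalls <- 0
    quasi <- FALSE
    for (it in seq_len(max_iter)) {
      g <- -ngr(th)                      # gradient of the loglik
      if (all(g == 0)) break             # infeasible point
      if (grad_ok(th, g)) { quasi <- TRUE; break }
      if (it %% 5 == 1 || is.null(Iraw)) {
        Iraw <- tryCatch(expected_info(model, th, stats_by_group),
                         error = function(e) NULL)
        if (is.null(Iraw)) break
      }
      D <- pmax(diag(Iraw), 1e-8 * max(diag(Iraw), 1))
      f0 <- nll(th)
      improved <- FALSE
      for (damp_try in 1:8) {
        step <- tryCatch(
          solve(Iraw + mu * diag(D, length(D)), g),
          error = function(e) NULL)
        if (!is.null(step)) {
          cand <- clamp(th + step)
          if (nll(cand) < f0 - 1e-10) {
            th <- cand; improved <- TRUE
            mu <- max(mu / 3, 1e-8)
            break
          }
        }
        mu <- mu * 10
        if (mu > 1e8) break
      }
      iters <- it
      if (!improved) break
      # on ill-conditioned surfaces the damped steps shrink to statistically
      # irrelevant likelihood gains; two consecutive sub-tolerance steps end
      # the fit as quasi-converged (documented numerical choice)
      stalls <- if (f0 - nll(th) < ll_tol) stalls + 1 else 0
      if (stalls >= 2) { quasi <- TRUE; break }
    }
    attr(th, "polish_iters") <- iters
    attr(th, "quasi") <- quasi
    th
  }
  scale <- 1 / pmax(abs(theta0), 0.1)
  run1 <- function(th) {
    # recover from an infeasible start by shrinking toward the declared one
    tries <- 0
    while (nll(th) >= penalty / 2 && tries < 12) {
      th <- clamp(0.5 * th + 0.5 * model$theta0)
      tries <- tries + 1
    }
    if (length(th) >= 40) {
      thp <- polish(th)
      quasi <- isTRUE(attr(thp, "quasi"))
      th <- c(thp)
      g <- -ngr(th)
      if (any(g != 0) && (quasi || grad_ok(th, g))) {
        return(list(par = th, objective = nll(th), convergence = 0L,
                    message = "fisher scoring converged", iterations = 0L))
      }
    }
    stats::nlminb(th, nll, gradient = ngr, lower = model$lower,
                  upper = model$upper, scale = scale,
                  control = list(iter.max = iter_max, eval.max = 3 * iter_max))
  }
  best <- run1(theta0)
  if (starts > 1) {
    jit <- with_local_seed(seed, lapply(seq_len(starts - 1), function(i)
      stats::rnorm(k, 0, 0.1 * pmax(abs(theta0), 0.5))))
    for (i in seq_len(starts - 1)) {
      th <- pmin(pmax(theta0 + jit[[i]], model$lower + 1e-8), model$upper)
      cand <- tryCatch(run1(th), error = function(e) NULL)
      if (!is.null(cand) && cand$objective < best$objective - 1e-8) best <- cand
    }
  }
  theta_hat <- best$par
  names(theta_hat) <- model$labels
  loglik <- -best$objective
  grad <- ngr(theta_hat)
  grad_scaled <- max(abs(grad) * pmax(abs(theta_hat), 1)) / max(1, abs(loglik))
  at_bound <- is.finite(model$lower) & (theta_hat - model$lower < 1e-6)
  converged <- (best$convergence == 0 || grad_scaled < grad_tol) &&
    loglik > -penalty / 2
  info <- vcov_naive <- NULL
  if (se) {
    # observed information = Hessian of the negative loglik (= FD of ngr)
    info <- numeric_hessian(ngr, theta_hat)
    vcov_naive <- tryCatch(chol2inv(chol((info + t(info)) / 2)),
                           error = function(e) {
                             ei <- eigen((info + t(info)) / 2, symmetric = TRUE)
                             pos <- ei$values > max(ei$values) * 1e-10
                             warning("information matrix singular; pseudo-inverse used")
                             ei$vectors[, pos, drop = FALSE] %*%
                               (t(ei$vectors[, pos, drop = FALSE]) / ei$values[pos])
                           })
    dimnames(vcov_naive) <- list(model$labels, model$labels)
  }
  structure(
    list(estimates = theta_hat, loglik = loglik, k = k,
         AIC = -2 * loglik + 2 * k, vcov = vcov_naive, info = info,
         vcov_robust = NULL,
         convergence = list(converged = converged, status = best$convergence,
                            message = best$message, grad_scaled = grad_scaled,
                            iterations = best$iterations,
                            boundary = model$labels[at_bound]),
         model = model, stats_by_group = stats_by_group,
         n = sum(vapply(stats_by_group, function(s) s$n, numeric(1)))),
    class = "twinpaths_fit"
  )
}

#' @export
print.twinpaths_fit <- function(x, ...) {
  cat("FIML fit:", x$k, "free parameters, n =", x$n, "\n")
  cat("  loglik =", format(x$loglik, digits = 10), "  AIC =",
      format(x$AIC, digits = 10), "\n")
  cat("  converged:", x$convergence$converged,
      " (scaled grad ", format(x$convergence$grad_scaled, digits = 3), ")\n")
  if (length(x$convergence$boundary)) {
    cat("  at lower bound:", paste(x$convergence$boundary, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit a `sem_spec` by FIML
#'
#' @param spec A [sem_spec()].
#' @param data Data frame with the spec's observed columns (one row per
#'   independent unit, NA = missing).
#' @param group Column of `data` with group labels for multi-group specs.
#' @param auto_start Improve the declared start values from sample moments
#'   (marginal means/variances and a least-squares projection for latent
#'   means)? Default TRUE.
#' @param ... Passed to [fit_fiml()] (`starts`, `se`, `start`, ...).
#' @return A `twinpaths_fit`.
#' @export
fit_sem <- function(spec, data, group = NULL, auto_start = TRUE, ...) {
  comp <- compile_spec(spec)
  dots <- list(...)
  if (auto_start && is.null(dots$start)) {
    dots$start <- moment_starts(comp, spec, as.data.frame(data))
  }
  do.call(fit_fiml, c(list(model = comp, data = data, group = group), dots))
}

# Heuristic start values from marginal sample moments: observed-variable
# means map to latent means by least squares through the fixed loadings;
# variance parameters start at fractions of the marginal variances.
moment_starts <- function(comp, spec, data) {
  th <- comp$theta0
  obs <- spec$observed
  if (!all(obs %in% names(data))) return(th)  # fit_fiml reports the error
  mbar <- vapply(obs, function(v) mean(data[[v]], na.rm = TRUE), numeric(1))
  vbar <- vapply(obs, function(v) stats::var(data[[v]], na.rm = TRUE), numeric(1))
  mbar[is.na(mbar)] <- 0; vbar[is.na(vbar) | vbar <= 0] <- 1
  mats <- comp$fill(th)[[spec$groups[1]]]
  Lam <- mats$lambda
  loc <- comp$free_locations
  # latent means: min-norm LS solution of Lambda alpha ~ sample means
  al <- loc[loc$matrix == "alpha", , drop = FALSE]
  if (nrow(al) > 0 && qr(Lam)$rank == ncol(Lam)) {
    a_hat <- qr.coef(qr(Lam), mbar)
    a_hat[is.na(a_hat)] <- 0
    for (i in seq_len(nrow(al))) th[[al$label[i]]] <- a_hat[[al$row[i]]]
  }
  # identity-indicator latents (single loading 1): variance of the indicator
  single <- names(which(colSums(Lam != 0) == 1))
  ind_of <- vapply(single, function(l) rownames(Lam)[which(Lam[, l] != 0)], "")
  ps <- loc[loc$matrix == "psi" & loc$row == loc$col, , drop = FALSE]
  for (i in seq_len(nrow(ps))) {
    l <- ps$row[i]
    if (l %in% single) th[[ps$label[i]]] <- max(0.8 * vbar[[ind_of[[l]]]], 1e-4)
  }
  thv <- loc[loc$matrix == "theta" & loc$row == loc$col, , drop = FALSE]
  for (i in seq_len(nrow(thv))) th[[thv$label[i]]] <- max(0.5 * vbar[[thv$row[i]]], 1e-4)
  th
}

# Start vector for a respecified model from a previous fit's estimates:
# matching labels carry over; labels merged across groups take the mean of
# the group-specific estimates; group-suffixed labels fall back to the
# merged estimate.
warm_start <- function(comp, est) {
  th <- comp$theta0
  nms <- names(est)
  for (j in seq_along(comp$labels)) {
    lb <- comp$labels[j]
    if (lb %in% nms) { th[j] <- est[[lb]]; next }
    hit <- nms[startsWith(nms, paste0(lb, "."))]
    if (length(hit)) { th[j] <- mean(unlist(est[hit])); next }
    base <- sub("\\.[^.]+$", "", lb)
    if (base %in% nms) th[j] <- est[[base]]
  }
  pmin(pmax(th, comp$lower + 1e-8), comp$upper)
}

#' Parameter table of a fit
#'
#' @param fit A `twinpaths_fit`.
#' @param robust Use the cluster-robust covariance if it has been attached by
#'   [cluster_robust_vcov()]? Default uses it when present.
#' @return Data frame: label, estimate, se, z, p, 95% CI.
#' @export
fit_parameters <- function(fit, robust = !is.null(fit$vcov_robust)) {
  V <- if (robust) fit$vcov_robust else fit$vcov
  se <- if (is.null(V)) rep(NA_real_, fit$k) else sqrt(pmax(diag(V), 0))
  est <- fit$estimates
  z <- est / se
  data.frame(label = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
             ci_lower = unname(est - 1.96 * se),
             ci_upper = unname(est + 1.96 * se), stringsAsFactors = FALSE)
}

#' Export a fit to JSON and a flat CSV parameter table
#'
#' @param fit A `twinpaths_fit`.
#' @param json_path,csv_path Output paths (NULL skips either).
#' @return Invisibly, the parameter table.
#' @export
export_fit <- function(fit, json_path = NULL, csv_path = NULL) {
  tab <- fit_parameters(fit)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(loglik = fit$loglik, k = fit$k, AIC = fit$AIC,
           converged = fit$convergence$converged,
           grad_scaled = fit$convergence$grad_scaled,
           boundary = fit$convergence$boundary,
           estimates = as.list(fit$estimates)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  invisible(tab)
}

#' Closed-form saturated log-likelihood for complete data
#'
#' The maximum of the multivariate-normal log-likelihood over an
#' unrestricted mean and covariance, attained at the sample mean and the
#' ML (denominator n) covariance: -n/2 (p log 2 pi + log|S| + p).
#'
#' @param Y Complete data matrix.
#' @return Scalar log-likelihood.
#' @export
saturated_loglik <- function(Y) {
  Y <- as.matrix(Y)
  stopifnot(!anyNA(Y))
  n <- nrow(Y); p <- ncol(Y)
  S <- crossprod(sweep(Y, 2, colMeans(Y))) / n
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -n / 2 * (p * log(2 * pi) + ld + p)
}

#' Saturated model spec (all means and covariances free)
#'
#' @param vars Observed variable names.
#' @param data Optional data used only for start values (marginal means and
#'   variances); covariances start at 0.
#' @param groups Group labels.
#' @return A [sem_spec()].
#' @export
saturated_spec <- function(vars, data = NULL, groups = "all") {
  lat <- paste0("f_", vars)
  sp <- sem_spec(vars, lat, groups)
  sp <- sem_par(sp, "lambda", vars, lat, value = 1, free = FALSE)
  mu0 <- rep(0, length(vars)); v0 <- rep(1, length(vars))
  if (!is.null(data)) {
    mu0 <- vapply(vars, function(v) mean(data[[v]], na.rm = TRUE), numeric(1))
    v0 <- vapply(vars, function(v) stats::var(data[[v]], na.rm = TRUE), numeric(1))
  }
  sp <- sem_par(sp, "alpha", lat, value = mu0, free = TRUE)
  sp <- sem_par(sp, "psi", lat, lat, value = v0, free = TRUE, lower = 1e-8)
  pairs <- utils::combn(lat, 2)
  sem_par(sp, "psi", pairs[1, ], pairs[2, ], value = 0, free = TRUE)
}
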