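# If a restricted fit beats its reference (possible when large fits stop at
# quasi-convergence), re-polish the reference warm-started from the
# restricted solution; the reference can only improve.
improve_reference <- function(fit_restricted, reference_fit, data, group,
                              rounds = 2, ...) {
  for (i in seq_len(rounds)) {
    if (fit_restricted$loglik <= reference_fit$loglik + 0.01) break
    spec_ref <- reference_fit$model$spec
    if (is.null(spec_ref)) break
    cand <- fit_sem(spec_ref, data, group = group, se = FALSE,
                    start = warm_start(compile_spec(spec_ref),
                                       fit_restricted$estimates), ...)
    if (cand$loglik > reference_fit$loglik) reference_fit <- cand
  }
  reference_fit
}

#' Chi-square difference (likelihood-ratio) test
#'
#' Tests a restricted model against the full model it is nested in. Nesting
#' is checked by label bookkeeping: every location that is free in the
#' restricted model must also be free in the full model, and the restricted
#' model cannot have more free parameters.
#'
#' @param fit_restricted,fit_full `twinpaths_fit` objects fitted to the same
#'   data.
#' @return List with `chisq` (2 * loglik difference, clipped at 0), `df`
#'   (difference in free-parameter counts) and `p` (chi-square upper tail;
#'   `p = 1` by convention when `df = 0`).
#' @export
lr_test <- function(fit_restricted, fit_full) {
  fr <- fit_restricted$model$free_locations
  ff <- fit_full$model$free_locations
  if (!is.null(fr) && !is.null(ff)) {
    key <- function(d) paste(d$matrix, d$row, d$col, d$group)
    if (!all(key(fr) %in% key(ff))) {
      stop("models are not nested: the restricted model frees locations ",
           "the full model fixes")
    }
  }
  df <- fit_full$k - fit_restricted$k
  if (df < 0) stop("restricted model has more free parameters than the full model")
  stat <- 2 * (fit_full$loglik - fit_restricted$loglik)
  # tolerance reflects the quasi-convergence slack of large ill-conditioned
  # fits; a deficit beyond it means a genuinely better restricted fit
  if (stat < -max(1e-6 * max(1, abs(fit_full$loglik)), 0.05)) {
    stop("restricted model fits better than the full model (delta = ",
         format(stat), "); refit with more starts")
  }
  stat <- max(0, stat)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(chisq = stat, df = df, p = p)
}

#' Wald test of equality of two coefficients
#'
#' `W = (b1 - b2)^2 / (se1^2 + se2^2 - 2 cov12)`, referred to chi-square
#' with 1 df. Used to compare regression coefficients between the male and
#' female groups of a multi-group model.
#'
#' @param b1,b2 Estimates.
#' @param se1,se2 Their standard errors.
#' @param cov12 Sampling covariance of the two estimates (0 for estimates
#'   from independent groups).
#' @return List with `W` and `p`.
#' @export
wald_equality <- function(b1, se1, b2, se2, cov12 = 0) {
  stopifnot(is.finite(b1), is.finite(b2), is.finite(se1), is.finite(se2))
  v <- se1^2 + se2^2 - 2 * cov12
  if (v <= 0) stop("nonpositive variance of the difference")
  W <- (b1 - b2)^2 / v
  list(W = W, p = stats::pchisq(W, 1, lower.tail = FALSE))
}

#' Free constrained parameters guided by exact fit improvements
#'
#' Starting from a constrained model that fits significantly worse than a
#' reference model, repeatedly frees the candidate equality constraint whose
#' release most improves the likelihood (the modification "index" is the
#' exact free-one-refit chi-square change, not the score-test
#' approximation), until the global chi-square difference test against the
#' reference is nonsignificant.
#'
#' @param spec The constrained multi-group [sem_spec()].
#' @param data,group Data and group column as in [fit_sem()].
#' @param candidates Character vector of base labels currently equated
#'   across groups (see [equate_across_groups()]) that may be freed.
#' @param reference_fit Fit of the reference (less constrained) model the
#'   global test is run against.
#' @param alpha Significance level of the stopping rule.
#' @param fit Optional existing fit of `spec` (avoids one refit).
#' @param ... Passed to [fit_sem()].
#' @return List: `log` (data frame of iterations: freed label, delta chisq),
#'   `spec`, `fit` (final), `p` (final global p), `irreducible` (TRUE when
#'   no candidate improved fit but the global test stayed significant).
#' @export
modification_search <- function(spec, data, group, candidates, reference_fit,
                                alpha = 0.05, fit = NULL, ...) {
  if (is.null(fit)) fit <- fit_sem(spec, data, group = group, se = FALSE, ...)
  log <- data.frame(iteration = integer(), freed = character(),
                    delta_chisq = numeric(), p_after = numeric(),
                    stringsAsFactors = FALSE)
  irreducible <- FALSE
  it <- 0
  repeat {
    reference_fit <- improve_reference(fit, reference_fit, data, group, ...)
    gt <- lr_test(fit, reference_fit)
    if (gt$p >= alpha || length(candidates) == 0) break
    it <- it + 1
    trial <- lapply(candidates, function(b) {
      sp2 <- free_across_groups(spec, b)
      f2 <- fit_sem(sp2, data, group = group, se = FALSE,
                    start = warm_start(compile_spec(sp2), fit$estimates), ...)
      list(spec = sp2, fit = f2, dchi = 2 * (f2$loglik - fit$loglik))
    })
    dchis <- vapply(trial, function(t) t$dchi, numeric(1))
    # deterministic tie-break: candidate order is the fixed label order
    best <- which(dchis >= max(dchis) - 1e-10)[1]
    if (dchis[best] <= 1e-8) { irreducible <- TRUE; break }
    spec <- trial[[best]]$spec
    fit <- trial[[best]]$fit
    gt2 <- lr_test(fit, reference_fit)
    log <- rbind(log, data.frame(iteration = it, freed = candidates[best],
                                 delta_chisq = dchis[best], p_after = gt2$p,
                                 stringsAsFactors = FALSE))
    candidates <- candidates[-best]
  }
  list(log = log, spec = spec, fit = fit, p = lr_test(fit, reference_fit)$p,
       irreducible = irreducible)
}
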