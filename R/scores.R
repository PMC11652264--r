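#' Prorated scale score from item responses
#'
#' SDQ subscale and AUDIT scores are the mean of the available items
#' multiplied by the total number of items, so that partially answered
#' scales stay on the full-scale metric. With complete responses this equals
#' the plain item sum.
#'
#' @param item_values Integer (or NA) item responses for one respondent.
#' @param item_count Number of items the scale has (5 for SDQ subscales, 10
#'   for AUDIT-Total, 3 for AUDIT-Consumption, 7 for AUDIT-Problem).
#' @param item_max Maximum value a single item can take (2 for SDQ, 4 for
#'   AUDIT).
#' @param min_prop Minimum proportion of items that must be answered for a
#'   score to be produced; below it the score is NA. Default 0 (any single
#'   item suffices).
#' @param wave Optional wave label used in error messages.
#' @return The prorated score, or NA if too few items are available.
#' @examples
#' compute_scale_score(c(0, 1, 2, 1, 1), 5, 2)  # 5
#' compute_scale_score(c(2, 2, NA, 1, 1), 5, 2) # 7.5
#' @export
compute_scale_score <- function(item_values, item_count, item_max,
                                min_prop = 0, wave = NULL) {
  if (length(item_values) != item_count) {
    stop("expected ", item_count, " items",
         if (!is.null(wave)) paste0(" for wave ", wave), ", got ",
         length(item_values))
  }
  bad <- which(!is.na(item_values) &
                 (item_values < 0 | item_values > item_max))
  if (length(bad)) {
    stop("item ", bad[1], if (!is.null(wave)) paste0(" of wave ", wave),
         " outside [0, ", item_max, "]: ", item_values[bad[1]])
  }
  k <- sum(!is.na(item_values))
  if (k == 0 || k < min_prop * item_count) return(NA_real_)
  mean(item_values, na.rm = TRUE) * item_count
}

#' Residualize a score on age
#'
#' Removes the linear effect of assessment age from a score by ordinary
#' least squares on the complete pairs; rows missing either input keep NA.
#' Used on the AUDIT scores, whose assessment age varies between twins.
#'
#' @param scores Numeric vector, NA allowed.
#' @param ages Numeric vector of the same length, NA allowed.
#' @return Residuals with zero mean and zero sample covariance with age on
#'   the fitted subset; NA where either input is NA.
#' @export
residualize_on_age <- function(scores, ages) {
  stopifnot(length(scores) == length(ages))
  ok <- !is.na(scores) & !is.na(ages)
  if (sum(ok) >= 2 && length(unique(ages[ok])) < 2) {
    stop("degenerate design: all ages identical; mean-center explicitly instead")
  }
  out <- rep(NA_real_, length(scores))
  if (sum(ok) == 0) return(out)
  if (sum(ok) == 1) { out[ok] <- 0; return(out) }
  fit <- stats::lm.fit(cbind(1, ages[ok]), scores[ok])
  out[ok] <- fit$residuals
  out
}

#' Log transform for skewed problem scores
#'
#' `log(score + offset)` with a default offset of 1 so that legitimate zero
#' scores map to zero. Applied to AUDIT-Problem, which is right skewed.
#'
#' @param score Non-negative numeric vector, NA allowed.
#' @param offset Positive shift added before the log; default 1.
#' @return Transformed scores, NA preserved.
#' @export
log_transform_problem_score <- function(score, offset = 1) {
  if (any(score < 0, na.rm = TRUE)) stop("negative score passed to log transform")
  log(score + offset)
}

#' Flag hazardous or harmful drinking
#'
#' AUDIT-Total at or above the recommended cut-off of eight flags hazardous
#' or harmful alcohol use.
#'
#' @param audit_total AUDIT-Total scores in \[0, 40\], NA allowed.
#' @param cutoff Threshold, default 8.
#' @return Logical vector (NA preserved): `TRUE` iff score >= cutoff.
#' @export
flag_hazardous <- function(audit_total, cutoff = 8) {
  if (any(audit_total < 0 | audit_total > 40, na.rm = TRUE)) {
    stop("AUDIT-Total outside [0, 40]")
  }
  audit_total >= cutoff
}
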