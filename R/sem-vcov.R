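# Per-row score vectors and the cluster-robust sandwich covariance.

# n x k matrix of per-row contributions to the gradient of the total
# log-likelihood, evaluated at the fit's estimates.
row_scores <- function(fit) {
  model <- fit$model
  theta <- fit$estimates
  mom <- model$moments(theta)
  dmom <- model_dmoments(model, theta, mom)
  k <- length(theta)
  p <- length(model$observed)
  n_total <- sum(vapply(fit$stats_by_group, function(s) s$n, numeric(1)))
  scores <- matrix(0, n_total, k)
  for (g in names(fit$stats_by_group)) {
    st <- fit$stats_by_group[[g]]
    mu <- mom[[g]]$mu; Sigma <- mom[[g]]$Sigma
    dMu <- dmom[[g]]$dMu; dSig <- dmom[[g]]$dSig
    for (pt in st$patterns) {
      o <- pt$obs
      po <- length(o)
      W <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
      R <- sweep(st$Y[pt$rows, o, drop = FALSE], 2, mu[o])
      lin <- as.vector(outer(o, (o - 1L) * p, "+"))
      dSo <- dSig[, lin, drop = FALSE]                     # k x po^2
      # mean part: r' W dmu_j
      s_mu <- (R %*% W) %*% t(dMu[, o, drop = FALSE])      # n_r x k
      # covariance part: 1/2 (q' dSigma_j q - tr(W dSigma_j)), q = W r
      Q <- R %*% W
      Tq <- Q[, rep(seq_len(po), each = po), drop = FALSE] *
        Q[, rep(seq_len(po), times = po), drop = FALSE]    # n_r x po^2
      tr_term <- drop(dSo %*% as.vector(W))                # k
      s_sig <- 0.5 * (Tq %*% t(dSo) -
                        matrix(tr_term, nrow(R), k, byrow = TRUE))
      scores[st$row_ids[pt$rows], ] <- s_mu + s_sig
    }
  }
  colnames(scores) <- model$labels
  scores
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster-robust (sandwich) covariance of the estimates
#'
#' Computes the sandwich A^-1 B A^-1 with A the observed information
#' (negative Hessian of the total log-likelihood) and B the sum over
#' clusters of outer products of per-cluster score vectors. Use it whenever
#' rows are not independent, e.g. individual twins clustered in pairs.
#'
#' @param fit A converged `twinpaths_fit` fitted with `se = TRUE`.
#' @param cluster_ids Vector of cluster identifiers, one per data row in the
#'   original row order.
#' @return The robust covariance matrix (also attached to a copy of the fit
#'   if you reassign: `fit$vcov_robust <- cluster_robust_vcov(fit, id)`).
#' @export
cluster_robust_vcov <- function(fit, cluster_ids) {
  stopifnot(inherits(fit, "twinpaths_fit"))
  if (is.null(fit$info)) stop("fit was run with se = FALSE; refit with se = TRUE")
  if (!fit$convergence$converged) {
    warning("sandwich covariance computed at a non-converged solution")
  }
  sc <- row_scores(fit)
  if (length(cluster_ids) != nrow(sc)) {
    stop("cluster_ids must have one entry per data row (", nrow(sc), ")")
  }
  cs <- rowsum(sc, group = as.character(cluster_ids))
  if (nrow(cs) < fit$k) {
    warning("fewer clusters (", nrow(cs), ") than free parameters (", fit$k,
            "); sandwich covariance is rank deficient")
  }
  B <- crossprod(cs)
  A_inv <- fit$vcov
  V <- A_inv %*% B %*% A_inv
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(fit$vcov)
  V
}

#' Attach a cluster-robust covariance to a fit
#'
#' Convenience wrapper storing the sandwich covariance inside the fit so
#' that [fit_parameters()] reports robust standard errors.
#'
#' @inheritParams cluster_robust_vcov
#' @return The fit with `$vcov_robust` set.
#' @export
with_robust_vcov <- function(fit, cluster_ids) {
  fit$vcov_robust <- cluster_robust_vcov(fit, cluster_ids)
  fit
}
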