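# Shared fixtures: a small linear-growth spec, random ACE structures, and an
# independent path-tracing oracle for twin pair covariances.

toy_growth_spec <- function(psi_is = 0.2) {
  sp <- sem_spec(c("y1", "y2", "y3"), c("I", "S"))
  sp <- sem_par(sp, "lambda", c("y1", "y2", "y3"), "I", value = 1)
  sp <- sem_par(sp, "lambda", c("y1", "y2", "y3"), "S", value = c(0, 1, 2))
  sp <- sem_par(sp, "psi", c("I", "S"), c("I", "S"), value = c(1, 0.1),
                free = TRUE, lower = 1e-8)
  sp <- sem_par(sp, "psi", "I", "S", value = psi_is, free = TRUE)
  sp <- sem_par(sp, "theta", c("y1", "y2", "y3"), c("y1", "y2", "y3"),
                value = 0.5, free = TRUE, lower = 1e-8)
  sem_par(sp, "alpha", c("I", "S"), value = c(1, 0.3), free = TRUE)
}

draw_mvn <- function(n, mu, Sigma, seed) {
  set.seed(seed)
  p <- length(mu)
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  ev$values[ev$values < 0] <- 0
  Y <- matrix(rnorm(n * p), n, p) %*% t(ev$vectors %*% diag(sqrt(ev$values), p))
  sweep(Y, 2, mu, "+")
}

random_ace_structure <- function(k, modes = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(modes)) modes <- sample(c("direct", "correlated"), k, TRUE)
  L <- function() {
    M <- matrix(rnorm(k * k, 0, 0.4), k)
    M[upper.tri(M)] <- 0
    diag(M) <- abs(diag(M)) + 0.3
    M
  }
  vals <- list(L_A = L(), L_C = L(), L_E = L(),
               b = ifelse(modes == "direct", rnorm(k, 0, 0.3), 0),
               w_A = ifelse(modes == "correlated", rnorm(k, 0, 0.3), 0),
               w_C = ifelse(modes == "correlated", rnorm(k, 0, 0.3), 0),
               w_E = ifelse(modes == "correlated", rnorm(k, 0, 0.3), 0),
               u = abs(rnorm(3, 0.5, 0.2)) + 0.1, means = rnorm(k + 1, 0, 0.5))
  ace_structure(paste0("P", seq_len(k)), "y", modes, vals)
}

# Independent oracle: builds the joint standard-normal latent vector of both
# twins (Cholesky factors A*, C*, E* plus outcome-unique components) with the
# appropriate cross-twin correlations, maps it linearly to the observed
# phenotypes, and returns M K M'. No shared code with implied_pair_cov.
trace_pair_cov <- function(st, zyg, b1 = st$values$b, b2 = st$values$b) {
  v <- st$values
  k <- st$k
  r <- if (startsWith(zyg, "MZ")) 1 else 0.5
  d <- 3 * k + 3
  K <- matrix(0, 2 * d, 2 * d)
  put <- function(i, rho) {
    K[i, i] <<- 1; K[i + d, i + d] <<- 1
    K[i, i + d] <<- rho; K[i + d, i] <<- rho
  }
  for (j in seq_len(k)) { put(j, r); put(k + j, 1); put(2 * k + j, 0) }
  put(3 * k + 1, r); put(3 * k + 2, 1); put(3 * k + 3, 0)
  map_twin <- function(b) {
    P <- cbind(v$L_A, v$L_C, v$L_E, matrix(0, k, 3))
    y <- c(drop(t(b) %*% v$L_A) + v$w_A,
           drop(t(b) %*% v$L_C) + v$w_C,
           drop(t(b) %*% v$L_E) + v$w_E, v$u)
    rbind(P, y)
  }
  M <- rbind(cbind(map_twin(b1), matrix(0, k + 1, d)),
             cbind(matrix(0, k + 1, d), map_twin(b2)))
  M %*% K %*% t(M)
}

# sampling SE of an ML covariance estimate between columns i and j
cov_se <- function(S, i, j, n) sqrt((S[i, i] * S[j, j] + S[i, j]^2) / n)
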