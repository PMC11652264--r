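#' Specify a structural equation model
#'
#' A `sem_spec` holds a parameterized mean/covariance structure, possibly for
#' several groups, in the usual all-y matrix form: observed variables y with
#' loadings Lambda on latent variables eta, latent regressions Beta, latent
#' (residual) covariance Psi, observed residual covariance Theta, latent
#' intercepts alpha and observed intercepts nu. The implied moments are
#'
#'   Sigma = Lambda (I - Beta)^-1 Psi (I - Beta)^-T Lambda^T + Theta
#'   mu    = nu + Lambda (I - Beta)^-1 alpha
#'
#' Every free parameter carries a label; parameters sharing a label are
#' constrained equal (within or across groups).
#'
#' @param observed Character vector of observed variable names.
#' @param latent Character vector of latent variable names.
#' @param groups Character vector of group labels (default a single group).
#' @return A `sem_spec` object.
#' @seealso [sem_par()], [implied_moments()], [fit_sem()]
#' @export
sem_spec <- function(observed, latent, groups = "all") {
  stopifnot(length(observed) > 0, length(latent) > 0,
            !anyDuplicated(c(observed, latent)), !anyDuplicated(groups))
  structure(
    list(observed = observed, latent = latent, groups = groups,
         params = data.frame(matrix = character(), row = character(),
                             col = character(), group = character(),
                             label = character(), free = logical(),
                             value = numeric(), lower = numeric(),
                             upper = numeric(), stringsAsFactors = FALSE)),
    class = "sem_spec"
  )
}

MAT_ROWS <- list(lambda = "observed", beta = "latent", psi = "latent",
                 theta = "observed", alpha = "latent", nu = "observed")
MAT_COLS <- list(lambda = "latent", beta = "latent", psi = "latent",
                 theta = "observed", alpha = NULL, nu = NULL)
SYM_MATS <- c("psi", "theta")

#' Set entries of a model matrix
#'
#' Declares fixed values or free parameters at positions of one model matrix.
#' Vectors `row`, `col`, `value`, `label` are recycled to a common length.
#' `psi` and `theta` are symmetric: entries are stored once and mirrored.
#'
#' @param spec A [sem_spec()].
#' @param matrix One of `"lambda"`, `"beta"`, `"psi"`, `"theta"`, `"alpha"`,
#'   `"nu"`.
#' @param row,col Variable names indexing the entry (no `col` for the mean
#'   vectors `alpha` / `nu`).
#' @param value Fixed value, or start value when `free`.
#' @param free Logical; free parameter (TRUE) or fixed value (FALSE).
#' @param label Optional parameter label. Defaults to
#'   `"<matrix>_<row>[_<col>][.<group>]"` (the group suffix only when the
#'   spec has several groups and the entry is group-specific). Passing the
#'   same label at several locations or groups constrains them equal.
#' @param group Group label(s), or NULL for every group.
#' @param lower,upper Box bounds for free parameters.
#' @return The updated `sem_spec`.
#' @export
sem_par <- function(spec, matrix, row, col = NULL, value = 0, free = FALSE,
                    label = NULL, group = NULL, lower = -Inf, upper = Inf) {
  stopifnot(inherits(spec, "sem_spec"))
  matrix <- match.arg(matrix, names(MAT_ROWS))
  rows_of <- spec[[MAT_ROWS[[matrix]]]]
  cols_of <- if (!is.null(MAT_COLS[[matrix]])) spec[[MAT_COLS[[matrix]]]]
  if (is.null(col)) {
    if (!is.null(cols_of)) stop(matrix, " needs both row and col")
    col <- "1"
  }
  n <- max(length(row), length(col), length(value))
  row <- rep_len(row, n); col <- rep_len(col, n)
  value <- rep_len(value, n); free <- rep_len(free, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (!is.null(label)) label <- rep_len(label, n)
  groups <- if (is.null(group)) spec$groups else group
  stopifnot(all(groups %in% spec$groups), all(row %in% rows_of),
            is.null(cols_of) || all(col %in% cols_of))
  if (matrix %in% SYM_MATS) {   # store lower triangle canonically
    ri <- match(row, rows_of); ci <- match(col, cols_of)
    swap <- ri < ci
    tmp <- row[swap]; row[swap] <- col[swap]; col[swap] <- tmp
  }
  add <- do.call(rbind, lapply(groups, function(g) {
    lab <- if (!is.null(label)) label else {
      base <- if (is.null(cols_of)) paste0(matrix, "_", row)
              else paste0(matrix, "_", row, "_", col)
      if (length(spec$groups) > 1L) paste0(base, ".", g) else base
    }
    data.frame(matrix = matrix, row = row, col = col, group = g,
               label = ifelse(free, lab, NA_character_), free = free,
               value = value, lower = lower, upper = upper,
               stringsAsFactors = FALSE)
  }))
  # later declarations at the same location override earlier ones
  key <- function(d) paste(d$matrix, d$row, d$col, d$group)
  keep <- !key(spec$params) %in% key(add)
  spec$params <- rbind(spec$params[keep, ], add)
  rownames(spec$params) <- NULL
  spec
}

#' @export
print.sem_spec <- function(x, ...) {
  k <- length(unique(stats::na.omit(x$params$label)))
  cat("sem_spec:", length(x$observed), "observed,", length(x$latent),
      "latent,", length(x$groups), "group(s),", k, "free parameters\n")
  invisible(x)
}

#' Constrain parameters equal across groups
#'
#' Merges the group-suffixed labels `<base>.<group>` of each base label into
#' one shared label `<base>`, imposing cross-group equality. [free_across_groups()]
#' undoes this, restoring per-group labels.
#'
#' @param spec A multi-group [sem_spec()].
#' @param base_labels Character vector of label stems (without group suffix).
#' @return The updated spec.
#' @export
equate_across_groups <- function(spec, base_labels) {
  p <- spec$params
  for (b in base_labels) {
    hit <- !is.na(p$label) & p$label %in% paste0(b, ".", spec$groups)
    if (!any(hit)) next
    p$value[hit] <- mean(p$value[hit])
    p$label[hit] <- b
  }
  spec$params <- p
  spec
}

#' @rdname equate_across_groups
#' @export
free_across_groups <- function(spec, base_labels) {
  p <- spec$params
  hit <- !is.na(p$label) & p$label %in% base_labels
  p$label[hit] <- paste0(p$label[hit], ".", p$group[hit])
  spec$params <- p
  spec
}

#' Labels of free parameters, optionally filtered by location
#'
#' @param spec A [sem_spec()].
#' @param matrix,row,col,group Optional filters.
#' @param diagonal For symmetric matrices: TRUE keeps only diagonal entries,
#'   FALSE only off-diagonal, NA (default) both.
#' @return Character vector of unique labels.
#' @export
spec_labels <- function(spec, matrix = NULL, row = NULL, col = NULL,
                        group = NULL, diagonal = NA) {
  p <- spec$params[spec$params$free, ]
  if (!is.null(matrix)) p <- p[p$matrix %in% matrix, ]
  if (!is.null(row)) p <- p[p$row %in% row, ]
  if (!is.null(col)) p <- p[p$col %in% col, ]
  if (!is.null(group)) p <- p[p$group %in% group, ]
  if (!is.na(diagonal)) p <- p[(p$row == p$col) == diagonal, ]
  unique(p$label)
}

# ---- compilation ----------------------------------------------------------

# Compiles a sem_spec into the engine's model interface: start vector,
# bounds, fast matrix fill, moments(), and an analytic-where-possible
# dmoments() (finite differences only for entries of lambda or beta).
compile_spec <- function(spec) {
  p <- length(spec$observed); m <- length(spec$latent)
  pars <- spec$params
  free <- pars[pars$free, , drop = FALSE]
  labels <- unique(free$label)
  k <- length(labels)
  pos <- match(free$label, labels)
  theta0 <- numeric(k); lower <- rep(-Inf, k); upper <- rep(Inf, k)
  for (j in seq_len(k)) {
    rows <- which(pos == j)
    theta0[j] <- free$value[rows[1]]
    lower[j] <- max(free$lower[rows]); upper[j] <- min(free$upper[rows])
  }
  names(theta0) <- labels

  dims <- list(lambda = c(p, m), beta = c(m, m), psi = c(m, m),
               theta = c(p, p), alpha = c(m, 1), nu = c(p, 1))
  templates <- lapply(spec$groups, function(g) {
    mats <- lapply(dims, function(d) array(0, d))
    fx <- pars[!pars$free & pars$group == g, , drop = FALSE]
    for (i in seq_len(nrow(fx))) {
      mt <- fx$matrix[i]
      ri <- match(fx$row[i], spec[[MAT_ROWS[[mt]]]])
      ci <- if (is.null(MAT_COLS[[mt]])) 1L else match(fx$col[i], spec[[MAT_COLS[[mt]]]])
      mats[[mt]][ri, ci] <- fx$value[i]
      if (mt %in% SYM_MATS) mats[[mt]][ci, ri] <- fx$value[i]
    }
    dimnames(mats$lambda) <- list(spec$observed, spec$latent)
    mats
  })
  names(templates) <- spec$groups

  # per group: fill indices (linear index into each matrix, theta position)
  fills <- lapply(spec$groups, function(g) {
    fg <- free[free$group == g, , drop = FALSE]
    pg <- pos[free$group == g]
    out <- list()
    for (mt in names(dims)) {
      sel <- fg$matrix == mt
      if (!any(sel)) next
      d <- dims[[mt]]
      ri <- match(fg$row[sel], spec[[MAT_ROWS[[mt]]]])
      ci <- if (is.null(MAT_COLS[[mt]])) rep(1L, sum(sel))
            else match(fg$col[sel], spec[[MAT_COLS[[mt]]]])
      lin <- ri + (ci - 1L) * d[1]
      tp <- pg[sel]
      if (mt %in% SYM_MATS) {
        off <- ri != ci
        lin <- c(lin, ci[off] + (ri[off] - 1L) * d[1])
        tp <- c(tp, tp[off])
      }
      out[[mt]] <- list(lin = lin, pos = tp, ri = ri, ci = ci, posu = pg[sel])
    }
    out
  })
  names(fills) <- spec$groups

  fill <- function(theta) {
    lapply(spec$groups, function(g) {
      mats <- templates[[g]]
      fg <- fills[[g]]
      for (mt in names(fg)) mats[[mt]][fg[[mt]]$lin] <- theta[fg[[mt]]$pos]
      mats
    }) |> stats::setNames(spec$groups)
  }

  moments1 <- function(mats) {
    Tm <- solve(diag(m) - mats$beta)
    LT <- mats$lambda %*% Tm
    Sigma <- LT %*% mats$psi %*% t(LT) + mats$theta
    list(mu = drop(mats$nu + LT %*% mats$alpha),
         Sigma = (Sigma + t(Sigma)) / 2, LT = LT, Tm = Tm, mats = mats)
  }
  moments <- function(theta) lapply(fill(theta), moments1)

  # theta positions that still require finite differences: free loadings,
  # and any label spanning more than one matrix type (would double count in
  # the analytic accumulation)
  span <- tapply(free$matrix, pos, function(x) length(unique(x)))
  multi <- as.integer(names(span))[span > 1]
  fd_pos <- sort(unique(c(pos[free$matrix == "lambda"], multi)))

  dmoments <- function(theta, mom = NULL) {
    if (is.null(mom)) mom <- moments(theta)
    out <- lapply(spec$groups, function(g) {
      dMu <- matrix(0, k, p); dSig <- matrix(0, k, p * p)
      LT <- mom[[g]]$LT
      fg <- fills[[g]]
      an <- function(mt) if (is.null(fg[[mt]])) NULL else fg[[mt]]
      f <- an("theta")
      if (!is.null(f)) for (i in seq_along(f$ri)) {
        a <- f$ri[i]; b <- f$ci[i]; j <- f$posu[i]
        if (j %in% fd_pos) next
        dSig[j, a + (b - 1L) * p] <- dSig[j, a + (b - 1L) * p] + 1
        if (a != b) dSig[j, b + (a - 1L) * p] <- dSig[j, b + (a - 1L) * p] + 1
      }
      f <- an("psi")
      if (!is.null(f)) for (i in seq_along(f$ri)) {
        a <- f$ri[i]; b <- f$ci[i]; j <- f$posu[i]
        if (j %in% fd_pos) next
        D <- outer(LT[, a], LT[, b])
        if (a != b) D <- D + t(D)
        dSig[j, ] <- dSig[j, ] + as.vector(D)
      }
      f <- an("alpha")
      if (!is.null(f)) for (i in seq_along(f$ri)) {
        j <- f$posu[i]
        if (j %in% fd_pos) next
        dMu[j, ] <- dMu[j, ] + LT[, f$ri[i]]
      }
      f <- an("nu")
      if (!is.null(f)) for (i in seq_along(f$ri)) {
        j <- f$posu[i]
        if (j %in% fd_pos) next
        dMu[j, f$ri[i]] <- dMu[j, f$ri[i]] + 1
      }
      f <- an("beta")
      if (!is.null(f)) {
        mg <- mom[[g]]
        P2 <- LT %*% mg$mats$psi %*% t(mg$Tm)   # Lambda T Psi T'
        Ta <- drop(mg$Tm %*% mg$mats$alpha)
        for (i in seq_along(f$ri)) {
          a <- f$ri[i]; b <- f$ci[i]; j <- f$posu[i]
          if (j %in% fd_pos) next
          D <- outer(LT[, a], P2[, b])
          dSig[j, ] <- dSig[j, ] + as.vector(D + t(D))
          dMu[j, ] <- dMu[j, ] + LT[, a] * Ta[b]
        }
      }
      list(dMu = dMu, dSig = dSig)
    })
    names(out) <- spec$groups
    # finite differences for loadings / regressions (and anything mixed)
    for (j in fd_pos) {
      h <- 1e-6 * max(1, abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      mp <- moments(tp); mm <- moments(tm)
      for (g in spec$groups) {
        out[[g]]$dMu[j, ] <- (mp[[g]]$mu - mm[[g]]$mu) / (2 * h)
        out[[g]]$dSig[j, ] <- as.vector(mp[[g]]$Sigma - mm[[g]]$Sigma) / (2 * h)
      }
    }
    out
  }

  free_locations <- free[, c("matrix", "row", "col", "group", "label")]
  structure(
    list(theta0 = theta0, lower = lower, upper = upper, labels = labels,
         groups = spec$groups, observed = spec$observed,
         moments = moments, dmoments = dmoments, fill = fill,
         free_locations = free_locations, spec = spec),
    class = "fiml_model"
  )
}

#' Filled model matrices at a parameter vector
#'
#' @param spec A [sem_spec()].
#' @param theta Named parameter vector (NULL: start values).
#' @param group Group label.
#' @return List of matrices `lambda`, `beta`, `psi`, `theta`, `alpha`, `nu`.
#' @export
spec_matrices <- function(spec, theta = NULL, group = spec$groups[1]) {
  comp <- compile_spec(spec)
  if (is.null(theta)) theta <- comp$theta0
  comp$fill(theta[comp$labels])[[group]]
}

#' Model-implied moments
#'
#' Evaluates the implied mean vector and covariance matrix of one group at a
#' parameter vector.
#'
#' @param spec A [sem_spec()].
#' @param theta Named parameter vector; NULL uses the declared start values.
#' @param group Group label; default the first group.
#' @return List with `mu` (named numeric) and `Sigma` (matrix).
#' @export
implied_moments <- function(spec, theta = NULL, group = spec$groups[1]) {
  comp <- compile_spec(spec)
  if (is.null(theta)) theta <- comp$theta0
  if (!is.null(names(theta))) theta <- theta[comp$labels]
  stopifnot(length(theta) == length(comp$theta0), !anyNA(theta))
  mom <- comp$moments(theta)[[group]]
  mu <- mom$mu; names(mu) <- spec$observed
  Sigma <- mom$Sigma; dimnames(Sigma) <- list(spec$observed, spec$observed)
  list(mu = mu, Sigma = Sigma)
}

#' Serialize a model spec to YAML (and back)
#'
#' @param spec A [sem_spec()].
#' @param path File path.
#' @return `spec_from_yaml()` returns the reconstructed `sem_spec`.
#' @export
spec_to_yaml <- function(spec, path) {
  obj <- list(observed = spec$observed, latent = spec$latent,
              groups = spec$groups, params = as.list(spec$params))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @export
spec_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  sp <- sem_spec(unlist(obj$observed), unlist(obj$latent), unlist(obj$groups))
  pr <- as.data.frame(lapply(obj$params, unlist), stringsAsFactors = FALSE)
  pr$label <- as.character(pr$label)
  sp$params <- pr
  sp
}
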