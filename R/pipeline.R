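# End-to-end orchestration: simulate (or load) -> preprocess -> growth ->
# phenotypic alcohol regressions -> sex-difference tests -> twin model
# comparison, with versioned artifacts and a hash manifest per run.

#' Pipeline configuration
#'
#' @param out_dir Output directory for run artifacts.
#' @param input_csv Optional existing twin table; NULL simulates one.
#' @param sim Overrides passed to [sim_config()] when simulating.
#' @param outcomes AUDIT outcomes to analyse.
#' @param covariates Covariates of the outcome regressions (stacked-frame
#'   columns; `sex_num` is added automatically for single-group fits).
#' @param alpha Significance level for pruning/tests.
#' @param wave_ages,anchors Growth geometry.
#' @param sex_outcomes Outcomes for which the multi-group sex pipeline runs
#'   (default: all of `outcomes`).
#' @param twin_outcomes Outcomes for which twin model comparison runs.
#' @param max_twin_predictors Cap on predictors entering the twin structure
#'   search (most significant first; the hybrid lattice is exhaustive and
#'   grows as 2^k). Default 4.
#' @param prune Prune nonsignificant covariances after the growth fit?
#' @param refit_per_outcome Re-run pruning for every outcome instead of
#'   sharing the growth structure (slower, closer to a per-outcome rebuild).
#' @param starts Optimizer starts per fit.
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("twinpaths_run_"),
                            input_csv = NULL, sim = list(),
                            outcomes = c("audit_total", "audit_consumption",
                                         "audit_problem"),
                            covariates = "ses", alpha = 0.05,
                            wave_ages = c(4, 7, 9, 9, 11, 16),
                            anchors = c(4, 9),
                            sex_outcomes = outcomes,
                            twin_outcomes = outcomes,
                            max_twin_predictors = 4,
                            prune = TRUE, refit_per_outcome = FALSE,
                            starts = 1, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  path
}

fit_artifact <- function(fit) {
  list(loglik = fit$loglik, k = fit$k, AIC = fit$AIC,
       converged = fit$convergence$converged,
       grad_scaled = fit$convergence$grad_scaled,
       boundary = fit$convergence$boundary,
       estimates = as.list(fit$estimates))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing versioned artifacts into
#' `config$out_dir` (`twins.csv`, `truth.json`, `preprocessed.csv`,
#' `growth_fit.json`, `phenotypic_<outcome>.csv/json`,
#' `sex_test_<outcome>.json`, `twin_<outcome>.json`) plus `manifest.json`
#' with an md5 per artifact. A stage failure writes a `FAILED` marker and
#' stops with a stage-tagged error; identical config and seed reproduce
#' identical artifact hashes.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the output directory (attribute `manifest`).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                            "\n", file = log_path, append = TRUE)
  artifacts <- character()
  stage <- function(name, code) {
    logf("stage", name, "start")
    res <- tryCatch(code, error = function(e) {
      writeLines(paste("FAILED at stage", name, ":", conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
    logf("stage", name, "done")
    res
  }

  # 1 simulate / load -------------------------------------------------------
  sim_out <- stage("simulate", {
    if (is.null(cfg$input_csv)) {
      sc <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
      s <- simulate_dataset(sc, keep_complete = FALSE)
      write_twin_table(s$data, file.path(cfg$out_dir, "twins.csv"))
      tr <- s$truth
      tr$config[c("Tcov", "A", "C", "E", "factor_corr")] <-
        lapply(tr$config[c("Tcov", "A", "C", "E", "factor_corr")],
               function(M) round(unclass(M), 12))
      write_json_artifact(tr[c("config", "implied")],
                          file.path(cfg$out_dir, "truth.json"))
      artifacts <- c(artifacts, "twins.csv", "truth.json")
      s$data
    } else {
      d <- read_twin_table(cfg$input_csv, validate = FALSE)
      write_twin_table(d, file.path(cfg$out_dir, "twins.csv"))
      artifacts <- c(artifacts, "twins.csv")
      d
    }
  })

  # 2 preprocess -------------------------------------------------------------
  pre <- stage("preprocess", {
    d <- preprocess_alcohol(sim_out)
    write_twin_table(d, file.path(cfg$out_dir, "preprocessed.csv"))
    artifacts <- c(artifacts, "preprocessed.csv")
    d
  })

  # 3 growth -----------------------------------------------------------------
  growth <- stage("growth", {
    long <- analysis_frame(pre, covariates = character(), preprocess = FALSE)
    spec <- build_piecewise_lgc(wave_ages = cfg$wave_ages, anchors = cfg$anchors)
    fit <- fit_sem(spec, long, starts = cfg$starts, seed = cfg$seed)
    fit <- with_robust_vcov(fit, long$family_id)
    pr <- if (cfg$prune) {
      prune_nonsignificant_covariances(fit, spec, long, alpha = cfg$alpha,
                                       starts = cfg$starts, seed = cfg$seed)
    } else list(spec = spec, fit = fit, dropped = character(),
                restored = character())
    art <- c(fit_artifact(pr$fit),
             list(dropped_covariances = pr$dropped, restored = pr$restored))
    write_json_artifact(art, file.path(cfg$out_dir, "growth_fit.json"))
    artifacts <- c(artifacts, "growth_fit.json")
    pr
  })

  # 4 phenotypic regressions -------------------------------------------------
  phen <- stage("phenotypic", {
    out <- list()
    for (oc in cfg$outcomes) {
      base_spec <- if (cfg$refit_per_outcome) {
        build_piecewise_lgc(wave_ages = cfg$wave_ages, anchors = cfg$anchors)
      } else growth$spec
      spec <- add_outcome(base_spec, oc, c("sex_num", cfg$covariates))
      fit <- fit_outcome_model(pre, oc, c("sex_num", cfg$covariates),
                               wave_ages = cfg$wave_ages,
                               anchors = cfg$anchors, spec = spec,
                               preprocess = FALSE,
                               starts = cfg$starts, seed = cfg$seed)
      utils::write.csv(fit$standardized,
                       file.path(cfg$out_dir, paste0("phenotypic_", oc, ".csv")),
                       row.names = FALSE)
      write_json_artifact(fit_artifact(fit),
                          file.path(cfg$out_dir, paste0("phenotypic_", oc, ".json")))
      artifacts <- c(artifacts,
                      paste0("phenotypic_", oc, c(".csv", ".json")))
      out[[oc]] <- fit
    }
    out
  })

  # 5 sex differences --------------------------------------------------------
  sex <- stage("sex_test", {
    out <- list()
    for (oc in cfg$sex_outcomes) {
      rep <- sex_difference_pipeline(pre, oc, cfg$covariates,
                                     alpha = cfg$alpha,
                                     wave_ages = cfg$wave_ages,
                                     anchors = cfg$anchors, preprocess = FALSE,
                                     starts = cfg$starts, seed = cfg$seed)
      art <- list(steps = rep$steps, wald = rep$wald,
                  equated_coefficients = rep$equated_coefficients,
                  intercept_residual = rep$intercept_residual[c("chisq", "df",
                                                                "p", "equated")])
      write_json_artifact(art, file.path(cfg$out_dir,
                                         paste0("sex_test_", oc, ".json")))
      artifacts <- c(artifacts, paste0("sex_test_", oc, ".json"))
      out[[oc]] <- rep
    }
    if (length(cfg$sex_outcomes) == 0) {
      write_json_artifact(list(note = "sex tests disabled"),
                          file.path(cfg$out_dir, "sex_test_none.json"))
      artifacts <- c(artifacts, "sex_test_none.json")
    }
    out
  })

  # 6 twin model comparison --------------------------------------------------
  stage("twin", {
    for (oc in cfg$twin_outcomes) {
      fit <- phen[[oc]]
      std <- fit$standardized
      sig <- std$predictor[!is.na(std$p) & std$p < cfg$alpha]
      if (oc %in% names(sex)) {    # significant in either sex also retained
        w <- sex[[oc]]$wald
        sexsig <- vapply(w$coefficient, function(b) {
          est <- sex[[oc]]$fit_se$estimates
          V <- sex[[oc]]$fit_se$vcov_robust
          any(vapply(c("female", "male"), function(g) {
            lb <- paste0(b, ".", g)
            lb %in% names(est) &&
              abs(est[[lb]]) > 1.96 * sqrt(V[lb, lb])
          }, logical(1)))
        }, logical(1))
        sig <- union(sig, sub(".*_(em|cd)_", "\\1_",
                              w$coefficient[sexsig])[grepl("_(em|cd)_",
                                                           w$coefficient[sexsig])])
      }
      sig <- intersect(sig, FACTORS)
      if (length(sig) > cfg$max_twin_predictors) {
        p_of <- std$p[match(sig, std$predictor)]
        sig <- sig[order(p_of)][seq_len(cfg$max_twin_predictors)]
      }
      art_path <- file.path(cfg$out_dir, paste0("twin_", oc, ".json"))
      if (length(sig) == 0) {
        write_json_artifact(list(note = "no significant predictors"), art_path)
        artifacts <- c(artifacts, paste0("twin_", oc, ".json"))
        next
      }
      scores <- compute_factor_scores(fit, pre, predictors = sig, outcome = oc,
                                      preprocess = FALSE)
      search <- structure_search(scores, sig, oc, starts = cfg$starts,
                                 seed = cfg$seed)
      sd_rep <- sex_difference_direct_paths(search$selected, scores,
                                            seed = cfg$seed)
      art <- list(predictors = sig,
                  aic_table = search$table,
                  selected = search$selected_code,
                  shares = as.data.frame(fit_ace_shares(search)),
                  sex_paths = sd_rep$paths, sex_lr = sd_rep$lr)
      write_json_artifact(art, art_path)
      artifacts <- c(artifacts, paste0("twin_", oc, ".json"))
    }
    invisible(NULL)
  })

  files <- file.path(cfg$out_dir, unique(artifacts))
  manifest <- list(seed = cfg$seed,
                   artifacts = stats::setNames(
                     as.list(unname(tools::md5sum(files))),
                     unique(artifacts)))
  write_json_artifact(manifest, file.path(cfg$out_dir, "manifest.json"))
  attr(cfg$out_dir, "manifest") <- manifest
  invisible(cfg$out_dir)
}

fit_ace_shares <- function(search) {
  f <- search$fit
  if (is.null(f$ace)) f$ace <- summarize_ace(f)
  f$ace$shares
}
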