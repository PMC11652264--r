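#' @title Wide twin-pair dataset
#' @description A `twin_dataset` is a validated data frame with one row per
#'   twin pair: `family_id`, `zyg` (MZ / DZss / DZos), per-twin measurement
#'   columns suffixed `_t1` / `_t2`, and family-level covariates. Missing
#'   values are allowed everywhere except `family_id` and `zyg`.
#' @name twin_dataset
NULL

ZYGOSITY_CODES <- c("MZ", "DZss", "DZos")

#' Construct and validate a twin dataset
#'
#' @param df Data frame in the wide pair-per-row layout.
#' @param schema A [default_schema()] describing expected measures.
#' @param validate Check invariants (zygosity codes, same-sex MZ pairs,
#'   score ranges)? Default TRUE.
#' @return The data frame with class `twin_dataset`.
#' @export
twin_dataset <- function(df, schema = default_schema(), validate = TRUE) {
  stopifnot(is.data.frame(df))
  req <- c("family_id", "zyg")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (validate) validate_twin_dataset(df, schema)
  class(df) <- c("twin_dataset", "data.frame")
  df
}

validate_twin_dataset <- function(df, schema = default_schema()) {
  if (nrow(df) == 0) return(invisible(TRUE))
  if (anyNA(df$family_id) || anyNA(df$zyg)) {
    stop("family_id and zyg must be complete")
  }
  bad <- which(!df$zyg %in% ZYGOSITY_CODES)
  if (length(bad)) {
    stop("row ", bad[1], ": unknown zygosity code '", df$zyg[bad[1]], "'")
  }
  if (all(c("sex_t1", "sex_t2") %in% names(df))) {
    ss <- df$zyg %in% c("MZ", "DZss")
    bad <- which(ss & !is.na(df$sex_t1) & !is.na(df$sex_t2) &
                   df$sex_t1 != df$sex_t2)
    if (length(bad)) {
      stop("row ", bad[1], ": ", df$zyg[bad[1]],
           " pair with discordant sexes (", df$sex_t1[bad[1]], ", ",
           df$sex_t2[bad[1]], ")")
    }
  }
  meas <- rbind(schema$waves, schema$alcohol)
  for (i in seq_len(nrow(meas))) {
    for (tw in 1:2) {
      col <- paste0(meas$wave_id[i], "_t", tw)
      if (!col %in% names(df)) next
      v <- df[[col]]
      hi <- meas$item_count[i] * meas$item_max[i]
      bad <- which(!is.na(v) & (v < 0 | v > hi))
      if (length(bad)) {
        stop("row ", bad[1], ": ", col, " = ", v[bad[1]],
             " outside [0, ", hi, "]")
      }
    }
  }
  invisible(TRUE)
}

#' Read / write the wide twin table
#'
#' CSV with a header row, one row per pair, measurement columns suffixed
#' `_t1` / `_t2`. Writing then reading reproduces all numeric values exactly
#' (full precision is kept on write).
#'
#' @param path File path.
#' @param schema A [default_schema()].
#' @param validate Validate invariants on read? Default TRUE.
#' @return `read_twin_table()` returns a `twin_dataset`;
#'   `write_twin_table()` returns `path` invisibly.
#' @export
read_twin_table <- function(path, schema = default_schema(), validate = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  twin_dataset(df, schema, validate = validate)
}

#' @rdname read_twin_table
#' @param dataset A `twin_dataset` (or plain data frame) to write.
#' @export
write_twin_table <- function(dataset, path) {
  df <- as.data.frame(dataset)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- format(df[[j]], digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Stack a pair-per-row table into one row per individual twin
#'
#' Per-twin columns lose their `_t1`/`_t2` suffix; a `twin` column (1/2)
#' records the position and family-level columns are repeated. Used before
#' phenotypic models that treat individuals as rows with family clustering.
#'
#' @param dataset A `twin_dataset`.
#' @return A data frame with `2 * nrow(dataset)` rows.
#' @export
stack_twins <- function(dataset) {
  df <- as.data.frame(dataset)
  t1 <- grep("_t1$", names(df), value = TRUE)
  t2 <- grep("_t2$", names(df), value = TRUE)
  base1 <- sub("_t1$", "", t1)
  base2 <- sub("_t2$", "", t2)
  stopifnot(setequal(base1, base2))
  fam <- setdiff(names(df), c(t1, t2))
  one <- function(tw) {
    cols <- df[paste0(base1, "_t", tw)]
    names(cols) <- base1
    cbind(df[fam], twin = tw, cols)
  }
  out <- rbind(one(1), one(2))
  out[order(match(out$family_id, df$family_id), out$twin), , drop = FALSE]
}

#' Pivot an individual-per-row (long) table back to pair-per-row
#'
#' Deterministic inverse of [stack_twins()]: twin position 1 is the lower
#' within-family `twin` index; per-twin columns regain `_t1` / `_t2`
#' suffixes and family-level columns are taken from twin 1's row.
#'
#' @param long Data frame with `family_id`, `twin` (1/2) and per-twin
#'   columns.
#' @param family_cols Columns constant within family (kept unsuffixed).
#' @return A wide data frame, one row per pair.
#' @export
pack_twins <- function(long, family_cols = intersect(c("zyg", "ses"),
                                                     names(long))) {
  stopifnot(all(c("family_id", "twin") %in% names(long)))
  per_twin <- setdiff(names(long), c("family_id", "twin", family_cols))
  long <- long[order(long$family_id, long$twin), , drop = FALSE]
  fams <- unique(long$family_id)
  one <- function(tw) {
    part <- long[long$twin == tw, c("family_id", per_twin), drop = FALSE]
    names(part)[-1] <- paste0(per_twin, "_t", tw)
    part
  }
  base <- long[long$twin == 1, c("family_id", family_cols), drop = FALSE]
  out <- merge(merge(base, one(1), by = "family_id"), one(2),
               by = "family_id", all.x = TRUE)
  out[match(fams, out$family_id), , drop = FALSE]
}

#' Apply standard preprocessing to a twin dataset
#'
#' Residualizes the three AUDIT scores on exact assessment age (pooled
#' across twins and sexes) and log-transforms AUDIT-Problem before
#' residualization. Problem-behaviour scores are left untouched.
#'
#' @param dataset A `twin_dataset` with `audit_*_t*` and `age22_t*` columns.
#' @param log_problem Log-transform AUDIT-Problem first? Default TRUE.
#' @param log_offset Offset for the log transform.
#' @return The dataset with `audit_total`, `audit_consumption`,
#'   `audit_problem` columns replaced by their age-residualized versions.
#' @export
preprocess_alcohol <- function(dataset, log_problem = TRUE, log_offset = 1) {
  df <- as.data.frame(dataset)
  long <- stack_twins(df)
  for (v in c("audit_total", "audit_consumption", "audit_problem")) {
    if (!v %in% names(long)) next
    y <- long[[v]]
    if (v == "audit_problem" && log_problem) {
      y <- log_transform_problem_score(y, log_offset)
    }
    r <- residualize_on_age(y, long$age22)
    for (tw in 1:2) {
      df[[paste0(v, "_t", tw)]] <- r[long$twin == tw]
    }
  }
  twin_dataset(df, validate = FALSE)
}
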