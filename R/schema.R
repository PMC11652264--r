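#' Measurement schema for the twin cohort
#'
#' Describes the measurement waves the analysis expects: six problem-behaviour
#' waves per trait (parent report at ages 4, 7 and 9; self report at ages 9,
#' 11 and 16) on the 5-item SDQ emotional and conduct subscales, and one
#' alcohol wave at a nominal age of 22 on the AUDIT.
#'
#' @param wave_ages Numeric vector of length 6, the (average) ages at the six
#'   problem waves in years. Defaults to the nominal ages 4, 7, 9, 9, 11, 16.
#' @param alcohol_age Nominal age in years of the alcohol assessment.
#' @return An object of class `measurement_schema`: a list with a `waves`
#'   data frame (wave_id, trait, rater, age, item_count, item_max) and the
#'   column naming conventions used by [read_twin_table()].
#' @examples
#' sch <- default_schema()
#' subset(sch$waves, trait == "emotional")
#' @export
default_schema <- function(wave_ages = c(4, 7, 9, 9, 11, 16), alcohol_age = 22) {
  stopifnot(length(wave_ages) == 6, !is.unsorted(wave_ages))
  raters <- c("parent", "parent", "parent", "self", "self", "self")
  tag <- paste0(substr(raters, 1, 1), wave_ages)   # p4 p7 p9 s9 s11 s16
  waves <- do.call(rbind, lapply(c("emotional", "conduct"), function(tr) {
    pre <- if (tr == "emotional") "em" else "cd"
    data.frame(
      wave_id = paste0(pre, "_", tag), trait = tr, rater = raters,
      age = wave_ages, item_count = 5L, item_max = 2L,
      stringsAsFactors = FALSE
    )
  }))
  alcohol <- data.frame(
    wave_id = c("audit_total", "audit_consumption", "audit_problem"),
    trait = "alcohol", rater = "self", age = alcohol_age,
    item_count = c(10L, 3L, 7L), item_max = 4L, stringsAsFactors = FALSE
  )
  structure(
    list(waves = waves, alcohol = alcohol,
         wave_ages = wave_ages, alcohol_age = alcohol_age),
    class = "measurement_schema"
  )
}

#' @export
print.measurement_schema <- function(x, ...) {
  cat("Measurement schema:", nrow(x$waves), "problem waves,",
      nrow(x$alcohol), "alcohol scores\n")
  print(rbind(x$waves, x$alcohol), row.names = FALSE)
  invisible(x)
}

# Maximum attainable scale score per wave row (prorated scores live in
# [0, item_count * item_max]).
scale_max <- function(schema_row) schema_row$item_count * schema_row$item_max

#' Data dictionary for the wide twin table
#'
#' One row per expected column of the pair-per-row CSV layout: measurement
#' columns are suffixed `_t1` / `_t2` for the two twin positions.
#'
#' @param schema A [default_schema()] object.
#' @return A data frame with columns `column`, `description`, `range`.
#' @export
twin_data_dictionary <- function(schema = default_schema()) {
  meas <- rbind(schema$waves, schema$alcohol)
  per_twin <- c(meas$wave_id, "age22", "sex")
  desc <- c(
    paste0(meas$trait, " score, ", meas$rater, " report, age ", meas$age),
    "exact age at alcohol assessment (years)", "sex (male/female)"
  )
  rng <- c(paste0("[0, ", meas$item_count * meas$item_max, "]"),
           "positive", "male|female")
  cols <- data.frame(
    column = c("family_id", "zyg",
               paste0(rep(per_twin, each = 2), "_t", 1:2), "ses"),
    description = c("family identifier", "zygosity (MZ/DZss/DZos)",
                    rep(desc, each = 2), "family socioeconomic status (z)"),
    range = c("unique", "MZ|DZss|DZos", rep(rng, each = 2), "real"),
    stringsAsFactors = FALSE
  )
  cols
}
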