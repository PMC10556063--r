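#' Interquartile-range threshold of compliance
#'
#' Computes the cohort-level cutoff below which a species' Benford R-squared
#' is declared non-compliant: `threshold = Q1 - q * IQR`, with `Q1`/`Q3` the
#' lower and upper quartiles of the defined R-squared values and
#' `IQR = Q3 - Q1`. This is the classical lower outer fence used in boxplot
#' outlier screening; `q = 1.5` is the conventional coefficient.
#'
#' @param data A data frame containing an `r_squared` column (NAs allowed and
#'   ignored), or a bare numeric vector of R-squared values.
#' @param q Positive coefficient placing the fence; default 1.5.
#' @param quantile_type Quartile convention passed to [stats::quantile()];
#'   default 7 (linear interpolation between order statistics, the convention
#'   shared by R's default and spreadsheet `PERCENTILE` functions). Recorded
#'   in the output because it shifts the fence on small cohorts.
#'
#' @return A one-row tibble: `q1`, `q3`, `iqr`, `q`, `threshold`,
#'   `n_defined`, `quantile_type`. The threshold may be negative, in which
#'   case no defined R-squared can fail it.
#'
#' @examples
#' compliance_threshold(c(0, 0.25, 0.5, 0.75, 1))
#' @export
compliance_threshold <- function(data, q = 1.5, quantile_type = 7) {
  r2 <- if (is.data.frame(data)) {
    if (!"r_squared" %in% names(data)) {
      abort("`data` must contain an `r_squared` column.")
    }
    data$r_squared
  } else if (is.numeric(data)) {
    data
  } else {
    abort("`data` must be a data frame with an `r_squared` column or a numeric vector.")
  }
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0) {
    abort("`q` must be a single non-negative number.")
  }
  r2 <- r2[!is.na(r2)]
  if (length(r2) < 4L) {
    abort(paste(
      "The IQR method needs at least 4 defined R-squared values to place",
      "quartiles; this cohort has", length(r2), "- audit more species."
    ))
  }
  qs <- quantile(r2, c(0.25, 0.75), type = quantile_type, names = FALSE)
  iqr <- qs[2] - qs[1]
  tibble(
    q1 = qs[1], q3 = qs[2], iqr = iqr, q = q,
    threshold = qs[1] - q * iqr,
    n_defined = length(r2), quantile_type = as.integer(quantile_type)
  )
}

#' Classify per-species Benford compliance
#'
#' Applies the IQR threshold of compliance to a cohort of per-species
#' R-squared values: a species passes when its R-squared is defined and
#' greater than or equal to the threshold (equality passes), and fails
#' otherwise. Species whose R-squared is undefined (constant digit
#' frequencies) fail with an explicit reason, since an undefined fit cannot
#' demonstrate compliance.
#'
#' @param data A data frame with one row per species carrying `species_id`
#'   and `r_squared` (NA where undefined); extra columns such as `n_sites`
#'   are carried through.
#' @inheritParams compliance_threshold
#'
#' @return The input tibble with `passed` (logical) and `reason` (why a
#'   species failed; NA for passes) appended, and the one-row threshold
#'   tibble attached as attribute `"threshold"` (also retrievable with
#'   [compliance_threshold()]).
#'
#' @export
classify_compliance <- function(data, q = 1.5, quantile_type = 7) {
  if (!is.data.frame(data) || !all(c("species_id", "r_squared") %in% names(data))) {
    abort("`data` must have `species_id` and `r_squared` columns.")
  }
  if (anyDuplicated(data$species_id)) {
    dup <- unique(data$species_id[duplicated(data$species_id)])
    abort(sprintf("Duplicate species_id(s): %s.", paste(utils::head(dup, 5), collapse = ", ")))
  }
  thr <- compliance_threshold(data, q = q, quantile_type = quantile_type)
  out <- as_tibble(data) |>
    dplyr::mutate(
      passed = !is.na(.data$r_squared) & .data$r_squared >= thr$threshold,
      reason = dplyr::case_when(
        is.na(.data$r_squared) ~ "undefined R-squared",
        .data$r_squared < thr$threshold ~
          sprintf("R-squared below threshold of compliance (%.4f)", thr$threshold),
        TRUE ~ NA_character_
      )
    )
  attr(out, "threshold") <- thr
  out
}
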