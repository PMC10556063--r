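#' Audit a monitoring dataset against Benford's law
#'
#' Runs the digit-compliance stage of the workflow on a long-format
#' occurrence table: pools all positive abundances for a whole-dataset
#' first-digit test, computes each species' Benford R-squared, and
#' classifies species as compliant or not with the IQR threshold of
#' compliance. Species that never occur with positive abundance are excluded
#' beforehand (see [species_exclusions()]).
#'
#' @param records Occurrence records (site_id, survey_id, species_id,
#'   abundance), e.g. from [read_monitoring_table()] or
#'   [simulate_monitoring()].
#' @inheritParams compliance_threshold
#' @inheritParams benford_r_squared
#' @inheritParams summarize_species
#'
#' @return An object of class `benford_audit`, a list with:
#' \describe{
#'   \item{whole}{whole-dataset digit distribution, its R-squared row and an
#'     advisory flag against the R-squared > 0.85 credibility guideline.}
#'   \item{species}{per-species tibble: species_id, n_values, n_sites,
#'     r_squared, passed, reason.}
#'   \item{threshold}{one-row IQR threshold tibble.}
#'   \item{excluded}{non-occurring species report.}
#'   \item{params}{the audit parameters.}
#' }
#' Use [tidy()] for the species table, [glance()] for a one-row summary and
#' [autoplot()] for the digit-distribution figure.
#'
#' @examples
#' sim <- simulate_monitoring(n_species = 12, seed = 1)
#' audit <- benford_audit(sim$records)
#' glance(audit)
#' @export
benford_audit <- function(records, q = 1.5,
                          method = c("correlation", "expected"),
                          values = c("record", "site_total"),
                          quantile_type = 7) {
  method <- match.arg(method)
  values <- match.arg(values)
  summary <- summarize_species(records, values = values)
  pooled <- unlist(summary$abundances)
  whole_dist <- digit_distribution(pooled)
  whole_r2 <- benford_r_squared(whole_dist, method = method)
  species <- summary |>
    dplyr::mutate(
      r_squared = purrr::map_dbl(
        .data$abundances,
        function(v) benford_r_squared(v, method = method)$r_squared
      )
    ) |>
    dplyr::select("species_id", "n_records", "n_values", "n_sites", "r_squared")
  classified <- classify_compliance(species, q = q, quantile_type = quantile_type)
  structure(
    list(
      whole = list(
        distribution = whole_dist,
        r_squared = whole_r2,
        high_credibility = isTRUE(whole_r2$r_squared > 0.85)
      ),
      species = classified,
      threshold = attr(classified, "threshold"),
      excluded = attr(summary, "excluded"),
      params = list(q = q, method = method, values = values,
                    quantile_type = quantile_type)
    ),
    class = "benford_audit"
  )
}

#' @export
print.benford_audit <- function(x, ...) {
  cat("Benford compliance audit\n")
  cat(sprintf("  whole dataset: n = %d values, R-squared = %.4f%s\n",
              x$whole$r_squared$n_values,
              x$whole$r_squared$r_squared,
              if (x$whole$high_credibility)
                " (above the 0.85 high-credibility guideline)" else ""))
  cat(sprintf("  species tested: %d (excluded for non-occurrence: %d)\n",
              nrow(x$species), nrow(x$excluded)))
  cat(sprintf("  threshold of compliance: %.4f (Q1 %.4f, IQR %.4f, q %.2f)\n",
              x$threshold$threshold, x$threshold$q1, x$threshold$iqr,
              x$threshold$q))
  cat(sprintf("  passed: %d, failed: %d\n",
              sum(x$species$passed), sum(!x$species$passed)))
  invisible(x)
}

#' @rdname benford_audit
#' @param x A `benford_audit` object.
#' @param ... Unused.
#' @export
tidy.benford_audit <- function(x, ...) {
  x$species
}

#' @rdname benford_audit
#' @export
glance.benford_audit <- function(x, ...) {
  tibble(
    n_species = nrow(x$species),
    n_excluded = nrow(x$excluded),
    n_passed = sum(x$species$passed),
    n_failed = sum(!x$species$passed),
    threshold = x$threshold$threshold,
    q = x$threshold$q,
    whole_r_squared = x$whole$r_squared$r_squared,
    whole_n_values = x$whole$r_squared$n_values,
    whole_high_credibility = x$whole$high_credibility
  )
}
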