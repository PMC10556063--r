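#' Contingency table at a candidate occurrence-site threshold
#'
#' Cross-tabulates a cohort of compliance-classified species against one
#' candidate minimum number of occurrence sites. Site count is the
#' predictor, Benford compliance the truth label:
#' `a` = at/above the candidate and compliant (true positive),
#' `b` = at/above and non-compliant (false positive),
#' `c` = below and compliant (false negative),
#' `d` = below and non-compliant (true negative).
#'
#' @param data A data frame with `n_sites` (non-negative integer) and
#'   `passed` (logical compliance label) columns, e.g. from
#'   [classify_compliance()] joined with site counts, or [tidy()] of a
#'   [benford_audit()].
#' @param candidate A single positive integer candidate threshold.
#' @param comparator `">="` (default) counts a species with exactly the
#'   candidate number of sites as passing the site threshold; `">"` is the
#'   strict alternative.
#'
#' @return A one-row tibble: `candidate`, `a`, `b`, `c`, `d`. Cells sum to
#'   the cohort size.
#' @export
contingency_at <- function(data, candidate, comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  check_scan_input(data)
  if (!is.numeric(candidate) || length(candidate) != 1L ||
      !is.finite(candidate) || candidate < 1 || candidate != trunc(candidate)) {
    abort("`candidate` must be a single positive integer.")
  }
  above <- if (comparator == ">=") data$n_sites >= candidate else data$n_sites > candidate
  tibble(
    candidate = as.integer(candidate),
    a = sum(above & data$passed),
    b = sum(above & !data$passed),
    c = sum(!above & data$passed),
    d = sum(!above & !data$passed)
  )
}

#' Sensitivity, specificity, TSS and overall accuracy
#'
#' Skill metrics of a 2x2 species contingency table:
#' sensitivity `a/(a+c)`, specificity `d/(b+d)`, true skill statistic
#' `TSS = sensitivity + specificity - 1` and overall accuracy
#' `(a+d)/(a+b+c+d)`. TSS ranges over \[-1, 1\]; 1 is perfect
#' discrimination, 0 no better than chance.
#'
#' @param data A data frame with integer columns `a`, `b`, `c`, `d` (one or
#'   more rows, e.g. a whole candidate scan).
#'
#' @return The input with `sensitivity`, `specificity`, `tss`,
#'   `overall_accuracy` and `defined` appended. Rows where one compliance
#'   class is absent (`a + c == 0` or `b + d == 0`) have undefined metrics:
#'   `defined` is FALSE and the metric columns are NA so scans can skip them.
#' @export
skill_metrics <- function(data) {
  if (!is.data.frame(data) || !all(c("a", "b", "c", "d") %in% names(data))) {
    abort("`data` must have columns a, b, c, d.")
  }
  cells <- data[c("a", "b", "c", "d")]
  if (any(unlist(cells) < 0)) {
    abort("Contingency cells must be non-negative counts.")
  }
  n <- data$a + data$b + data$c + data$d
  defined <- (data$a + data$c) > 0 & (data$b + data$d) > 0
  sens <- ifelse(defined, data$a / (data$a + data$c), NA_real_)
  spec <- ifelse(defined, data$d / (data$b + data$d), NA_real_)
  as_tibble(data) |>
    dplyr::mutate(
      sensitivity = sens,
      specificity = spec,
      tss = sens + spec - 1,
      overall_accuracy = ifelse(defined, (data$a + data$d) / n, NA_real_),
      defined = defined
    )
}

#' Scan candidate thresholds for the minimum number of occurrence sites
#'
#' Evaluates every candidate minimum occurrence-site count against the
#' cohort's compliance labels and selects the smallest candidate at which
#' the true skill statistic first attains its maximum — the point at which
#' site count best discriminates Benford-compliant from non-compliant
#' species, read as the minimum number of occurrence sites to require before
#' species distribution modelling.
#'
#' @param data A data frame with `n_sites` and `passed` columns (e.g.
#'   [tidy()] of a [benford_audit()]), or a `benford_audit` object.
#' @param candidates Integer candidate thresholds to evaluate; default all
#'   integers from 1 to `max(n_sites) + 1`, which realises every achievable
#'   contingency table.
#' @inheritParams contingency_at
#'
#' @return An object of class `occurrence_scan`: a list with `scan` (one row
#'   per candidate with contingency cells, skill metrics and a `selected`
#'   flag), `selected` (one-row tibble for the chosen threshold) and
#'   `params`. Candidates with undefined metrics are retained in the table
#'   but excluded from maximisation. Use [tidy()], [glance()], [autoplot()].
#'
#' @examples
#' cohort <- tibble::tibble(n_sites = c(30, 25, 10, 5),
#'                          passed = c(TRUE, TRUE, FALSE, FALSE))
#' scan_occurrence_threshold(cohort)
#' @export
scan_occurrence_threshold <- function(data, candidates = NULL,
                                      comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  if (inherits(data, "benford_audit")) {
    data <- data$species
  }
  check_scan_input(data)
  if (nrow(data) < 2L) {
    abort("Threshold scanning needs at least 2 classified species.")
  }
  if (all(data$passed) || !any(data$passed)) {
    abort(paste(
      "Threshold determination requires both compliant and non-compliant",
      "species; this cohort has a single compliance class, so no candidate",
      "yields a defined TSS."
    ))
  }
  if (is.null(candidates)) {
    candidates <- seq_len(max(data$n_sites) + 1L)
  }
  if (length(candidates) == 0L || any(candidates < 1 | candidates != trunc(candidates))) {
    abort("`candidates` must be positive integers.")
  }
  candidates <- sort(unique(as.integer(candidates)))
  scan <- purrr::map(candidates, contingency_at, data = data,
                     comparator = comparator) |>
    purrr::list_rbind() |>
    skill_metrics()
  usable <- which(scan$defined)
  if (length(usable) == 0L) {
    abort("No candidate yields a defined TSS for this cohort.")
  }
  max_tss <- max(scan$tss[usable])
  sel_idx <- usable[scan$tss[usable] >= max_tss - 1e-12][1]
  scan$selected <- seq_len(nrow(scan)) == sel_idx
  structure(
    list(
      scan = scan,
      selected = scan[sel_idx, ],
      params = list(comparator = comparator, n_species = nrow(data),
                    n_candidates = length(candidates))
    ),
    class = "occurrence_scan"
  )
}

check_scan_input <- function(data) {
  if (!is.data.frame(data) || !all(c("n_sites", "passed") %in% names(data))) {
    abort("`data` must have `n_sites` and `passed` columns.")
  }
  if (nrow(data) == 0L) {
    abort("`data` has no species.")
  }
  if (any(is.na(data$passed))) {
    abort("`passed` must not contain NA; classify compliance first.")
  }
  invisible(data)
}

#' @export
print.occurrence_scan <- function(x, ...) {
  sel <- x$selected
  cat("Minimum occurrence-site threshold scan\n")
  cat(sprintf("  species: %d, candidates: %d (comparator %s)\n",
              x$params$n_species, x$params$n_candidates, x$params$comparator))
  cat(sprintf("  selected minimum: %d sites\n", sel$candidate))
  cat(sprintf("  TSS %.3f (sensitivity %.3f, specificity %.3f), accuracy %.3f\n",
              sel$tss, sel$sensitivity, sel$specificity, sel$overall_accuracy))
  cat(sprintf("  advisory: TSS %s the 0.6 guideline commonly taken as acceptable\n",
              if (sel$tss > 0.6) "exceeds" else "does not exceed"))
  invisible(x)
}

#' @rdname scan_occurrence_threshold
#' @param x An `occurrence_scan` object.
#' @param ... Unused.
#' @export
tidy.occurrence_scan <- function(x, ...) {
  x$scan
}

#' @rdname scan_occurrence_threshold
#' @export
glance.occurrence_scan <- function(x, ...) {
  sel <- x$selected
  tibble(
    selected_threshold = sel$candidate,
    tss = sel$tss,
    sensitivity = sel$sensitivity,
    specificity = sel$specificity,
    overall_accuracy = sel$overall_accuracy,
    tss_above_guideline = sel$tss > 0.6,
    n_species = x$params$n_species,
    comparator = x$params$comparator
  )
}
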