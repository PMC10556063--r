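#' Read a long-format monitoring table
#'
#' Reads a delimited text file with one row per site x survey x species
#' observation carrying an abundance count, the layout national monitoring
#' programmes typically export. Lines starting with `#` are treated as
#' metadata comments (the package's own writers emit such headers).
#'
#' @param file Path to a delimited text file with a header row.
#' @param columns Named character vector mapping the roles `site`, `survey`,
#'   `species` and `abundance` to column names in the file.
#' @param delim Field delimiter; `","` by default, use `"\t"` for TSV.
#' @param mode `"strict"` (default) aborts on the first malformed abundance;
#'   `"permissive"` drops offending rows with a message naming them.
#' @param allow_fractional Accept positive non-integer abundances (e.g.
#'   densities). By default abundances must be whole counts of individuals.
#'
#' @return A tibble of occurrence records with columns `site_id`,
#'   `survey_id`, `species_id` (character) and `abundance` (numeric,
#'   non-negative).
#'
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("site,survey,species,abundance",
#'              "s1,2008,minnow,12", "s2,2008,minnow,0"), path)
#' read_monitoring_table(path, columns = c(site = "site", survey = "survey",
#'                                         species = "species",
#'                                         abundance = "abundance"))
#' @export
read_monitoring_table <- function(file,
                                  columns = c(site = "site_id",
                                              survey = "survey_id",
                                              species = "species_id",
                                              abundance = "abundance"),
                                  delim = ",",
                                  mode = c("strict", "permissive"),
                                  allow_fractional = FALSE) {
  mode <- match.arg(mode)
  if (!file.exists(file)) {
    abort(sprintf("Input file does not exist: %s", file))
  }
  roles <- c("site", "survey", "species", "abundance")
  if (!all(roles %in% names(columns))) {
    abort(sprintf(
      "`columns` must map all of %s; missing: %s.",
      paste(roles, collapse = ", "),
      paste(setdiff(roles, names(columns)), collapse = ", ")
    ))
  }
  raw <- readr::read_delim(
    file, delim = delim, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0L) {
    abort(sprintf("Input file %s contains a header but no data rows.", file))
  }
  missing_cols <- setdiff(unname(columns[roles]), names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "Input file %s lacks mapped column(s): %s. Available: %s.",
      file, paste(missing_cols, collapse = ", "),
      paste(names(raw), collapse = ", ")
    ))
  }
  out <- tibble(
    site_id = raw[[columns[["site"]]]],
    survey_id = raw[[columns[["survey"]]]],
    species_id = raw[[columns[["species"]]]],
    abundance_raw = raw[[columns[["abundance"]]]]
  )
  abundance <- suppressWarnings(as.numeric(out$abundance_raw))
  bad <- is.na(abundance) | abundance < 0 |
    (!allow_fractional & is.finite(abundance) & abundance != trunc(abundance))
  if (any(bad)) {
    rows <- which(bad)
    desc <- sprintf(
      "row %d: %s column has invalid abundance %s",
      rows, columns[["abundance"]],
      vapply(out$abundance_raw[rows], function(v) {
        if (is.na(v)) "NA" else sprintf("\"%s\"", v)
      }, character(1))
    )
    if (mode == "strict") {
      abort(c("Malformed abundance value(s):", utils::head(desc, 5)))
    }
    inform(c(sprintf("Dropping %d malformed row(s):", length(rows)),
             utils::head(desc, 5)))
    out <- out[!bad, ]
    abundance <- abundance[!bad]
  }
  out$abundance <- abundance
  out$abundance_raw <- NULL
  out
}

#' Summarise occurrence records per species
#'
#' Builds the per-species view the Benford audit works on: the positive
#' abundance values (zero-abundance rows carry no leading digit and are
#' removed) and the number of distinct occurrence sites, i.e. sites where the
#' species was recorded at least once with positive abundance, pooled over
#' the full time span of the table. Species that never occur with positive
#' abundance are excluded from the summary and reported via
#' [species_exclusions()].
#'
#' @param records A data frame of occurrence records with columns `site_id`,
#'   `survey_id`, `species_id` and `abundance` (as returned by
#'   [read_monitoring_table()] or [simulate_monitoring()]).
#' @param values `"record"` (default) feeds every positive per-record
#'   abundance to the digit audit; `"site_total"` first sums abundance per
#'   site and species and audits the per-site totals instead.
#'
#' @return A tibble with one row per retained species: `species_id`,
#'   `n_records` (input rows), `n_values` (positive values retained for digit
#'   extraction), `n_sites` (distinct occurrence sites) and `abundances`
#'   (list-column of the positive values). The excluded (non-occurring)
#'   species are attached as attribute `"excluded"`.
#'
#' @export
summarize_species <- function(records, values = c("record", "site_total")) {
  values <- match.arg(values)
  needed <- c("site_id", "species_id", "abundance")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    abort("`records` must be a data frame with site_id, species_id and abundance columns.")
  }
  if (nrow(records) == 0L) {
    abort("`records` is empty; nothing to summarise.")
  }
  if (any(!is.finite(records$abundance) | records$abundance < 0)) {
    abort("Abundances must be finite and non-negative; run read_monitoring_table() first.")
  }
  per_species <- records |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      n_sites = dplyr::n_distinct(.data$site_id[.data$abundance > 0]),
      .groups = "drop"
    )
  pos <- dplyr::filter(records, .data$abundance > 0)
  if (values == "site_total") {
    pos <- pos |>
      dplyr::group_by(.data$species_id, .data$site_id) |>
      dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")
  }
  vals <- pos |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      n_values = dplyr::n(),
      abundances = list(.data$abundance),
      .groups = "drop"
    )
  out <- per_species |>
    dplyr::left_join(vals, by = "species_id") |>
    dplyr::arrange(.data$species_id)
  excluded <- out |>
    dplyr::filter(is.na(.data$n_values)) |>
    dplyr::transmute(.data$species_id, .data$n_records,
                     reason = "non-occurrence (no positive abundance record)")
  out <- out |>
    dplyr::filter(!is.na(.data$n_values)) |>
    dplyr::mutate(n_values = as.integer(.data$n_values)) |>
    dplyr::select("species_id", "n_records", "n_values", "n_sites", "abundances")
  attr(out, "excluded") <- excluded
  attr(out, "values") <- values
  out
}

#' Species excluded from an audit for non-occurrence
#'
#' @param summary A species summary from [summarize_species()] or an audit
#'   from [benford_audit()].
#' @return A tibble of excluded species with the exclusion reason.
#' @export
species_exclusions <- function(summary) {
  if (inherits(summary, "benford_audit")) {
    return(summary$excluded)
  }
  attr(summary, "excluded") %||%
    abort("No exclusion report attached; pass a summarize_species() result.")
}
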