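# Independent oracles, deliberately implemented by different routes than the
# package: repeated division instead of string normalisation, normal
# equations instead of cor(), hand interpolation instead of quantile(), and
# exhaustive enumeration instead of the package's scan.

benford_probs <- log10(1 + 1 / (1:9))

oracle_leading_digit <- function(x) {
  vapply(x, function(v) {
    while (v >= 10) v <- v / 10
    while (v < 1) v <- v * 10
    as.integer(floor(v))
  }, integer(1))
}

# OLS simple linear regression of y on x via the normal equations.
oracle_ols_r2 <- function(y, x) {
  n <- length(y)
  b1 <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  b0 <- mean(y) - b1 * mean(x)
  resid <- y - (b0 + b1 * x)
  1 - sum(resid^2) / sum((y - mean(y))^2)
}

# Linear interpolation between closest order statistics: h = (n-1)p + 1.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# Brute-force argmax of TSS over every candidate threshold; smallest
# candidate attaining the maximum (ties closer than 1e-9 are equal, far
# looser than any distinct rational gap at <= 50 species).
oracle_scan <- function(n_sites, passed, comparator = ">=") {
  candidates <- seq_len(max(n_sites) + 1L)
  tss <- vapply(candidates, function(cand) {
    above <- if (comparator == ">=") n_sites >= cand else n_sites > cand
    a <- sum(above & passed); b <- sum(above & !passed)
    c_ <- sum(!above & passed); d <- sum(!above & !passed)
    if (a + c_ == 0 || b + d == 0) return(NA_real_)
    a / (a + c_) + d / (b + d) - 1
  }, numeric(1))
  best <- max(tss, na.rm = TRUE)
  sel <- candidates[which(!is.na(tss) & tss >= best - 1e-9)[1]]
  list(selected = sel, tss = best)
}

make_records <- function(site, species, abundance, survey = "v1") {
  tibble::tibble(site_id = site, survey_id = survey, species_id = species,
                 abundance = abundance)
}

write_records_csv <- function(records, path = tempfile(fileext = ".csv")) {
  readr::write_csv(records, path)
  path
}
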