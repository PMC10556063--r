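test_that("contingency cells tally species by site count and compliance", {
  cohort <- tibble::tibble(n_sites = c(30L, 25L, 10L, 5L),
                           passed = c(TRUE, FALSE, TRUE, FALSE))
  tab <- contingency_at(cohort, 20)
  expect_identical(unlist(tab[c("a", "b", "c", "d")]),
                   c(a = 1L, b = 1L, c = 1L, d = 1L))

  # candidate 1: every species is at or above it
  t1 <- contingency_at(cohort, 1)
  expect_identical(t1$c + t1$d, 0L)
  # candidate beyond the range: nothing passes the site threshold
  t99 <- contingency_at(cohort, 99)
  expect_identical(t99$a + t99$b, 0L)
  # cells always sum to the cohort size
  for (cand in 1:31) {
    tab <- contingency_at(cohort, cand)
    expect_identical(tab$a + tab$b + tab$c + tab$d, 4L)
  }
  # strict comparator shifts species at exactly the candidate below it
  tge <- contingency_at(cohort, 25, comparator = ">=")
  tgt <- contingency_at(cohort, 25, comparator = ">")
  expect_identical(tge$a + tge$b, 2L)
  expect_identical(tgt$a + tgt$b, 1L)
})

test_that("skill metrics evaluate the contingency equations exactly", {
  perfect <- skill_metrics(tibble::tibble(a = 10, b = 0, c = 0, d = 5))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "tss",
                                "overall_accuracy")]),
               c(sensitivity = 1, specificity = 1, tss = 1,
                 overall_accuracy = 1))

  inverted <- skill_metrics(tibble::tibble(a = 0, b = 5, c = 10, d = 0))
  expect_equal(inverted$tss, -1)
  expect_equal(inverted$overall_accuracy, 0)

  # exact rational evaluation
  m <- skill_metrics(tibble::tibble(a = 10, b = 2, c = 3, d = 15))
  expect_equal(m$sensitivity, 10 / 13, tolerance = 1e-12)
  expect_equal(m$specificity, 15 / 17, tolerance = 1e-12)
  expect_equal(m$tss, 10 / 13 + 15 / 17 - 1, tolerance = 1e-12)
  expect_equal(m$overall_accuracy, 25 / 30, tolerance = 1e-12)
  expect_equal(m$tss, m$sensitivity + m$specificity - 1, tolerance = 1e-12)

  # a single compliance class leaves the metrics undefined, flagged
  und <- skill_metrics(tibble::tibble(a = 4, b = 0, c = 6, d = 0))
  expect_false(und$defined)
  expect_true(is.na(und$tss))
  expect_error(skill_metrics(tibble::tibble(a = -1, b = 1, c = 1, d = 1)),
               "non-negative")
})

test_that("the scan selects the first TSS maximum", {
  # perfectly separable at 7 sites
  sep <- tibble::tibble(n_sites = c(7L, 9L, 12L, 3L, 5L, 6L),
                        passed = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  scan <- scan_occurrence_threshold(sep)
  expect_identical(scan$selected$candidate, 7L)
  expect_equal(scan$selected$tss, 1)
  expect_identical(scan$scan$candidate, 1:13)

  # a tie at the maximum goes to the smaller candidate: no species between
  # 8 and 11 sites, so candidates 8..11 share the maximum
  tie <- tibble::tibble(n_sites = c(12L, 15L, 3L, 7L),
                        passed = c(TRUE, TRUE, FALSE, FALSE))
  tsel <- scan_occurrence_threshold(tie)
  tied_set <- with(tidy(tsel), candidate[defined & tss >= max(tss[defined]) - 1e-12])
  expect_gt(length(tied_set), 1)
  expect_identical(tsel$selected$candidate, min(tied_set))
})

test_that("scan preconditions are enforced", {
  expect_error(
    scan_occurrence_threshold(tibble::tibble(n_sites = 5L, passed = TRUE)),
    "at least 2")
  expect_error(
    scan_occurrence_threshold(tibble::tibble(n_sites = c(5L, 9L),
                                             passed = c(TRUE, TRUE))),
    "single compliance class")
  expect_error(
    scan_occurrence_threshold(tibble::tibble(n_sites = c(5L, 9L),
                                             passed = c(TRUE, NA))),
    "NA")
})

test_that("the scan matches exhaustive brute force on random cohorts", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    cohort <- tibble::tibble(
      n_sites = sample(1:100, n, replace = TRUE),
      passed = runif(n) < runif(1, 0.2, 0.8))
    if (all(cohort$passed) || !any(cohort$passed)) next
    comparator <- sample(c(">=", ">"), 1)
    scan <- scan_occurrence_threshold(cohort, comparator = comparator)
    oracle <- oracle_scan(cohort$n_sites, cohort$passed, comparator)
    expect_identical(scan$selected$candidate, as.integer(oracle$selected))
    expect_lt(abs(scan$selected$tss - oracle$tss), 1e-12)
    # invariants: cells sum to cohort size, defined TSS within [-1, 1]
    expect_true(all(scan$scan$a + scan$scan$b + scan$scan$c + scan$scan$d == n))
    ok <- scan$scan$defined
    expect_true(all(scan$scan$tss[ok] >= -1 - 1e-12 & scan$scan$tss[ok] <= 1 + 1e-12))
    expect_true(all(scan$scan$overall_accuracy[ok] >= 0 &
                      scan$scan$overall_accuracy[ok] <= 1))
  }
})

test_that("tidy, glance and autoplot expose the scan", {
  cohort <- tibble::tibble(n_sites = c(30L, 25L, 10L, 5L),
                           passed = c(TRUE, TRUE, FALSE, FALSE))
  scan <- scan_occurrence_threshold(cohort)
  expect_s3_class(tidy(scan), "tbl_df")
  expect_identical(nrow(glance(scan)), 1L)
  expect_identical(glance(scan)$selected_threshold, scan$selected$candidate)
  expect_s3_class(autoplot(scan), "ggplot")
  expect_output(print(scan), "selected minimum")
})
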