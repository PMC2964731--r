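# Independent oracles -------------------------------------------------------

# Exact binomial CI by direct numeric inversion of the binomial tail sums.
ci_oracle <- function(x, n, alpha = 0.05) {
  lower <- if (x == 0) 0 else {
    stats::uniroot(function(p) sum(stats::dbinom(x:n, n, p)) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (x == n) 1 else {
    stats::uniroot(function(p) sum(stats::dbinom(0:x, n, p)) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(low = 100 * lower, high = 100 * upper)
}

# Two-sided Fisher p by exhaustive enumeration of the hypergeometric support,
# with table probabilities computed from binomial coefficients.
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  nn <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(nn, c1)
  p_obs <- logp[support == m[1, 1]]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# Hochberg step-up adjustment evaluated directly from its definition.
hochberg_oracle <- function(p) {
  m <- length(p)
  o <- order(p)          # ascending
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    adj[k] <- min(1, min((m - (k:m) + 1) * ps[k:m]))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Clopper-Pearson ------------------------------------------------------------

test_that("exact binomial CI matches direct tail inversion to 1e-6", {
  cases <- list(c(18, 226), c(15, 226), c(20, 226), c(18, 118), c(12, 118),
                c(24, 118), c(1, 10), c(5, 5), c(7, 400))
  for (cs in cases) {
    got <- clopper_pearson_ci(cs[1], cs[2])
    want <- ci_oracle(cs[1], cs[2])
    expect_equal(got, want, tolerance = 1e-6, info = paste(cs, collapse = "/"))
  }
})

test_that("exact binomial CI boundary identities and argument checks hold", {
  expect_equal(clopper_pearson_ci(0, 50)[["low"]], 0)
  expect_equal(clopper_pearson_ci(50, 50)[["high"]], 100)
  expect_error(clopper_pearson_ci(-1, 10), "0 <= x <= n")
  expect_error(clopper_pearson_ci(11, 10), "0 <= x <= n")
  expect_error(clopper_pearson_ci(2, 10, alpha = 1.2), "alpha")
  expect_error(clopper_pearson_ci(2.5, 10), "integer")
})

# Fisher's exact test ---------------------------------------------------------

test_that("two-sided Fisher p matches exhaustive enumeration on assorted tables", {
  tables <- list(
    matrix(c(0, 86, 5, 73), 2, 2, byrow = TRUE),
    matrix(c(16, 446, 4, 690), 2, 2, byrow = TRUE),
    matrix(c(18, 208, 18, 100), 2, 2, byrow = TRUE),
    matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE),
    matrix(c(10, 2, 3, 15), 2, 2, byrow = TRUE)
  )
  for (m in tables) {
    expect_equal(fisher_exact_2x2(m), fisher_oracle(m), tolerance = 1e-10)
  }
})

test_that("Fisher p is 1 for perfectly symmetric and zero-margin tables", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2)), 1.0)
  expect_warning(p <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(p, 1.0)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2, 2)), "non-negative")
})

# Hochberg adjustment ---------------------------------------------------------

test_that("Hochberg adjustment matches the step-up definition", {
  expect_equal(hochberg_adjust(0.03), 0.03)
  expect_equal(hochberg_adjust(c(0.01, 0.04, 0.03)),
               hochberg_oracle(c(0.01, 0.04, 0.03)))
  expect_equal(hochberg_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  # degenerate ties: the largest keeps its raw value
  expect_equal(hochberg_adjust(rep(0.02, 4)), hochberg_oracle(rep(0.02, 4)))
  expect_equal(hochberg_adjust(rep(0.02, 4)), rep(0.02, 4))
  expect_error(hochberg_adjust(c(0.1, 1.7)), "\\[0, 1\\]")
})

test_that("Hochberg adjustment commutes with permutation of its input", {
  withr::local_seed(42)
  for (i in 1:25) {
    p <- runif(sample(2:8, 1))
    adj <- hochberg_adjust(p)
    perm <- sample(seq_along(p))
    expect_equal(hochberg_adjust(p[perm]), adj[perm])
    expect_equal(adj, hochberg_oracle(p))
  }
  # adjusted values are monotone non-decreasing in the raw p-values
  p <- runif(10)
  adj <- hochberg_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

# Record classification -------------------------------------------------------

test_that("records partition into the three review categories with correct counts", {
  fx <- cohort_from_marginals(
    n = c(no_missing_index = 60, missing_not_found = 25, missing_found = 15),
    missing = list(missing_not_found = c(gender = 3),
                   missing_found = c(gender = 4))
  )
  cat <- classify_records(fx$records, "xrt_start", fx$review_results)
  expect_equal(unname(table(cat)[c("no_missing_index", "missing_not_found", "missing_found")]),
               as.integer(c(60, 25, 15)), ignore_attr = TRUE)
})

test_that("a review result for a non-missing record is a hard error", {
  fx <- cohort_from_marginals(
    n = c(no_missing_index = 5, missing_not_found = 2, missing_found = 1),
    missing = list()
  )
  rv <- fx$review_results
  rv[["M00001"]] <- TRUE # record in the no-missing category
  expect_error(classify_records(fx$records, "xrt_start", rv), "present")
  expect_error(classify_records(fx$records, "xrt_start", rv[-1][0]), "missing review")
})

# Co-occurrence analysis ------------------------------------------------------

test_that("co-occurrence table reproduces marginal counts, percents and CIs", {
  fx <- cohort_from_marginals(
    n = c(no_missing_index = 40, missing_not_found = 30, missing_found = 20),
    missing = list(missing_not_found = c(gender = 6, dob = 3, cancer_site = 9),
                   missing_found = c(gender = 5, dob = 2, cancer_site = 8))
  )
  co <- cooccurrence_analysis(fx$records, "xrt_start", fx$review_results)
  tab <- co$table
  b <- tab[tab$category == "missing_not_found", ]
  expect_equal(b$missing[b$field == "gender"], 6L)
  expect_equal(b$percent_raw[b$field == "gender"], 100 * 6 / 30)
  got_ci <- c(b$ci_low[b$field == "gender"], b$ci_high[b$field == "gender"])
  want <- clopper_pearson_ci(6, 30)
  expect_equal(got_ci, round(c(want[["low"]], want[["high"]]) * 10) / 10,
               tolerance = 1e-9)
  # CI brackets the point estimate
  ok <- !is.na(tab$percent_raw)
  expect_true(all(tab$ci_low[ok] <= tab$percent_raw[ok] + 0.05))
  expect_true(all(tab$ci_high[ok] >= tab$percent_raw[ok] - 0.05))
})

test_that("a zero-missingness cohort yields all-zero cells", {
  fx <- cohort_from_marginals(
    n = c(no_missing_index = 10, missing_not_found = 5, missing_found = 5),
    missing = list()
  )
  co <- cooccurrence_analysis(fx$records, "xrt_start", fx$review_results)
  expect_true(all(co$table$missing == 0L))
  expect_true(all(co$table$percent == 0))
})

test_that("any-field-missing rate is at least every single-field rate", {
  sim <- generate_cohort(generator_spec(n_records = 600, seed = 9))
  co <- cooccurrence_analysis(sim$records, "xrt_start",
                              sim$ground_truth$review_results)
  for (cat in unique(co$table$category)) {
    rows <- co$table[co$table$category == cat, ]
    any_row <- co$any_missing[co$any_missing$category == cat, ]
    if (!is.na(any_row$percent_raw)) {
      expect_gte(any_row$percent_raw, max(rows$percent_raw))
    }
  }
})

test_that("an empty category is emitted with n = 0 and undefined CI markers", {
  fx <- cohort_from_marginals(
    n = c(missing_not_found = 5, missing_found = 5),
    missing = list()
  )
  co <- cooccurrence_analysis(fx$records, "xrt_start", fx$review_results)
  empty <- co$table[co$table$category == "no_missing_index", ]
  expect_true(all(empty$n == 0L))
  expect_true(all(is.na(empty$ci_low)))
})

# Effectiveness ---------------------------------------------------------------

test_that("planted access-edit latencies split on the attribution window", {
  recs <- list(bare_record("W1"), bare_record("W2"), bare_record("W3"))
  traces <- dplyr::bind_rows(
    access_trace("W1", timestamp = "2008-07-04 10:00:00"),
    edit_trace("W1", timestamp = "2008-07-04 10:05:00"),  # 5 min: inside
    access_trace("W2", timestamp = "2008-07-04 11:00:00"),
    edit_trace("W2", timestamp = "2008-07-04 11:15:00"),  # 15 min: outside
    edit_trace("W3", timestamp = "2008-07-04 12:00:00")   # corrected, never accessed
  )
  eff <- suppressWarnings(effectiveness_analysis(recs, traces, window_minutes = 10))
  expect_equal(eff$window_attributed, 1L)
  expect_equal(eff$contingency["yes", "yes"], 2L)
  expect_equal(eff$contingency["no", "yes"], 1L)
  expect_equal(sum(eff$contingency), 3L)
})

test_that("contingency margins conserve the number of records", {
  sim <- generate_cohort(generator_spec(n_records = 400, seed = 13))
  eff <- effectiveness_analysis(sim$records, sim$traces)
  expect_equal(sum(eff$contingency), 400L)
  expect_equal(sum(eff$contingency["yes", ]),
               sum(sim$ground_truth$outcomes$accessed))
})

test_that("only unknown-to-present edits count as corrections", {
  recs <- list(bare_record("V1"), bare_record("V2"), bare_record("V3"))
  traces <- dplyr::bind_rows(
    edit_trace("V1", before = "", after = "2005-01-01"),          # correction
    edit_trace("V2", before = "2004-01-01", after = "2005-01-01"),# revision
    edit_trace("V3", before = "NA!", after = "2005-01-01")        # not from unknown
  )
  eff <- suppressWarnings(effectiveness_analysis(recs, traces))
  expect_equal(sum(eff$contingency[, "yes"]), 1L)
  expect_equal(eff$revisions, 1L)
})

test_that("no-op edits are ignored with a warning; no traces gives the p = 1 convention", {
  recs <- list(bare_record("V1"))
  w <- capture_warnings(
    eff <- effectiveness_analysis(recs, edit_trace("V1", before = "x", after = "x"))
  )
  expect_match(w, "identical before and after", all = FALSE)
  expect_equal(sum(eff$contingency[, "yes"]), 0L)
  expect_warning(
    eff0 <- effectiveness_analysis(list(bare_record("V1"), bare_record("V2")),
                                   access_trace("V9")[0, ]),
    "zero margin"
  )
  expect_equal(eff0$fisher_p, 1.0)
  expect_equal(sum(eff0$contingency["yes", ]), 0L)
})

test_that("unknown record ids in traces are refused", {
  expect_error(effectiveness_analysis(list(bare_record("V1")), access_trace("ZZ")),
               "unknown record id")
})

# Utilization -----------------------------------------------------------------

test_that("utilization histogram totals the cohort and buckets repeat accesses", {
  recs <- list(bare_record("U1"), bare_record("U2"), bare_record("U3"),
               bare_record("U4"))
  traces <- dplyr::bind_rows(
    access_trace("U1"),
    access_trace("U2", timestamp = "2008-07-04 10:00:00"),
    access_trace("U2", timestamp = "2008-07-04 10:10:00"),
    access_trace("U3", timestamp = "2008-07-04 10:00:00"),
    access_trace("U3", timestamp = "2008-07-04 10:10:00"),
    access_trace("U3", timestamp = "2008-07-04 10:20:00"),
    access_trace("U3", timestamp = "2008-07-04 10:30:00")
  )
  u <- utilization_summary(recs, traces)
  expect_equal(sum(u$histogram$records), 4L)
  expect_equal(u$histogram$records, c(1L, 1L, 1L, 1L))
  expect_equal(u$overall$rate_percent, 75.0)
})

test_that("utilization with no traces reports zero rates", {
  u <- utilization_summary(list(bare_record("U1")), access_trace("U1")[0, ])
  expect_equal(u$overall$rate_percent, 0)
  expect_equal(nrow(u$per_user), 0L)
})

test_that("per-user rates are computed over each user's own workload", {
  recs <- list(bare_record("U1"), bare_record("U2"), bare_record("U3"))
  traces <- dplyr::bind_rows(
    edit_trace("U1", user_id = "a", field = "t_stage", after = "T2"),
    edit_trace("U2", user_id = "a", field = "t_stage", after = "T2"),
    access_trace("U1", user_id = "a"),
    edit_trace("U3", user_id = "b", field = "t_stage", after = "T2")
  )
  u <- utilization_summary(recs, traces)
  expect_equal(u$per_user$rate_percent[u$per_user$user_id == "a"], 50.0)
  expect_equal(u$per_user$rate_percent[u$per_user$user_id == "b"], 0)
})
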