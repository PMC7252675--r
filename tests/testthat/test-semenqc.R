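base_record <- function(...) {
  defaults <- list(
    bull_id = "B1", collection_date = as.Date("2015-06-01"),
    age_days = 500L, interval_days = 14L, volume_ml = 4,
    concentration_1e9_per_ml = 1.3, motility_pct = 85, head_score = 0L,
    tail_score = 0L, sperm_per_straw_mio = 16, collector_id = "C1",
    pooled_flag = FALSE, rejection_cause = NA_character_
  )
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(defaults)
}

removed_at <- function(log, step) {
  i <- match(step, log$step)
  log$n_records[i - 1] - log$n_records[i]
}

test_that("threshold records are removed at the right cascade step", {
  recs <- dplyr::bind_rows(
    base_record(bull_id = "B1", motility_pct = 69.9),
    base_record(bull_id = "B2", age_days = 399L),
    base_record(bull_id = "B3", age_days = 1001L),
    base_record(bull_id = "B4", motility_pct = 70),   # inclusive: kept
    base_record(bull_id = "B5", volume_ml = 1),       # strict: removed
    base_record(bull_id = "B6", concentration_1e9_per_ml = 0.3),  # strict
    base_record(bull_id = "B7")
  )
  f <- filter_ejaculates(recs, filter_config(min_ejaculates = 1))
  log <- attrition(f)
  expect_equal(removed_at(log, "fresh sperm motility >= minimum"), 1)
  expect_equal(removed_at(log, "age at collection within range"), 2)
  expect_equal(removed_at(log, "ejaculate volume above minimum"), 1)
  expect_equal(removed_at(log, "sperm concentration above minimum"), 1)
  expect_setequal(f$bull_id, c("B4", "B7"))
})

test_that("implausible anomaly scores warn and drop rather than error", {
  recs <- dplyr::bind_rows(
    base_record(),
    base_record(head_score = 9L, collection_date = as.Date("2015-06-08"))
  )
  expect_warning(f <- filter_ejaculates(recs, filter_config(min_ejaculates = 1)),
                 "implausible")
  expect_equal(nrow(f), 1)
})

test_that("the cascade is monotone and idempotent", {
  rec <- small_records()
  f1 <- filter_ejaculates(rec$records)
  log <- attrition(f1)
  expect_true(all(diff(log$n_records) <= 0))
  expect_true(all(diff(log$n_bulls) <= 0))
  f2 <- filter_ejaculates(f1)
  expect_equal(nrow(f2), nrow(f1))
  expect_identical(dplyr::as_tibble(f2), dplyr::as_tibble(f1))
})

test_that("per-bull aggregation averages retained ejaculates only", {
  recs <- dplyr::bind_rows(
    base_record(motility_pct = 80, collection_date = as.Date("2015-06-01")),
    base_record(motility_pct = 90, collection_date = as.Date("2015-06-15")),
    base_record(bull_id = "B2", motility_pct = 75)
  )
  f <- filter_ejaculates(recs, filter_config(min_ejaculates = 2))
  tr <- aggregate_traits(f)
  expect_equal(tr$motility_pct[tr$bull_id == "B1"], 85)
  expect_false("B2" %in% tr$bull_id)  # below the minimum-ejaculate rule

  # synthetic cohort grand mean lands at the configured architecture:
  # 0.9424 * 86.37 + 0.0576 * 82.77 = 86.16 (the expected population mean)
  tr_all <- small_scan_inputs()$traits
  expect_lt(abs(mean(tr_all$motility_pct) - 86.16), 0.35)
})

test_that("fixed-effect adjustment tracks the raw means and matches a dummy-coded OLS oracle", {
  # null fixed effects: adjusted means are essentially a recentred copy
  cfg0 <- sim_config(seed = 9, n_bulls = 120L, collector_sd = 0, season_sd = 0,
                     age_slope = 0, n_snps_per_chrom = c(900L, 60L, 60L),
                     records_per_bull = c(8L, 16L))
  rec0 <- simulate_records(cfg0, simulate_panel(cfg0)$status)
  f0 <- filter_ejaculates(rec0$records)
  adj0 <- adjust_traits(f0, traits = "motility_pct")
  expect_gt(attr(adj0, "raw_adjusted_r")[["motility_pct"]], 0.99)

  # cohort-scale effects: correlation stays high
  rec <- small_records()
  f <- filter_ejaculates(rec$records)
  adj <- adjust_traits(f, traits = "motility_pct")
  expect_gt(attr(adj, "raw_adjusted_r")[["motility_pct"]], 0.90)

  # 30-record instance against an explicit normal-equations solve
  set.seed(4)
  d30 <- f[sample(nrow(f), 30), ]
  adj30 <- adjust_traits(d30, traits = "motility_pct")
  X <- stats::model.matrix(~ age_days + interval_days + factor(collector_id) +
                             factor(quarter_of_oracle(collection_date)),
                           data = d30)
  beta <- solve(crossprod(X), crossprod(X, d30$motility_pct))
  res <- d30$motility_pct - X %*% beta
  oracle <- tapply(as.numeric(res), d30$bull_id, mean)
  expect_equal(adj30$motility_pct,
               as.numeric(oracle[adj30$bull_id]), tolerance = 1e-8)
})

test_that("single-level factors are dropped from the adjustment model with a warning", {
  recs <- dplyr::bind_rows(
    base_record(motility_pct = 80),
    base_record(motility_pct = 90, collector_id = "C2",
                collection_date = as.Date("2015-06-08")),
    base_record(bull_id = "B2", motility_pct = 84),
    base_record(bull_id = "B2", motility_pct = 86, collector_id = "C2",
                collection_date = as.Date("2015-06-08"))
  )
  f <- filter_ejaculates(recs, filter_config(min_ejaculates = 1))
  # all records fall in one calendar quarter: season is degenerate
  expect_warning(adjust_traits(f, traits = "motility_pct"), "season")
})

test_that("fertility indices are standardized exactly and recover simulated truth", {
  cfg <- sim_config(seed = 5, n_insem_per_bull = 2000L)
  truth <- stats::setNames(rnorm(60), sprintf("B%04d", 1:60))
  ins <- simulate_inseminations(cfg, truth)
  fert <- suppressMessages(estimate_fertility(ins))
  expect_equal(mean(fert$index), 100, tolerance = 1e-6)
  expect_equal(sd(fert$index), 12, tolerance = 1e-6)
  expect_gt(cor(fert$index, truth[fert$bull_id]), 0.8)

  # an implanted very-low-fertility bull is flagged and dropped
  truth2 <- truth
  truth2[["B0001"]] <- -8
  f2 <- suppressMessages(estimate_fertility(simulate_inseminations(cfg, truth2)))
  expect_false("B0001" %in% f2$bull_id)
  expect_true("B0001" %in% attr(f2, "outliers")$bull_id)

  # no outcome variance: everyone sits at the population mean
  ins3 <- dplyr::mutate(ins, outcome = 1L)
  f3 <- suppressMessages(estimate_fertility(ins3))
  expect_true(all(abs(f3$index - 100) < 1e-9))

  # bulls under the insemination minimum are excluded up front
  few <- dplyr::bind_rows(ins, dplyr::mutate(ins[1:50, ], bull_id = "B9999"))
  f4 <- suppressMessages(estimate_fertility(few))
  expect_false("B9999" %in% f4$bull_id)
  expect_true("B9999" %in% attr(f4, "excluded"))
})

test_that("trait correlations behave like Pearson correlations", {
  tr <- small_scan_inputs()$traits
  cm <- trait_correlations(tr)
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  x <- tr$motility_pct
  d <- tibble::tibble(bull_id = tr$bull_id, n_ejaculates = tr$n_ejaculates,
                      a = x, b = -x)
  expect_equal(trait_correlations(d)["a", "b"], -1)

  # two-pass covariance oracle on 20 bulls
  d20 <- tr[1:20, c("motility_pct", "tail_score")]
  mx <- mean(d20$motility_pct); my <- mean(d20$tail_score)
  r_oracle <- sum((d20$motility_pct - mx) * (d20$tail_score - my)) /
    sqrt(sum((d20$motility_pct - mx)^2) * sum((d20$tail_score - my)^2))
  expect_equal(trait_correlations(tr[1:20, ])["motility_pct", "tail_score"],
               r_oracle)
})
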