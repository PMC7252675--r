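#' Ejaculate filter configuration
#'
#' Thresholds of the sequential quality-control cascade applied to raw
#' ejaculate records. Defaults are the AI-laboratory minimum requirements:
#' collection age between 400 and 1000 days, at least 70% motile sperm,
#' ejaculate volume strictly above 1 ml, concentration strictly above 0.3e9
#' sperm per ml, 15 to 25 million sperm per straw, and at least 8 retained
#' ejaculates per bull.
#'
#' @param age_range Inclusive age bounds at collection, in days.
#' @param min_motility Minimum motile-sperm percentage (inclusive).
#' @param min_volume_ml Volume threshold (exclusive: volume must exceed it).
#' @param min_concentration Concentration threshold in 1e9/ml (exclusive).
#' @param straw_range Inclusive bounds on million sperm per straw.
#' @param min_ejaculates Minimum retained ejaculates per bull.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(age_range = c(400, 1000),
                          min_motility = 70,
                          min_volume_ml = 1,
                          min_concentration = 0.3,
                          straw_range = c(15, 25),
                          min_ejaculates = 8) {
  stopifnot(age_range[1] < age_range[2], straw_range[1] < straw_range[2])
  structure(list(age_range = age_range, min_motility = min_motility,
                 min_volume_ml = min_volume_ml,
                 min_concentration = min_concentration,
                 straw_range = straw_range, min_ejaculates = min_ejaculates),
            class = "filter_config")
}

#' Sequential quality-control cascade for ejaculate records
#'
#' Applies the filter rules one after the other in a fixed order (each rule
#' sees only the records surviving the previous one), recording the number of
#' remaining records and bulls after every step. "First ejaculate per day"
#' keeps the earliest record per bull and collection date (ties broken by row
#' order); the minimum-ejaculates rule is applied last. Implausible anomaly
#' scores (outside 0..3) drop the record with a warning rather than an error.
#'
#' @param records Ejaculate tibble (see [simulate_records()] for the schema).
#' @param cfg A [filter_config()].
#' @param genotyped_ids Optional character vector; if given, a final step
#'   keeps only bulls with genotypes.
#' @return The filtered tibble, with the attrition log attached as attribute
#'   `"attrition"` (retrieve with [attrition()]).
#' @export
filter_ejaculates <- function(records, cfg = filter_config(),
                              genotyped_ids = NULL) {
  x <- as_tibble(records)
  log <- list(tibble(step = "raw", n_records = nrow(x),
                     n_bulls = dplyr::n_distinct(x$bull_id)))
  keep_step <- function(x, label, keep) {
    keep[is.na(keep)] <- FALSE
    x <- x[keep, , drop = FALSE]
    log[[length(log) + 1L]] <<- tibble(step = label, n_records = nrow(x),
                                       n_bulls = dplyr::n_distinct(x$bull_id))
    x
  }
  x <- keep_step(x, "interval to preceding ejaculate known",
                 !is.na(x$interval_days))
  x <- keep_step(x, "age at collection within range",
                 x$age_days >= cfg$age_range[1] & x$age_days <= cfg$age_range[2])
  x <- keep_step(x, "ejaculate volume recorded", !is.na(x$volume_ml))
  x <- keep_step(x, "fresh sperm motility recorded", !is.na(x$motility_pct))
  x <- keep_step(x, "no cause of rejection recorded",
                 is.na(x$rejection_cause) | x$rejection_cause == "")
  x <- keep_step(x, "fresh sperm motility >= minimum",
                 x$motility_pct >= cfg$min_motility)
  x <- keep_step(x, "ejaculate volume above minimum",
                 x$volume_ml > cfg$min_volume_ml)
  x <- keep_step(x, "sperm concentration above minimum",
                 x$concentration_1e9_per_ml > cfg$min_concentration)
  x <- keep_step(x, "ejaculate not pooled", !x$pooled_flag)
  first_of_day <- !duplicated(paste(x$bull_id, x$collection_date, sep = "\r"))
  x <- keep_step(x, "only first ejaculate per day", first_of_day)
  x <- keep_step(x, "semen collector recorded", !is.na(x$collector_id))
  plaus <- x$head_score %in% 0:3 & x$tail_score %in% 0:3
  if (any(!plaus, na.rm = TRUE)) {
    warn(sprintf("%d record(s) dropped for implausible anomaly scores",
                 sum(!plaus, na.rm = TRUE)))
  }
  x <- keep_step(x, "plausible head and tail anomaly scores", plaus)
  x <- keep_step(x, "sperm per straw within target range",
                 x$sperm_per_straw_mio >= cfg$straw_range[1] &
                   x$sperm_per_straw_mio <= cfg$straw_range[2])
  enough <- x |>
    dplyr::count(.data$bull_id) |>
    dplyr::filter(.data$n >= cfg$min_ejaculates) |>
    dplyr::pull(.data$bull_id)
  x <- keep_step(x, "minimum ejaculates per bull", x$bull_id %in% enough)
  if (!is.null(genotyped_ids)) {
    x <- keep_step(x, "bull genotyped", x$bull_id %in% genotyped_ids)
  }
  attr(x, "attrition") <- dplyr::bind_rows(log)
  x
}

#' Attrition log of a filter cascade
#'
#' @param x A tibble returned by [filter_ejaculates()].
#' @return A tibble `step`, `n_records`, `n_bulls`, one row per cascade step
#'   (first row is the raw data).
#' @export
attrition <- function(x) {
  a <- attr(x, "attrition", exact = TRUE)
  if (is.null(a)) abort("no attrition log attached; was this filtered with filter_ejaculates()?")
  a
}

#' Per-bull trait averages
#'
#' Arithmetic means of each semen trait across a bull's retained ejaculates.
#'
#' @param filtered Output of [filter_ejaculates()].
#' @param traits Character vector of trait columns to average.
#' @return A tibble with `bull_id`, `n_ejaculates`, and one mean per trait.
#' @export
aggregate_traits <- function(filtered,
                             traits = c("volume_ml", "concentration_1e9_per_ml",
                                        "motility_pct", "head_score",
                                        "tail_score", "sperm_per_straw_mio")) {
  filtered |>
    dplyr::group_by(.data$bull_id) |>
    dplyr::summarise(n_ejaculates = dplyr::n(),
                     dplyr::across(dplyr::all_of(traits), ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
}

#' Fixed-effects-adjusted per-bull trait averages
#'
#' Fits, per trait, the record-level least-squares model
#' `y = mu + a*age + f*interval + collector + season + e` and averages the
#' residuals per bull. Season is the calendar quarter of the collection date.
#' Factors with a single level are dropped with a warning (singular design).
#'
#' @inheritParams aggregate_traits
#' @return A tibble with `bull_id`, `n_ejaculates`, and one adjusted
#'   (residual-mean) column per trait; the Pearson correlation between raw
#'   and adjusted bull means is attached as attribute `"raw_adjusted_r"`.
#' @export
adjust_traits <- function(filtered,
                          traits = c("volume_ml", "concentration_1e9_per_ml",
                                     "motility_pct", "head_score",
                                     "tail_score", "sperm_per_straw_mio")) {
  dat <- dplyr::mutate(filtered, season = factor(quarter_of(.data$collection_date)))
  terms <- c("age_days", "interval_days")
  for (fac in c("collector_id", "season")) {
    if (dplyr::n_distinct(dat[[fac]]) >= 2) {
      terms <- c(terms, fac)
    } else {
      warn(sprintf("factor `%s` has a single level and was dropped from the adjustment model", fac))
    }
  }
  form_rhs <- paste(terms, collapse = " + ")
  out <- aggregate_traits(filtered, traits)
  rr <- numeric(length(traits))
  names(rr) <- traits
  for (tr in traits) {
    fit <- lm(stats::as.formula(paste0("`", tr, "` ~ ", form_rhs)), data = dat)
    res <- tibble(bull_id = dat$bull_id, r = stats::residuals(fit)) |>
      dplyr::group_by(.data$bull_id) |>
      dplyr::summarise(adj = mean(.data$r), .groups = "drop")
    raw_means <- out[[tr]][match(res$bull_id, out$bull_id)]
    rr[tr] <- if (sd(raw_means) > 0 && sd(res$adj) > 0) {
      cor(raw_means, res$adj)
    } else NA_real_
    out[[tr]] <- res$adj[match(out$bull_id, res$bull_id)]
  }
  attr(out, "raw_adjusted_r") <- rr
  out
}

#' Bull-fertility index from insemination outcomes
#'
#' Fits a linear probability model of the 56-day non-return outcome on
#' insemination month, parity, straw-price class, breed combination,
#' technician, herd and bull, extracts the bull effects as deviations, and
#' standardizes them to a mean of 100 and an SD of 12 over the estimation
#' cohort. Bulls more than `outlier_sd` standard deviations below the mean
#' are flagged and dropped (returned in attribute `"outliers"`); bulls with
#' fewer than `min_inseminations` records are excluded up front (attribute
#' `"excluded"`).
#'
#' @param inseminations Tibble of insemination records (see
#'   [simulate_inseminations()] for the schema).
#' @param min_inseminations Minimum inseminations per bull.
#' @param mean_target,sd_target Standardization constants.
#' @param outlier_sd Outlier cut in SD units below the mean.
#' @return A tibble `bull_id`, `index`, `n_inseminations`.
#' @export
estimate_fertility <- function(inseminations, min_inseminations = 200,
                               mean_target = 100, sd_target = 12,
                               outlier_sd = 3) {
  counts <- dplyr::count(inseminations, .data$bull_id, name = "n_inseminations")
  keep <- counts$bull_id[counts$n_inseminations >= min_inseminations]
  excluded <- setdiff(counts$bull_id, keep)
  if (length(excluded)) {
    inform(sprintf("%d bull(s) excluded with fewer than %d inseminations",
                   length(excluded), min_inseminations))
  }
  dat <- dplyr::filter(inseminations, .data$bull_id %in% keep)
  if (dplyr::n_distinct(dat$bull_id) < 2) abort("need at least two bulls to estimate fertility")
  fac <- function(v) factor(v)
  dat <- dplyr::mutate(dat, dplyr::across(c("bull_id", "month", "parity",
                                            "straw_price", "breed_combination",
                                            "technician_id", "herd_id"), fac))
  # bull first and no intercept => one coefficient per bull, never aliased
  X <- Matrix::sparse.model.matrix(
    ~ 0 + bull_id + month + parity + straw_price + breed_combination +
      technician_id + herd_id, data = dat)
  XtX <- Matrix::crossprod(X)
  Xty <- Matrix::crossprod(X, dat$outcome)
  # drop aliased columns (rank deficiency among the environmental factors)
  ch <- tryCatch(Matrix::Cholesky(XtX, perm = TRUE), error = function(e) NULL)
  if (is.null(ch)) {
    d <- Matrix::diag(XtX)
    sol <- Matrix::solve(XtX + Matrix::Diagonal(ncol(X), 1e-8 * mean(d)), Xty)
  } else {
    sol <- Matrix::solve(ch, Xty, system = "A")
  }
  beta <- as.numeric(sol)
  names(beta) <- colnames(X)
  bcols <- startsWith(names(beta), "bull_id")
  eff <- beta[bcols]
  names(eff) <- sub("^bull_id", "", names(eff))
  dev <- eff - mean(eff)
  s <- sd(dev)
  index <- if (s < .Machine$double.eps) {
    rep(mean_target, length(dev))
  } else {
    mean_target + sd_target * dev / s
  }
  out <- tibble(bull_id = names(eff), index = unname(index)) |>
    dplyr::left_join(counts, by = "bull_id")
  low <- out$index < mean_target - outlier_sd * sd_target
  outliers <- out[low, , drop = FALSE]
  if (nrow(outliers)) {
    inform(sprintf("%d bull(s) dropped as fertility outliers (> %g SD below mean)",
                   nrow(outliers), outlier_sd))
  }
  res <- out[!low, , drop = FALSE]
  attr(res, "outliers") <- outliers
  attr(res, "excluded") <- excluded
  res
}

#' Phenotypic correlations between bull-level traits
#'
#' Pearson correlations across bulls, using pairwise-complete observations.
#'
#' @param bull_traits Output of [aggregate_traits()] or [adjust_traits()].
#' @param traits Trait columns to correlate (defaults to all numeric columns
#'   except `n_ejaculates`).
#' @return A symmetric correlation matrix.
#' @export
trait_correlations <- function(bull_traits, traits = NULL) {
  if (is.null(traits)) {
    traits <- setdiff(names(bull_traits)[vapply(bull_traits, is.numeric, logical(1))],
                      "n_ejaculates")
  }
  cor(as.matrix(bull_traits[traits]), use = "pairwise.complete.obs")
}
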