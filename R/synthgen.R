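#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode the
#' study conditions the package is designed around: a cohort of 800 AI bulls,
#' a 50-SNP haplotype segregating at 24% frequency with a purely recessive
#' effect on semen quality (homozygote motility 82.77% vs 86.37%, a shift of
#' about 1.6 phenotypic standard deviations), repeated ejaculate records per
#' bull with repeatability (0.43) exceeding heritability (0.25), and a long
#' founder segment (about 2.38 Mb of markers) shared by all carrier
#' haplotypes, which homozygous carriers expose as shared autozygosity.
#'
#' Trait means are given per haplotype-copy status (0, 1, 2 copies);
#' heterozygotes equal non-carriers, which is what makes the architecture
#' recessive. `trait_sd` values are phenotypic standard deviations of per-bull
#' trait averages; the generator scales the per-record variance accordingly.
#'
#' @param seed Integer seed; every generator draws from it deterministically.
#' @param n_bulls Number of genotyped bulls.
#' @param n_chroms Number of autosomes to simulate.
#' @param n_snps_per_chrom Markers per chromosome (recycled to `n_chroms`).
#' @param n_founders Size of the founder haplotype pool the copying model
#'   mosaics over.
#' @param switch_prob Per-marker probability of switching founder template;
#'   controls local linkage disequilibrium.
#' @param marker_spacing_bp Mean marker spacing in basepairs.
#' @param qtl_chrom,qtl_window_start Chromosome and first marker index (within
#'   that chromosome) of the implanted 50-SNP QTL window.
#' @param window_size Markers per haplotype window.
#' @param qtl_hap_freq Population frequency of the QTL haplotype, in (0, 0.5].
#' @param span_start,span_end First/last marker index (within `qtl_chrom`) of
#'   the identical-by-descent founder segment carried by every QTL haplotype;
#'   must contain the QTL window.
#' @param implant_qtl If `FALSE` no haplotype is implanted (pure null panel).
#' @param traits Tibble with columns `trait`, `mean0`, `mean1`, `mean2`, `sd`.
#' @param h2 Narrow-sense heritability of each trait, in `[0, 1)`.
#' @param repeatability Repeatability (additive plus permanent-environment
#'   fraction); must be at least `h2`.
#' @param records_per_bull Length-2 inclusive bounds on ejaculate records per
#'   bull.
#' @param n_collectors,collector_sd Number of semen collectors and the SD of
#'   their effects (in units of the trait SD).
#' @param season_sd SD of calendar-quarter season effects (trait-SD units).
#' @param age_slope Linear age effect per 300 days of age (trait-SD units).
#' @param n_sires,n_dams Founder sires/dams in the simulated pedigree.
#' @param qc_violations Named integer vector of deliberate quality-control
#'   violations to inject (see [simulate_records()]).
#' @param n_insem_per_bull Inseminations per bull for the fertility generator.
#' @param base_nrr Baseline 56-day non-return probability.
#' @param fertility_scale Shift in success probability per unit of true bull
#'   fertility (truth is expressed in SD units).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_bulls = 800L,
                       n_chroms = 3L,
                       n_snps_per_chrom = c(900L, 450L, 450L),
                       n_founders = 4L,
                       switch_prob = 0.01,
                       marker_spacing_bp = 4000,
                       qtl_chrom = 1L,
                       qtl_window_start = 256L,
                       window_size = 50L,
                       qtl_hap_freq = 0.24,
                       span_start = 240L,
                       span_end = 834L,
                       implant_qtl = TRUE,
                       traits = default_traits(),
                       h2 = 0.25,
                       repeatability = 0.43,
                       records_per_bull = c(8L, 32L),
                       n_collectors = 8L,
                       collector_sd = 0.15,
                       season_sd = 0.10,
                       age_slope = 0.05,
                       n_sires = 40L,
                       n_dams = 400L,
                       qc_violations = integer(0),
                       n_insem_per_bull = 1000L,
                       base_nrr = 0.70,
                       fertility_scale = 0.03) {
  cfg <- list(
    seed = as.integer(seed), n_bulls = as.integer(n_bulls),
    n_chroms = as.integer(n_chroms),
    n_snps_per_chrom = rep_len(as.integer(n_snps_per_chrom), n_chroms),
    n_founders = as.integer(n_founders), switch_prob = switch_prob,
    marker_spacing_bp = marker_spacing_bp,
    qtl_chrom = as.integer(qtl_chrom),
    qtl_window_start = as.integer(qtl_window_start),
    window_size = as.integer(window_size),
    qtl_hap_freq = qtl_hap_freq,
    span_start = as.integer(span_start), span_end = as.integer(span_end),
    implant_qtl = isTRUE(implant_qtl),
    traits = traits, h2 = h2, repeatability = repeatability,
    records_per_bull = as.integer(records_per_bull),
    n_collectors = as.integer(n_collectors), collector_sd = collector_sd,
    season_sd = season_sd, age_slope = age_slope,
    n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
    qc_violations = qc_violations,
    n_insem_per_bull = as.integer(n_insem_per_bull),
    base_nrr = base_nrr, fertility_scale = fertility_scale
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default simulated trait architecture
#'
#' Means per haplotype-copy status and bull-level phenotypic SDs for the six
#' ejaculate traits. Non-carriers and heterozygotes share the same mean;
#' homozygotes are shifted for motility (-1.6 SD), head and tail anomaly
#' scores (+2 and +2.1 SD) and sperm per straw (+1.5 SD), while ejaculate
#' volume and sperm concentration are unaffected.
#'
#' @return A tibble with columns `trait`, `mean0`, `mean1`, `mean2`, `sd`.
#' @export
default_traits <- function() {
  tibble::tribble(
    ~trait,                    ~mean0, ~mean1, ~mean2,  ~sd,
    "volume_ml",                 3.93,   3.93,   3.93, 0.94,
    "concentration_1e9_per_ml",  1.32,   1.32,   1.32, 0.32,
    "motility_pct",             86.37,  86.37,  82.77, 2.33,
    "head_score",                0.05,   0.05,   0.33, 0.14,
    "tail_score",                0.13,   0.13,   0.68, 0.26,
    "sperm_per_straw_mio",      16.29,  16.29,  19.15, 1.91
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_bulls > 0, cfg$n_chroms > 0, all(cfg$n_snps_per_chrom > 0),
    cfg$n_founders >= 2, cfg$switch_prob >= 0, cfg$switch_prob <= 1,
    cfg$marker_spacing_bp > 0, cfg$window_size > 0,
    length(cfg$records_per_bull) == 2, all(cfg$records_per_bull > 0),
    cfg$records_per_bull[1] <= cfg$records_per_bull[2]
  )
  if (!(cfg$qtl_hap_freq > 0 && cfg$qtl_hap_freq <= 0.5)) {
    abort("`qtl_hap_freq` must lie in (0, 0.5].")
  }
  if (cfg$h2 < 0 || cfg$h2 >= 1) abort("`h2` must lie in [0, 1).")
  if (cfg$repeatability < cfg$h2 || cfg$repeatability >= 1) {
    abort("`repeatability` must satisfy h2 <= repeatability < 1.")
  }
  if (cfg$implant_qtl) {
    n_qtl <- cfg$n_snps_per_chrom[cfg$qtl_chrom]
    w_end <- cfg$qtl_window_start + cfg$window_size - 1L
    if (cfg$qtl_window_start < 1L || w_end > n_qtl) {
      abort("QTL window falls outside the marker map of its chromosome.")
    }
    if (cfg$span_start > cfg$qtl_window_start || cfg$span_end < w_end ||
        cfg$span_start < 1L || cfg$span_end > n_qtl) {
      abort("IBD span must contain the QTL window and fit on its chromosome.")
    }
  }
  invisible(cfg)
}

#' Simulate a phased haplotype panel with an implanted recessive haplotype
#'
#' Haplotypes are mosaics of a pool of founder haplotypes (per-marker founder
#' switch probability `switch_prob`), which induces local linkage
#' disequilibrium and recurrent multi-SNP haplotype sharing. Per-marker allele
#' frequencies are drawn from Uniform(0.05, 0.95). A fraction
#' `qtl_hap_freq` of haplotypes (binomially sampled) carries the QTL segment:
#' founder-1 alleles across the IBD span with a unique 50-SNP core string in
#' the QTL window. The core string occurs only on carrier haplotypes, so the
#' QTL window is the single strongest recessive signal, while homozygous
#' carriers still share the whole span as a run of identical homozygosity.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `panel` (a `haplotype_panel`: marker map
#'   tibble plus two phased 0/1 allele matrices), `status` (tibble
#'   `sample_id`, `copies`), and `qtl` (window and span coordinates, the core
#'   allele string, and the seed used).
#' @export
simulate_panel <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_bulls
  n_hap <- 2L * n
  sample_ids <- sprintf("B%04d", seq_len(n))

  maps <- vector("list", cfg$n_chroms)
  hap_chunks <- vector("list", cfg$n_chroms)
  for (ch in seq_len(cfg$n_chroms)) {
    s <- cfg$n_snps_per_chrom[ch]
    pos <- cumsum(pmax(1L, round(rexp(s, 1 / cfg$marker_spacing_bp)))) + 100000L
    p <- runif(s, 0.05, 0.95)
    founders <- matrix(rbinom(cfg$n_founders * s, 1L, rep(p, each = cfg$n_founders)),
                       nrow = cfg$n_founders, ncol = s)
    # mosaic copying: markov chain over founder templates
    state <- matrix(0L, nrow = n_hap, ncol = s)
    state[, 1] <- sample.int(cfg$n_founders, n_hap, replace = TRUE)
    if (s > 1) {
      sw <- matrix(runif(n_hap * (s - 1)) < cfg$switch_prob, nrow = n_hap)
      new_state <- matrix(sample.int(cfg$n_founders, n_hap * (s - 1), replace = TRUE),
                          nrow = n_hap)
      for (j in 2:s) {
        state[, j] <- ifelse(sw[, j - 1], new_state[, j - 1], state[, j - 1])
      }
    }
    H <- matrix(founders[cbind(as.vector(state), rep(seq_len(s), each = n_hap))],
                nrow = n_hap, ncol = s)
    maps[[ch]] <- tibble(
      snp_id = sprintf("snp%d_%05d", ch, seq_len(s)),
      chrom = as.character(ch), pos_bp = as.integer(pos),
      ref = "A", alt = "C"
    )
    hap_chunks[[ch]] <- list(H = H, founders = founders)
  }

  qtl <- NULL
  if (cfg$implant_qtl) {
    ch <- cfg$qtl_chrom
    H <- hap_chunks[[ch]]$H
    founders <- hap_chunks[[ch]]$founders
    w0 <- cfg$qtl_window_start
    w1 <- w0 + cfg$window_size - 1L
    span <- cfg$span_start:cfg$span_end
    core <- w0:w1
    # unique core string: must differ from every founder's core substring
    repeat {
      core_str <- rbinom(cfg$window_size, 1L, 0.5)
      dmin <- min(apply(founders[, core, drop = FALSE], 1L,
                        function(f) sum(f != core_str)))
      if (dmin >= 3L) break
    }
    carrier <- rbinom(n_hap, 1L, cfg$qtl_hap_freq) == 1L
    if (any(carrier)) {
      span_template <- founders[1L, span]
      H[carrier, span] <- matrix(span_template, nrow = sum(carrier),
                                 ncol = length(span), byrow = TRUE)
      H[carrier, core] <- matrix(core_str, nrow = sum(carrier),
                                 ncol = length(core), byrow = TRUE)
    }
    hap_chunks[[ch]]$H <- H
    offset <- if (ch > 1) sum(cfg$n_snps_per_chrom[seq_len(ch - 1)]) else 0L
    map_ch <- maps[[ch]]
    qtl <- list(
      chrom = as.character(ch),
      window_start_index = offset + w0, window_end_index = offset + w1,
      window_start_bp = map_ch$pos_bp[w0], window_end_bp = map_ch$pos_bp[w1],
      span_start_index = offset + cfg$span_start,
      span_end_index = offset + cfg$span_end,
      span_start_bp = map_ch$pos_bp[cfg$span_start],
      span_end_bp = map_ch$pos_bp[cfg$span_end],
      hap = paste(core_str, collapse = ""),
      seed = cfg$seed
    )
  }

  map <- dplyr::bind_rows(maps)
  H_all <- do.call(cbind, lapply(hap_chunks, `[[`, "H"))
  odd <- seq(1L, n_hap, by = 2L)
  panel <- new_haplotype_panel(map, H_all[odd, , drop = FALSE],
                               H_all[odd + 1L, , drop = FALSE], sample_ids)

  status <- if (is.null(qtl)) {
    tibble(sample_id = sample_ids, copies = 0L)
  } else {
    assign_status(panel, qtl$window_start_index, qtl$window_end_index, qtl$hap)
  }
  list(panel = panel, status = status, qtl = qtl)
}

#' Construct a haplotype panel object
#'
#' @param markers Marker map tibble (`snp_id`, `chrom`, `pos_bp`, and
#'   optionally `ref`, `alt`); positions must be strictly increasing within
#'   chromosome.
#' @param H1,H2 Integer 0/1 matrices, samples in rows, markers in columns.
#' @param sample_ids Character vector of sample names.
#' @return A list of class `haplotype_panel`.
#' @export
new_haplotype_panel <- function(markers, H1, H2, sample_ids) {
  stopifnot(ncol(H1) == nrow(markers), ncol(H2) == nrow(markers),
            nrow(H1) == length(sample_ids), nrow(H2) == length(sample_ids))
  if (!all(H1 %in% c(0L, 1L)) || !all(H2 %in% c(0L, 1L))) {
    abort("phased alleles must be 0/1")
  }
  bad <- markers |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos_bp) > 0) || dplyr::n() == 1) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) abort("marker positions must be strictly increasing within chromosome")
  structure(list(markers = as_tibble(markers),
                 H1 = H1, H2 = H2, sample_ids = sample_ids),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d samples x %d markers on %d chromosome(s)\n",
              length(x$sample_ids), nrow(x$markers),
              dplyr::n_distinct(x$markers$chrom)))
  invisible(x)
}

#' Simulate a pedigree for the genotyped bulls
#'
#' Founder sires and dams (unknown parents) plus the genotyped bulls as their
#' offspring, giving paternal half-sib family structure typical of AI
#' breeding.
#'
#' @param cfg A [sim_config()].
#' @param sample_ids Bull identifiers (defaults to the panel's ids).
#' @return A tibble `animal`, `sire`, `dam` (NA = unknown), parents first.
#' @export
simulate_pedigree <- function(cfg, sample_ids = sprintf("B%04d", seq_len(cfg$n_bulls))) {
  set.seed(cfg$seed + 11L)
  sires <- sprintf("S%03d", seq_len(cfg$n_sires))
  dams <- sprintf("D%04d", seq_len(cfg$n_dams))
  dplyr::bind_rows(
    tibble(animal = c(sires, dams), sire = NA_character_, dam = NA_character_),
    tibble(animal = sample_ids,
           sire = sample(sires, length(sample_ids), replace = TRUE),
           dam = sample(dams, length(sample_ids), replace = TRUE))
  )
}

#' Simulate repeated ejaculate records
#'
#' Per-record trait values follow the repeated-records animal model: a status
#' mean, an additive genetic effect transmitted along the pedigree (offspring
#' receive the parent average plus a Mendelian-sampling deviation), a
#' permanent-environment effect, collector, season (calendar quarter) and age
#' effects, and a record-level residual. Components are scaled so that
#' per-bull average phenotypes have the configured trait SDs and
#' `Var(g) = h2 * sigma2`, `Var(g + pe) = repeatability * sigma2` at the
#' record level. Deliberate quality-control violations listed in
#' `cfg$qc_violations` are appended as cloned records altered in exactly one
#' field, and their row ids and per-rule counts are returned in the manifest.
#'
#' Supported violation names: `interval_missing`, `age_range`,
#' `volume_missing`, `motility_missing`, `rejection_cause`, `motility_min`,
#' `volume_min`, `concentration_min`, `pooled`, `duplicate_day`,
#' `collector_missing`, `score_implausible`, `straw_range`,
#' `min_ejaculates` (adds one extra bull with that many records, fewer than
#' the per-bull minimum).
#'
#' @param cfg A [sim_config()].
#' @param status Tibble `sample_id`, `copies` from [simulate_panel()].
#' @param pedigree Optional pedigree tibble; simulated if `NULL`.
#' @return A list with `records` (ejaculate tibble), `pedigree`, and
#'   `manifest` (true variance components per trait, per-bull genetic values,
#'   injected-violation bookkeeping).
#' @export
simulate_records <- function(cfg, status, pedigree = NULL) {
  validate_sim_config(cfg)
  if (is.null(pedigree)) pedigree <- simulate_pedigree(cfg, status$sample_id)
  set.seed(cfg$seed + 23L)
  bulls <- status$sample_id
  n <- length(bulls)
  m <- sample(seq(cfg$records_per_bull[1], cfg$records_per_bull[2]),
              n, replace = TRUE)
  mbar <- mean(m)
  r <- cfg$repeatability
  h2 <- cfg$h2

  # pedigree-ordered genetic effects, one independent set per trait
  ped <- pedigree
  idx <- setNames(seq_len(nrow(ped)), ped$animal)
  traits <- cfg$traits
  k <- nrow(traits)
  sigma2_rec <- traits$sd^2 / (r + (1 - r) / mbar)
  g <- matrix(0, nrow(ped), k)
  for (t in seq_len(k)) {
    sg <- sqrt(h2 * sigma2_rec[t])
    for (i in seq_len(nrow(ped))) {
      s <- ped$sire[i]; d <- ped$dam[i]
      if (is.na(s) && is.na(d)) {
        g[i, t] <- rnorm(1, 0, sg)
      } else {
        ps <- if (is.na(s)) 0 else g[idx[[s]], t]
        pd <- if (is.na(d)) 0 else g[idx[[d]], t]
        nk <- (!is.na(s)) + (!is.na(d))
        mend_var <- h2 * sigma2_rec[t] * (1 - 0.25 * nk)
        g[i, t] <- 0.5 * (ps + pd) + rnorm(1, 0, sqrt(mend_var))
      }
    }
  }
  pe <- matrix(rnorm(n * k), n, k) %*% diag(sqrt(pmax(0, (r - h2) * sigma2_rec)), k)
  g_bulls <- g[idx[bulls], , drop = FALSE]

  coll_ids <- sprintf("C%02d", seq_len(cfg$n_collectors))
  coll_eff <- matrix(rnorm(cfg$n_collectors * k), cfg$n_collectors, k) %*%
    diag(cfg$collector_sd * traits$sd, k)
  seas_eff <- matrix(rnorm(4 * k), 4, k) %*% diag(cfg$season_sd * traits$sd, k)

  birth <- as.Date("2012-01-01") + sample.int(1000L, n, replace = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    age0 <- sample(405:470, 1L)
    gaps <- sample(7:21, m[i], replace = TRUE)
    ages <- age0 + cumsum(gaps) - gaps[1]
    rows[[i]] <- tibble(
      bull_id = bulls[i],
      collection_date = birth[i] + ages,
      age_days = as.integer(ages),
      interval_days = as.integer(gaps),
      collector_id = sample(coll_ids, m[i], replace = TRUE)
    )
  }
  rec <- dplyr::bind_rows(rows)
  n_rec <- nrow(rec)
  season <- quarter_of(rec$collection_date)
  bi <- match(rec$bull_id, bulls)
  ci <- match(rec$collector_id, coll_ids)
  stshift <- status$copies[bi]

  vals <- matrix(0, n_rec, k)
  for (t in seq_len(k)) {
    mu <- c(traits$mean0[t], traits$mean1[t], traits$mean2[t])[stshift + 1L]
    e <- rnorm(n_rec, 0, sqrt((1 - r) * sigma2_rec[t]))
    vals[, t] <- mu + g_bulls[bi, t] + pe[bi, t] +
      coll_eff[ci, t] + seas_eff[season, t] +
      cfg$age_slope * traits$sd[t] * (rec$age_days - 700) / 300 + e
  }
  colnames(vals) <- traits$trait
  rec <- dplyr::bind_cols(rec, as_tibble(vals))
  # clean records are generated clear of every QC boundary so that the
  # attrition log reflects deliberately injected violations exactly
  rec$motility_pct <- pmin(100, pmax(70, rec$motility_pct))
  rec$volume_ml <- pmax(1.05, rec$volume_ml)
  rec$concentration_1e9_per_ml <- pmax(0.305, rec$concentration_1e9_per_ml)
  rec$sperm_per_straw_mio <- pmin(25, pmax(15, rec$sperm_per_straw_mio))
  rec$head_score <- as.integer(pmin(3, pmax(0, round(rec$head_score))))
  rec$tail_score <- as.integer(pmin(3, pmax(0, round(rec$tail_score))))
  rec$pooled_flag <- FALSE
  rec$rejection_cause <- NA_character_
  rec <- dplyr::select(
    rec, "bull_id", "collection_date", "age_days", "interval_days",
    "volume_ml", "concentration_1e9_per_ml", "motility_pct",
    "head_score", "tail_score", "sperm_per_straw_mio",
    "collector_id", "pooled_flag", "rejection_cause"
  )

  inj <- inject_qc_violations(rec, cfg$qc_violations)
  manifest <- list(
    seed = cfg$seed,
    sigma2_record = setNames(sigma2_rec, traits$trait),
    sigma_g2 = setNames(h2 * sigma2_rec, traits$trait),
    sigma_pe2 = setNames((r - h2) * sigma2_rec, traits$trait),
    sigma_e2 = setNames((1 - r) * sigma2_rec, traits$trait),
    h2 = h2, repeatability = r,
    genetic_values = tibble(bull_id = bulls, !!!as_tibble(setNames(
      as.data.frame(g_bulls), paste0("g_", traits$trait)))),
    expected_removals = inj$expected_removals,
    injected_rows = inj$injected_rows
  )
  list(records = inj$records, pedigree = pedigree, manifest = manifest)
}

quarter_of <- function(date) {
  (as.integer(format(as.Date(date), "%m")) - 1L) %/% 3L + 1L
}

inject_qc_violations <- function(rec, viol) {
  if (length(viol) == 0) {
    return(list(records = rec, expected_removals = integer(0),
                injected_rows = integer(0)))
  }
  known <- c("interval_missing", "age_range", "volume_missing",
             "motility_missing", "rejection_cause", "motility_min",
             "volume_min", "concentration_min", "pooled", "duplicate_day",
             "collector_missing", "score_implausible", "straw_range",
             "min_ejaculates")
  bad <- setdiff(names(viol), known)
  if (length(bad) > 0) abort(paste0("unknown QC violation rule(s): ",
                                    paste(bad, collapse = ", ")))
  extra <- list()
  for (rule in names(viol)) {
    cnt <- viol[[rule]]
    if (cnt <= 0) next
    if (rule == "min_ejaculates") {
      base <- rec[sample.int(nrow(rec), cnt, replace = TRUE), ]
      base$bull_id <- "BX_FEW"
      base$collection_date <- base$collection_date + seq_len(cnt) * 400
      extra[[rule]] <- base
      next
    }
    base <- rec[sample.int(nrow(rec), cnt), ]
    # rules checked after the first-per-day step need clone dates that do not
    # collide with the source record's (bull, date) key
    shift <- c(collector_missing = 1L, score_implausible = 2L, straw_range = 3L)
    if (rule %in% names(shift)) {
      base$collection_date <- base$collection_date + shift[[rule]]
      base$age_days <- base$age_days + shift[[rule]]
    }
    base <- switch(rule,
      interval_missing = dplyr::mutate(base, interval_days = NA_integer_),
      age_range = dplyr::mutate(base, age_days = sample(c(399L, 1001L), cnt, replace = TRUE),
                                collection_date = .data$collection_date + 40000),
      volume_missing = dplyr::mutate(base, volume_ml = NA_real_),
      motility_missing = dplyr::mutate(base, motility_pct = NA_real_),
      rejection_cause = dplyr::mutate(base, rejection_cause = "impurities"),
      motility_min = dplyr::mutate(base, motility_pct = runif(cnt, 40, 69.9)),
      volume_min = dplyr::mutate(base, volume_ml = runif(cnt, 0.2, 1.0)),
      concentration_min = dplyr::mutate(base, concentration_1e9_per_ml = runif(cnt, 0.05, 0.3)),
      pooled = dplyr::mutate(base, pooled_flag = TRUE),
      duplicate_day = base,  # identical (bull, date): removed at first-per-day
      collector_missing = dplyr::mutate(base, collector_id = NA_character_),
      score_implausible = dplyr::mutate(base, head_score = 7L),
      straw_range = dplyr::mutate(base, sperm_per_straw_mio = sample(c(9, 31), cnt, replace = TRUE))
    )
    # age_range shifts must keep other rules satisfied: undo date shift side
    # effects by leaving all other fields untouched
    extra[[rule]] <- base
  }
  injected <- dplyr::bind_rows(extra)
  out <- dplyr::bind_rows(rec, injected)
  list(records = out,
       expected_removals = vapply(extra, nrow, integer(1)),
       injected_rows = if (nrow(injected)) (nrow(rec) + 1L):nrow(out) else integer(0))
}

#' Simulate insemination records with known bull fertility
#'
#' Bernoulli 56-day non-return outcomes whose success probability is the base
#' rate shifted by the bull's true fertility plus month, parity, straw-price,
#' breed-combination, technician and herd effects.
#'
#' @param cfg A [sim_config()].
#' @param fertility_truth Tibble `bull_id`, `truth` (true fertility in SD
#'   units), or a named numeric vector.
#' @return A tibble of insemination records (one row per insemination).
#' @export
simulate_inseminations <- function(cfg, fertility_truth) {
  if (!is.data.frame(fertility_truth)) {
    fertility_truth <- tibble(bull_id = names(fertility_truth),
                              truth = as.numeric(fertility_truth))
  }
  set.seed(cfg$seed + 37L)
  n_tech <- 30L; n_herd <- 50L
  tech_eff <- rnorm(n_tech, 0, 0.02)
  herd_eff <- rnorm(n_herd, 0, 0.02)
  month_eff <- rnorm(12L, 0, 0.02)
  price_eff <- c(0, 0.01, -0.01)
  breed_eff <- c(0, -0.015)
  rows <- purrr::map2(fertility_truth$bull_id, fertility_truth$truth, function(b, tr) {
    ni <- cfg$n_insem_per_bull
    month <- sample.int(12L, ni, replace = TRUE)
    parity <- sample(c("heifer", "cow"), ni, replace = TRUE)
    price <- sample.int(3L, ni, replace = TRUE)
    breed <- sample.int(2L, ni, replace = TRUE)
    tech <- sample.int(n_tech, ni, replace = TRUE)
    herd <- sample.int(n_herd, ni, replace = TRUE)
    p <- cfg$base_nrr + cfg$fertility_scale * tr + month_eff[month] +
      0.03 * (parity == "cow") + price_eff[price] + breed_eff[breed] +
      tech_eff[tech] + herd_eff[herd]
    p <- pmin(0.98, pmax(0.02, p))
    tibble(bull_id = b, month = month, parity = parity,
           straw_price = paste0("P", price),
           breed_combination = paste0("BC", breed),
           technician_id = sprintf("T%02d", tech),
           herd_id = sprintf("H%03d", herd),
           outcome = rbinom(ni, 1L, p))
  })
  dplyr::bind_rows(rows)
}

#' Simulate a candidate-region VCF with known recessive compatibility
#'
#' Writes a plain-text VCF in which exactly `n_compatible` variants satisfy
#' the recessive-compatibility rule for the supplied haplotype-status groups
#' and every other variant violates exactly one threshold. The violated group
#' (or `missing` for all-missing genotypes) is recorded in the INFO field
#' (`VIOL=`), and compatible variants carry `COMPAT=1`, so downstream filters
#' can be checked against constructed truth.
#'
#' @param groups A list with character vectors `hom`, `het`, `non` (sample ids
#'   by haplotype status), or a status tibble accepted by [status_groups()].
#' @param n_variants,n_compatible Total and rule-compatible variant counts.
#' @param seed Integer seed.
#' @param path Output VCF path.
#' @param chrom,start,end Region simulated.
#' @param n_missing Number of variants (among the incompatible ones) whose
#'   genotypes are all missing.
#' @param sv If `TRUE`, write symbolic structural-variant records
#'   (`<DEL>`, `<DUP>`, ...) instead of SNPs/indels.
#' @return Invisibly, a tibble of per-variant ground truth (`pos`,
#'   `compatible`, `violation`).
#' @export
simulate_region_vcf <- function(groups, n_variants, n_compatible, seed = 1L,
                                path = tempfile(fileext = ".vcf"),
                                chrom = "6", start = 55e6, end = 65e6,
                                n_missing = 0L, sv = FALSE) {
  if (is.data.frame(groups)) groups <- status_groups(groups)
  if (length(groups$hom) == 0) {
    abort("recessive-compatibility simulation requires at least one homozygous carrier")
  }
  if (n_compatible > n_variants) abort("n_compatible exceeds n_variants")
  if (n_missing > n_variants - n_compatible) {
    abort("n_missing must fit among the incompatible variants")
  }
  set.seed(seed)
  samples <- c(groups$hom, groups$het, groups$non)
  nh <- length(groups$hom); ne <- length(groups$het); nn <- length(groups$non)
  pos <- sort(sample(seq(as.integer(start), as.integer(end)), n_variants))
  compat <- rep(FALSE, n_variants)
  compat[sample.int(n_variants, n_compatible)] <- TRUE
  viol_pool <- c("hom", "het", "non")
  viol <- rep(NA_character_, n_variants)
  viol[!compat] <- rep_len(viol_pool, sum(!compat))
  if (n_missing > 0) {
    viol[sample(which(!compat), n_missing)] <- "missing"
  }

  gt_line <- function(i) {
    if (!is.na(viol[i]) && viol[i] == "missing") {
      return(rep("./.", nh + ne + nn))
    }
    hom <- rep("1/1", nh)
    if (compat[i] && nh >= 3 && runif(1) < 0.5) hom[nh] <- "0/1"  # e.g. 5/6 alleles
    het <- rep("0/1", ne)
    non <- rep("0/0", nn)
    if (!compat[i]) {
      switch(viol[i],
        hom = { hom <- rep("0/1", nh) },
        het = { het <- rep(sample(c("1/1", "0/0"), 1), ne) },
        non = { k <- max(1L, ceiling(0.12 * 2 * nn))
                non[seq_len(min(k, nn))] <- "0/1" }
      )
    }
    c(hom, het, non)
  }

  if (sv) {
    svtypes <- sample(c("DEL", "DUP", "INV", "INS"), n_variants, replace = TRUE)
    ref <- rep("N", n_variants)
    alt <- paste0("<", svtypes, ">")
  } else {
    is_indel <- runif(n_variants) < 0.15
    ref <- ifelse(is_indel, "AT", sample(c("A", "C", "G", "T"), n_variants, replace = TRUE))
    alt <- ifelse(is_indel, "A", ifelse(ref == "G", "T", "G"))
  }
  info <- ifelse(compat, "COMPAT=1", paste0("VIOL=", viol))
  if (sv) info <- paste0(info, ";SVTYPE=", svtypes, ";END=", pos + 1000L)

  body <- vapply(seq_len(n_variants), function(i) {
    paste(c(chrom, pos[i], sprintf("var%05d", i), ref[i], alt[i], ".",
            "PASS", info[i], "GT", gt_line(i)), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, as.integer(end + 1e6)),
    "##INFO=<ID=COMPAT,Number=0,Type=Flag,Description=\"Constructed rule-compatible variant\">",
    "##INFO=<ID=VIOL,Number=1,Type=String,Description=\"Constructed violated group\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(tibble(pos = pos, compatible = compat, violation = viol))
}

#' Construct a synthetic gene with a variant-activated cryptic splice donor
#'
#' Builds a three-exon plus-strand gene and region sequence in which a C>T
#' substitution 8 bp upstream of the natural splice-donor site of the middle
#' exon creates a strong cryptic GT donor 9 bp upstream of the natural exon
#' end. Use of the cryptic donor truncates the exon by 9 bp (in frame) and
#' deletes protein residues 414-416: the coding sequence upstream of the
#' truncated bases spans exactly 413 codons. The reference sequence carries
#' GC at the cryptic position, so the donor exists only on the alternate
#' allele.
#'
#' @param seed Integer seed for the filler codons.
#' @return A list: `gene` (a [gene_model()]), `seq` and `seq_start` (region
#'   sequence), `variant` (`pos`, `ref`, `alt`), `junction` (a
#'   [splice_junction_pair()] for the natural vs cryptic junction), and
#'   `expected` (constructed truth: truncation, frame, deleted residues).
#' @export
simulate_splice_gene <- function(seed = 1L) {
  set.seed(seed)
  safe_codons <- c("GCT", "GAA", "TTG", "CGA", "AAA", "ACC", "GAT", "TGC",
                   "ATG", "TCG", "CAT", "GGA")
  rand_cds <- function(n_codons) {
    paste(sample(safe_codons, n_codons, replace = TRUE), collapse = "")
  }
  rand_seq <- function(n) paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")

  exon1_cds <- rand_cds(396)                             # 1188 bp, codons 1..396
  exon2_head <- rand_cds(16)                             # 48 bp, codons 397..412
  exon2_tail <- "CAGGCAAGTCAA"                           # C>T at base 5 creates CAG|GTAAGT
  exon3_cds <- paste0("AAA", rand_cds(9))                # 30 bp, first codon differs from GTA
  intron1 <- paste0("GT", rand_seq(196), "AG")           # 200 bp
  intron2 <- paste0("GTAAGT", rand_seq(142), "AG")       # 150 bp
  utr5 <- rand_seq(1000)
  utr3 <- rand_seq(60)

  seq <- paste0(utr5, exon1_cds, intron1, exon2_head, exon2_tail, intron2,
                exon3_cds, utr3)
  e1s <- 1001L; e1e <- e1s + 1188L - 1L                  # 1001..2188
  e2s <- e1e + 200L + 1L; e2e <- e2s + 60L - 1L          # 2389..2448
  e3s <- e2e + 150L + 1L; e3e <- e3s + 30L - 1L          # 2599..2628
  gene <- gene_model(tibble(start = c(e1s, e2s, e3s), end = c(e1e, e2e, e3e)),
                     cds_start = e1s, cds_end = e3e)
  variant <- list(chrom = "6", pos = e2e - 7L, ref = "C", alt = "T")
  list(
    gene = gene, seq = seq, seq_start = 1L, variant = variant,
    junction = splice_junction_pair(e2e, e3s, truncation = 9L),
    expected = list(g_pos = e2e - 8L, truncation = 9L, frame = "in-frame",
                    res_start = 414L, res_end = 416L)
  )
}

#' Simulate junction-spanning RNA-seq reads as a SAM file
#'
#' Writes spliced alignments (`aM nN bM` CIGARs) supporting either the
#' wild-type or the truncated (mutant) exon junction, with at least
#' `min_overhang` aligned bases on each side of the junction. Counts are
#' exact. Custom reads (e.g. sub-overhang alignments) can be supplied via
#' `extra_reads`.
#'
#' @param wt_count,mt_count Number of reads supporting each junction.
#' @param junction A [splice_junction_pair()].
#' @param read_len Read length in basepairs.
#' @param seed Integer seed.
#' @param path Output SAM path.
#' @param chrom Reference name written to the header.
#' @param min_overhang Minimum aligned bases on each side of the junction.
#' @param extra_reads Optional tibble `junction` ("wt"/"mt"), `left_len`,
#'   `right_len` for hand-specified block lengths.
#' @return `path`, invisibly.
#' @export
simulate_junction_reads <- function(wt_count, mt_count, junction,
                                    read_len = 100L, seed = 1L,
                                    path = tempfile(fileext = ".sam"),
                                    chrom = "6", min_overhang = 10L,
                                    extra_reads = NULL) {
  set.seed(seed)
  stopifnot(wt_count >= 0, mt_count >= 0, read_len >= 2 * min_overhang)
  mk_read <- function(id, donor_end, acceptor_start, left_len, right_len) {
    gap <- acceptor_start - donor_end - 1L
    pos <- donor_end - left_len + 1L
    cigar <- sprintf("%dM%dN%dM", left_len, gap, right_len)
    paste(c(id, 0L, chrom, pos, 60L, cigar, "*", 0L, 0L,
            strrep("A", left_len + right_len), "*"), collapse = "\t")
  }
  lines <- character(0)
  if (wt_count > 0) {
    ll <- sample(seq(min_overhang, read_len - min_overhang), wt_count, replace = TRUE)
    lines <- c(lines, vapply(seq_len(wt_count), function(i) {
      mk_read(sprintf("wt%04d", i), junction$wt["donor_end"],
              junction$wt["acceptor_start"], ll[i], read_len - ll[i])
    }, character(1)))
  }
  if (mt_count > 0) {
    ll <- sample(seq(min_overhang, read_len - min_overhang), mt_count, replace = TRUE)
    lines <- c(lines, vapply(seq_len(mt_count), function(i) {
      mk_read(sprintf("mt%04d", i), junction$mt["donor_end"],
              junction$mt["acceptor_start"], ll[i], read_len - ll[i])
    }, character(1)))
  }
  if (!is.null(extra_reads)) {
    lines <- c(lines, vapply(seq_len(nrow(extra_reads)), function(i) {
      j <- junction[[extra_reads$junction[i]]]
      mk_read(sprintf("x%04d", i), j["donor_end"], j["acceptor_start"],
              extra_reads$left_len[i], extra_reads$right_len[i])
    }, character(1)))
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, 2e8))
  writeLines(c(header, lines), path)
  invisible(path)
}
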