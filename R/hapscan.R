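#' Genotype quality control
#'
#' Drops samples with more than `max_missing` missing genotypes, then SNPs
#' with more than `max_missing` missingness, SNPs with minor allele frequency
#' below `maf_min`, and SNPs whose genotype distribution deviates from
#' Hardy-Weinberg proportions at `hwe_p` (exact test).
#'
#' @param genotypes Integer matrix of 0/1/2 allele dosages (samples x SNPs,
#'   `NA` = missing) with sample ids as rownames.
#' @param map Marker map tibble aligned to the columns.
#' @param max_missing Missingness threshold for samples and SNPs.
#' @param maf_min Minor-allele-frequency threshold (SNPs with MAF strictly
#'   below are removed).
#' @param hwe_p Hardy-Weinberg exact-test threshold (SNPs with P strictly
#'   below are removed).
#' @return A list `genotypes`, `map`, and `removed` (per-criterion counts).
#' @export
qc_genotypes <- function(genotypes, map, max_missing = 0.2, maf_min = 0.005,
                         hwe_p = 1e-5) {
  stopifnot(ncol(genotypes) == nrow(map))
  miss_sample <- rowMeans(is.na(genotypes))
  keep_s <- miss_sample <= max_missing
  genotypes <- genotypes[keep_s, , drop = FALSE]
  miss_snp <- colMeans(is.na(genotypes))
  keep_miss <- miss_snp <= max_missing
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_maf <- !is.na(maf) & maf >= maf_min
  hwe <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                   sum(g == 2, na.rm = TRUE))
  }, numeric(1))
  keep_hwe <- hwe >= hwe_p
  keep <- keep_miss & keep_maf & keep_hwe
  if (!any(keep)) abort("all SNPs removed by genotype QC")
  list(
    genotypes = genotypes[, keep, drop = FALSE],
    map = map[keep, , drop = FALSE],
    removed = c(samples = sum(!keep_s), snp_missing = sum(!keep_miss),
                snp_maf = sum(keep_miss & !keep_maf),
                snp_hwe = sum(keep_miss & keep_maf & !keep_hwe))
  )
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test for deviation from Hardy-Weinberg proportions given
#' genotype counts, summing the probabilities of all heterozygote counts no
#' more likely than the observed one (no mid-p correction). Uses the standard
#' recurrence over heterozygote counts.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (hom ref, het, hom alt).
#' @return The exact P value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  het_obs <- n_ab
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # recurrences over the heterozygote count at fixed allele counts
  mid <- which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))
  probs[mid] <- 1
  if (mid < length(hets)) {
    for (k in mid:(length(hets) - 1)) {
      het <- hets[k]
      hom_r <- (rare - het) / 2
      hom_c <- (2 * n - rare - het) / 2
      probs[k + 1] <- probs[k] * 4 * hom_r * hom_c / ((het + 2) * (het + 1))
    }
  }
  if (mid > 1) {
    for (k in mid:2) {
      het <- hets[k]
      hom_r <- (rare - het) / 2
      hom_c <- (2 * n - rare - het) / 2
      probs[k - 1] <- probs[k] * het * (het - 1) /
        (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(het_obs, hets)]
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}

#' Principal components of the genomic relationship matrix
#'
#' Builds a VanRaden-style GRM from the centered, variance-standardized
#' genotype matrix and returns the leading eigenvectors scaled by the square
#' root of their eigenvalues.
#'
#' @param genotypes 0/1/2 dosage matrix (samples x SNPs); sporadically
#'   missing genotypes are mean-imputed for the decomposition.
#' @param k Number of components.
#' @return A tibble `sample_id`, `PC1` ... `PCk`.
#' @export
grm_pcs <- function(genotypes, k = 10) {
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  G <- genotypes[, keep, drop = FALSE]
  p <- p[keep]
  M <- sweep(G, 2, 2 * p)
  M <- sweep(M, 2, sqrt(2 * p * (1 - p)), "/")
  M[is.na(M)] <- 0
  K <- tcrossprod(M) / ncol(M)
  ev <- eigen(K, symmetric = TRUE)
  k <- min(k, ncol(K))
  pcs <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(k)], 0)), k)
  colnames(pcs) <- paste0("PC", seq_len(k))
  ids <- rownames(genotypes) %||% paste0("S", seq_len(nrow(genotypes)))
  dplyr::bind_cols(tibble(sample_id = ids), as_tibble(pcs))
}

#' Genotype dosages of a haplotype panel
#'
#' @param panel A `haplotype_panel`.
#' @return Integer 0/1/2 matrix (samples x markers).
#' @export
panel_genotypes <- function(panel) {
  G <- panel$H1 + panel$H2
  rownames(G) <- panel$sample_ids
  colnames(G) <- panel$markers$snp_id
  G
}

#' Enumerate sliding haplotype windows
#'
#' Windows of `size` contiguous markers advanced in steps of `step` markers,
#' independently per chromosome; only complete windows are emitted, so
#' trailing markers shorter than a window are untested.
#'
#' @param map Marker map tibble (`chrom`, `pos_bp`), in map order.
#' @param size,step Window size and step, in markers.
#' @return A tibble `window_id`, `chrom`, `start_index`, `end_index` (row
#'   indices into `map`), `start_bp`, `end_bp`.
#' @export
enumerate_windows <- function(map, size = 50, step = 15) {
  out <- list()
  for (ch in unique(map$chrom)) {
    rows <- which(map$chrom == ch)
    s <- length(rows)
    if (s < size) next
    starts <- seq(1L, s - size + 1L, by = step)
    out[[ch]] <- tibble(
      chrom = ch,
      start_index = rows[starts],
      end_index = rows[starts + size - 1L],
      start_bp = map$pos_bp[rows[starts]],
      end_bp = map$pos_bp[rows[starts + size - 1L]]
    )
  }
  res <- dplyr::bind_rows(out)
  dplyr::mutate(res, window_id = dplyr::row_number(), .before = 1)
}

#' Haplotypes observed in one window
#'
#' Haplotype identity is the exact allele string over the window's markers.
#' Copy counts are exact string matches on each phased chromosome; the
#' frequency is copies over `2N`. Only haplotypes with frequency strictly
#' above `min_freq` are returned, but copy counts always sum to `2N` before
#' that filter.
#'
#' @param panel A `haplotype_panel`.
#' @param start_index,end_index Window bounds as row indices into the map.
#' @param min_freq Frequency filter (default 1%).
#' @return A tibble `haplotype`, `count`, `freq`, `n_hom`, and a list-column
#'   `copies` holding the per-sample copy count vector.
#' @export
window_haplotypes <- function(panel, start_index, end_index, min_freq = 0.01) {
  cols <- start_index:end_index
  s1 <- hap_strings(panel$H1, cols)
  s2 <- hap_strings(panel$H2, cols)
  all_str <- c(s1, s2)
  tab <- sort(table(all_str), decreasing = TRUE)
  n2 <- length(all_str)
  res <- tibble(
    haplotype = names(tab),
    count = as.integer(tab),
    freq = as.integer(tab) / n2
  )
  res <- dplyr::filter(res, .data$freq > min_freq)
  res$copies <- lapply(res$haplotype, function(h) {
    (s1 == h) + (s2 == h)
  })
  res$n_hom <- vapply(res$copies, function(cp) sum(cp == 2L), integer(1))
  res
}

hap_strings <- function(H, cols) {
  sub <- H[, cols, drop = FALSE]
  do.call(paste0, as.data.frame(sub))
}

#' Association test of one haplotype under a chosen inheritance model
#'
#' Ordinary least squares of the phenotype on an intercept, the supplied
#' principal components, optional conditioning covariates, and the haplotype
#' predictor: copy count (additive), carrier indicator (dominant) or
#' homozygosity indicator (recessive). The P value is the two-sided t-test of
#' the predictor coefficient.
#'
#' @param y Phenotype vector.
#' @param pcs Numeric matrix of covariates (may have zero columns).
#' @param copies Integer vector of haplotype copies (0/1/2) per sample.
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @param condition Optional numeric matrix/vector of conditioning
#'   covariates.
#' @return A one-row tibble `model`, `beta`, `se`, `p`, `n`, or `NULL` when
#'   the coded predictor is constant (test skipped).
#' @export
test_haplotype <- function(y, pcs, copies, model = c("additive", "dominant", "recessive"),
                           condition = NULL) {
  model <- match.arg(model)
  x <- code_predictor(copies, model)
  keep <- !is.na(y)
  y <- y[keep]; x <- x[keep]
  pcs <- if (is.null(pcs)) matrix(0, length(y), 0) else as.matrix(pcs)[keep, , drop = FALSE]
  if (!is.null(condition)) condition <- as.matrix(condition)[keep, , drop = FALSE]
  if (var(x) < .Machine$double.eps) return(NULL)
  Xbase <- cbind(`(Intercept)` = 1, pcs, condition)
  fit <- lm.fit(cbind(Xbase, hap = x), y)
  df <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  R <- qr.R(fit$qr)
  XtXi <- chol2inv(R)
  j <- fit$rank
  beta <- fit$coefficients[["hap"]]
  if (is.na(beta)) return(NULL)
  se <- sqrt(rss / df * XtXi[j, j])
  tval <- beta / se
  tibble(model = model, beta = beta, se = se,
         p = 2 * pt(-abs(tval), df), n = length(y))
}

code_predictor <- function(copies, model) {
  switch(model,
         additive = as.numeric(copies),
         dominant = as.numeric(copies >= 1),
         recessive = as.numeric(copies == 2))
}

#' Genome-wide sliding-window haplotype association scan
#'
#' Tests every haplotype with frequency above `min_freq` in every complete
#' window under the requested inheritance model, adjusting for the top
#' principal components. Recessive tests are only performed for haplotypes
#' homozygous in at least `ceiling(0.01 * N)` individuals. The Bonferroni
#' threshold is 0.05 divided by the number of haplotype tests actually
#' performed, and the genomic inflation factor is
#' `median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`.
#'
#' Internally each test residualizes the phenotype and predictor on the base
#' design (intercept, PCs, conditioning covariates) once per scan, which is
#' algebraically identical to the full ordinary-least-squares fit.
#'
#' @param panel A `haplotype_panel`.
#' @param phenotypes Tibble `sample_id`, `value` (or a vector named by
#'   sample id). Samples without phenotype are dropped from the scan.
#' @param pcs Tibble from [grm_pcs()], a numeric matrix, or `NULL`.
#' @param model Inheritance model for the haplotype predictor.
#' @param window_size,step Window geometry in markers.
#' @param min_freq Haplotype frequency filter.
#' @param min_hom_frac Minimum homozygote fraction for recessive tests.
#' @param condition Optional per-sample conditioning covariate(s): numeric
#'   vector/matrix aligned to the panel, e.g. a haplotype-status coding from
#'   [condition_covariate()]. A constant covariate is ignored, making the
#'   scan identical to the unconditioned one.
#' @return An object of class `hap_scan`: tibble of association records plus
#'   `n_windows`, `n_tests`, `bonferroni_alpha`, `lambda`, `model`.
#' @export
hap_scan <- function(panel, phenotypes, pcs = NULL,
                     model = c("recessive", "additive", "dominant"),
                     window_size = 50, step = 15, min_freq = 0.01,
                     min_hom_frac = 0.01, condition = NULL) {
  model <- match.arg(model)
  y_all <- align_phenotypes(panel, phenotypes)
  keep <- !is.na(y_all)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("%d sample(s) without phenotype dropped from scan", n_dropped))
  }
  y <- y_all[keep]
  n <- length(y)
  P <- pcs_matrix(pcs, panel$sample_ids)[keep, , drop = FALSE]
  cond <- NULL
  if (!is.null(condition)) {
    cond <- as.matrix(condition)[keep, , drop = FALSE]
    cond <- cond[, apply(cond, 2, var) > .Machine$double.eps, drop = FALSE]
    if (ncol(cond) == 0) cond <- NULL
  }
  Xbase <- cbind(rep(1, n), P, cond)
  qrB <- qr(Xbase)
  yr <- qr.resid(qrB, y)
  df <- n - qrB$rank - 1L
  min_hom <- ceiling(min_hom_frac * n)

  windows <- enumerate_windows(panel$markers, size = window_size, step = step)
  H1 <- panel$H1[keep, , drop = FALSE]
  H2 <- panel$H2[keep, , drop = FALSE]
  recs <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    cols <- windows$start_index[w]:windows$end_index[w]
    s1 <- hap_strings(H1, cols)
    s2 <- hap_strings(H2, cols)
    tab <- table(c(s1, s2))
    freq <- as.numeric(tab) / (2 * n)
    haps <- names(tab)[freq > min_freq]
    freqs <- freq[freq > min_freq]
    if (length(haps) == 0) next
    out <- vector("list", length(haps))
    for (h in seq_along(haps)) {
      cp <- (s1 == haps[h]) + (s2 == haps[h])
      n_hom <- sum(cp == 2L)
      if (model == "recessive" && n_hom < min_hom) next
      x <- code_predictor(cp, model)
      if (var(x) < .Machine$double.eps) next
      xr <- qr.resid(qrB, x)
      xx <- sum(xr^2)
      if (xx < .Machine$double.eps) next
      beta <- sum(xr * yr) / xx
      rss <- sum(yr^2) - beta^2 * xx
      se <- sqrt(rss / df / xx)
      tval <- beta / se
      out[[h]] <- tibble(
        window_id = windows$window_id[w], haplotype = haps[h],
        freq = freqs[h], n_hom = n_hom, beta = beta, se = se,
        p = 2 * pt(-abs(tval), df)
      )
    }
    recs[[w]] <- dplyr::bind_rows(out)
  }
  assoc <- dplyr::bind_rows(recs)
  assoc <- dplyr::left_join(assoc, windows, by = "window_id")
  assoc <- dplyr::select(assoc, "window_id", "chrom", "start_index",
                         "end_index", "start_bp", "end_bp", "haplotype",
                         "freq", "n_hom", "beta", "se", "p")
  n_tests <- nrow(assoc)
  structure(list(
    assoc = assoc,
    n_windows = nrow(windows),
    n_tests = n_tests,
    bonferroni_alpha = if (n_tests > 0) 0.05 / n_tests else NA_real_,
    lambda = genomic_lambda(assoc$p),
    model = model,
    conditioned = !is.null(cond),
    n_samples = n
  ), class = "hap_scan")
}

align_phenotypes <- function(panel, phenotypes) {
  if (is.data.frame(phenotypes)) {
    stopifnot(all(c("sample_id", "value") %in% names(phenotypes)))
    phenotypes <- setNames(phenotypes$value, phenotypes$sample_id)
  }
  as.numeric(phenotypes[panel$sample_ids])
}

pcs_matrix <- function(pcs, sample_ids) {
  if (is.null(pcs)) return(matrix(0, length(sample_ids), 0))
  if (is.data.frame(pcs)) {
    m <- as.matrix(pcs[match(sample_ids, pcs$sample_id),
                       setdiff(names(pcs), "sample_id"), drop = FALSE])
  } else {
    m <- as.matrix(pcs)
  }
  stopifnot(nrow(m) == length(sample_ids))
  m
}

#' Genomic inflation factor
#'
#' `median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`; approximately 1 when the P
#' values are uniform under the null.
#'
#' @param p Vector of P values.
#' @return The inflation factor lambda.
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) return(NA_real_)
  median(qchisq(1 - p, 1)) / qchisq(0.5, 1)
}

#' Conditioning covariate from haplotype status
#'
#' Recessive scans condition on the homozygosity indicator of the given
#' haplotype; additive scans condition on its copy count.
#'
#' @param status Tibble `sample_id`, `copies` (see [assign_status()]).
#' @param model Inheritance model of the scan to condition.
#' @param sample_ids Panel sample order.
#' @return A one-column numeric matrix aligned to `sample_ids`.
#' @export
condition_covariate <- function(status, model, sample_ids) {
  cp <- status$copies[match(sample_ids, status$sample_id)]
  matrix(code_predictor(cp, if (model == "dominant") "dominant" else model),
         ncol = 1, dimnames = list(NULL, "condition"))
}

#' Conditional haplotype scan
#'
#' Re-runs [hap_scan()] with the conditioning haplotype's coding added to
#' every regression: the homozygosity indicator for recessive scans, the copy
#' count for additive scans.
#'
#' @inheritParams hap_scan
#' @param condition_status Tibble `sample_id`, `copies` of the conditioning
#'   haplotype.
#' @return A `hap_scan` object.
#' @export
conditional_scan <- function(panel, phenotypes, pcs = NULL,
                             model = c("recessive", "additive", "dominant"),
                             condition_status, ...) {
  model <- match.arg(model)
  cond <- condition_covariate(condition_status, model, panel$sample_ids)
  hap_scan(panel, phenotypes, pcs = pcs, model = model, condition = cond, ...)
}

#' @export
print.hap_scan <- function(x, ...) {
  cat(sprintf("<hap_scan> model=%s%s: %d tests in %d windows (n=%d)\n",
              x$model, if (x$conditioned) " (conditional)" else "",
              x$n_tests, x$n_windows, x$n_samples))
  cat(sprintf("  Bonferroni alpha = %.3g, lambda = %.3f\n",
              x$bonferroni_alpha, x$lambda))
  if (x$n_tests > 0) {
    top <- x$assoc[which.min(x$assoc$p), ]
    cat(sprintf("  top: chr%s:%d-%d freq=%.3f p=%.3g\n", top$chrom,
                top$start_bp, top$end_bp, top$freq, top$p))
  }
  invisible(x)
}
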