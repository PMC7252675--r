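test_that("genotype QC removes low-MAF, monomorphic and HWE-violating SNPs", {
  set.seed(21)
  n <- 500
  g_ok <- rbinom(n, 2, 0.3)
  g_rare <- c(1L, rep(0L, n - 1))          # MAF 0.001 < 0.005
  g_mono <- rep(0L, n)
  g_hwe <- c(rep(0L, 250), rep(2L, 250))   # no heterozygotes at p = 0.5
  G <- cbind(g_ok, g_rare, g_mono, g_hwe)
  rownames(G) <- paste0("S", 1:n)
  map <- tibble::tibble(snp_id = colnames(G), chrom = "1",
                        pos_bp = 1:4 * 1000L)
  qc <- qc_genotypes(G, map)
  expect_equal(qc$map$snp_id, "g_ok")
  expect_equal(unname(qc$removed[c("snp_maf", "snp_hwe")]), c(2, 1))
  expect_error(qc_genotypes(G[, 3, drop = FALSE], map[3, ]), "all SNPs")
})

test_that("the Hardy-Weinberg exact test matches a full-enumeration oracle", {
  set.seed(22)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    p <- runif(1, 0.05, 0.95)
    g <- rbinom(n, 2, p)
    cnt <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
  expect_equal(hwe_exact_test(0, 0, 0), 1)
})

test_that("GRM principal components match the spectral decomposition and duplicate samples coincide", {
  set.seed(23)
  G <- matrix(rbinom(30 * 100, 2, runif(100, 0.1, 0.9)), nrow = 30,
              byrow = TRUE)
  G[2, ] <- G[1, ]  # exact duplicate
  rownames(G) <- paste0("S", 1:30)
  pcs <- grm_pcs(G, k = 5)
  expect_equal(as.numeric(pcs[1, -1]), as.numeric(pcs[2, -1]),
               tolerance = 1e-10)

  p <- colMeans(G) / 2
  keep <- p > 0 & p < 1
  M <- sweep(sweep(G[, keep], 2, 2 * p[keep]), 2,
             sqrt(2 * p[keep] * (1 - p[keep])), "/")
  K <- tcrossprod(M) / ncol(M)
  expect_lt(max(abs(rowSums(K))), 1e-8)  # centering
  ev <- eigen(K, symmetric = TRUE)
  for (j in 1:5) {
    ref <- ev$vectors[, j] * sqrt(ev$values[j])
    expect_lt(min(max(abs(pcs[[j + 1]] - ref)), max(abs(pcs[[j + 1]] + ref))),
              1e-8)
  }
})

test_that("window enumeration follows the 50/15 geometry and never spans chromosomes", {
  map80 <- tibble::tibble(snp_id = paste0("s", 1:80), chrom = "1",
                          pos_bp = 1:80 * 100L)
  w <- enumerate_windows(map80, size = 50, step = 15)
  expect_equal(nrow(w), 3)
  expect_equal(w$start_index, c(1L, 16L, 31L))
  expect_equal(w$end_index, c(50L, 65L, 80L))
  expect_equal(nrow(enumerate_windows(map80[1:50, ], 50, 15)), 1)
  expect_equal(nrow(enumerate_windows(map80[1:49, ], 50, 15)), 0)

  map2 <- dplyr::bind_rows(map80, dplyr::mutate(map80, chrom = "2"))
  w2 <- enumerate_windows(map2, 50, 15)
  expect_equal(nrow(w2), 6)
  for (i in seq_len(nrow(w2))) {
    expect_equal(map2$chrom[w2$start_index[i]], map2$chrom[w2$end_index[i]])
  }
})

test_that("window haplotypes are exact string matches with conserved copy counts", {
  set.seed(24)
  H <- matrix(rbinom(40 * 60, 1, 0.5), 40, 60)
  panel <- toy_panel(H[1:20, ], H[21:40, ])
  wh <- window_haplotypes(panel, 1, 50, min_freq = 0)
  expect_equal(sum(wh$count), 40)  # 2N conservation before any filter

  # a constructed string present on 24 of 100 chromosomes
  target <- rbinom(50, 1, 0.5)
  H1 <- matrix(rbinom(50 * 50, 1, 0.5), 50, 50)
  H2 <- matrix(rbinom(50 * 50, 1, 0.5), 50, 50)
  carrier <- sample(100, 24)
  for (i in carrier) {
    if (i <= 50) H1[i, ] <- target else H2[i - 50, ] <- target
  }
  p2 <- toy_panel(H1, H2)
  wh2 <- window_haplotypes(p2, 1, 50)
  tstr <- paste(target, collapse = "")
  expect_equal(wh2$freq[wh2$haplotype == tstr], 0.24)

  # all samples identical: a single haplotype at frequency 1
  p3 <- toy_panel(matrix(1L, 5, 50), matrix(1L, 5, 50))
  wh3 <- window_haplotypes(p3, 1, 50)
  expect_equal(nrow(wh3), 1)
  expect_equal(wh3$freq, 1)
})

test_that("the haplotype test equals a full OLS fit to numerical precision", {
  set.seed(25)
  n <- 40
  copies <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  pcs <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("PC", 1:3)))
  y <- 0.3 * copies + pcs %*% c(1, -1, 0.5) + rnorm(n)
  for (model in c("additive", "dominant", "recessive")) {
    res <- test_haplotype(y, pcs, copies, model)
    x <- switch(model, additive = copies, dominant = as.numeric(copies >= 1),
                recessive = as.numeric(copies == 2))
    fit <- stats::lm(y ~ pcs + x)
    sm <- summary(fit)$coefficients["x", ]
    expect_equal(res$beta, unname(sm["Estimate"]), tolerance = 1e-10)
    expect_equal(res$se, unname(sm["Std. Error"]), tolerance = 1e-10)
    expect_equal(res$p, unname(sm["Pr(>|t|)"]), tolerance = 1e-10)
  }
  expect_null(test_haplotype(y, pcs, rep(2L, n), "additive"))
})

test_that("null haplotype tests produce uniform P values", {
  set.seed(26)
  n <- 500
  copies <- rbinom(n, 2, 0.3)
  pcs <- matrix(rnorm(n * 2), n, 2)
  p <- replicate(1000, {
    test_haplotype(rnorm(n), pcs, copies, "additive")$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("scan results equal per-haplotype OLS and are deterministic and affine-invariant", {
  inp <- small_scan_inputs()
  sc1 <- suppressMessages(hap_scan(inp$sim$panel, inp$pheno, inp$pcs,
                                   model = "recessive"))
  sc2 <- suppressMessages(hap_scan(inp$sim$panel, inp$pheno, inp$pcs,
                                   model = "recessive"))
  expect_identical(tidy(sc1), tidy(sc2))
  expect_equal(sc1$bonferroni_alpha, 0.05 / sc1$n_tests)

  # affine phenotype transform leaves P values untouched
  ph2 <- dplyr::mutate(inp$pheno, value = 3 * value - 100)
  sc3 <- suppressMessages(hap_scan(inp$sim$panel, ph2, inp$pcs,
                                   model = "recessive"))
  expect_equal(tidy(sc3)$p, tidy(sc1)$p, tolerance = 1e-9)

  # cross-check one window against the standalone haplotype test
  a <- tidy(sc1)
  row <- a[which.min(a$p), ]
  wh <- window_haplotypes(inp$sim$panel, row$start_index, row$end_index)
  cp <- wh$copies[[match(row$haplotype, wh$haplotype)]]
  y <- stats::setNames(inp$pheno$value, inp$pheno$sample_id)[inp$sim$panel$sample_ids]
  keep <- !is.na(y)
  ref <- test_haplotype(y[keep], pcs_ms(inp$pcs, inp$sim$panel$sample_ids)[keep, ],
                        cp[keep], "recessive")
  expect_equal(row$beta, ref$beta, tolerance = 1e-10)
  expect_equal(row$p, ref$p, tolerance = 1e-10)
})

test_that("haplotype frequencies per window sum to one before the filter", {
  inp <- small_scan_inputs()
  wh <- window_haplotypes(inp$sim$panel, 101, 150, min_freq = 0)
  expect_equal(sum(wh$freq), 1, tolerance = 1e-12)
})

test_that("the inflation factor matches its defining formula", {
  set.seed(27)
  p <- runif(1000)
  expect_equal(genomic_lambda(p),
               median(qchisq(1 - p, 1)) / 0.4549364, tolerance = 1e-6)
  expect_true(is.na(genomic_lambda(numeric(0))))
})

test_that("conditioning on a constant covariate reproduces the unconditioned scan", {
  inp <- small_scan_inputs()
  sc <- suppressMessages(hap_scan(inp$sim$panel, inp$pheno, inp$pcs,
                                  model = "recessive"))
  const <- tibble::tibble(sample_id = inp$sim$panel$sample_ids, copies = 1L)
  cs <- suppressMessages(conditional_scan(inp$sim$panel, inp$pheno, inp$pcs,
                                          model = "recessive",
                                          condition_status = const))
  expect_equal(tidy(cs)$p, tidy(sc)$p, tolerance = 1e-12)
})

test_that("conditioning on the causal haplotype removes the signal; a random haplotype does not", {
  inp <- small_scan_inputs()
  sim <- inp$sim
  st <- assign_status(sim$panel, sim$qtl$window_start_index,
                      sim$qtl$window_end_index, sim$qtl$hap)
  cs <- suppressMessages(conditional_scan(sim$panel, inp$pheno, inp$pcs,
                                          model = "recessive",
                                          condition_status = st))
  a <- tidy(cs)
  on_qtl <- a$chrom == sim$qtl$chrom
  expect_gt(min(a$p[on_qtl]), cs$bonferroni_alpha)

  # conditioning on an unlinked haplotype leaves the causal window significant
  other_w <- enumerate_windows(sim$panel$markers)
  off <- other_w[other_w$chrom == "2", ][1, ]
  wh <- window_haplotypes(sim$panel, off$start_index, off$end_index)
  rnd <- tibble::tibble(sample_id = sim$panel$sample_ids,
                        copies = wh$copies[[1]])
  cs2 <- suppressMessages(conditional_scan(sim$panel, inp$pheno, inp$pcs,
                                           model = "recessive",
                                           condition_status = rnd))
  a2 <- tidy(cs2)
  top2 <- a2[which.min(a2$p), ]
  expect_lt(top2$p, cs2$bonferroni_alpha)
  expect_true(top2$start_index <= sim$qtl$window_end_index &&
                top2$end_index >= sim$qtl$window_start_index)
})

test_that("a purely recessive effect is detected more strongly under the recessive model", {
  wins <- 0
  for (seed in 1:8) {
    cfg <- sim_config(seed = seed, n_bulls = 300L,
                      n_snps_per_chrom = c(900L, 60L, 60L),
                      records_per_bull = c(6L, 10L))
    sim <- simulate_panel(cfg)
    rec <- simulate_records(cfg, sim$status)
    tr <- aggregate_traits(filter_ejaculates(rec$records))
    y <- tibble::tibble(sample_id = tr$bull_id, value = tr$motility_pct)
    pcs <- grm_pcs(panel_genotypes(sim$panel), k = 10)
    yv <- stats::setNames(y$value, y$sample_id)[sim$panel$sample_ids]
    cp <- sim$status$copies
    keep <- !is.na(yv)
    pr <- test_haplotype(yv[keep], pcs_ms(pcs, sim$panel$sample_ids)[keep, ],
                         cp[keep], "recessive")
    pa <- test_haplotype(yv[keep], pcs_ms(pcs, sim$panel$sample_ids)[keep, ],
                         cp[keep], "additive")
    if (pr$p < pa$p) wins <- wins + 1
  }
  expect_gt(wins, 4)  # majority of seeds
})
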