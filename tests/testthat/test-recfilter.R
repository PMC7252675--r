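mini_groups <- list(hom = paste0("H", 1:3), het = paste0("E", 1:10),
                    non = paste0("N", 1:29))

test_that("pooled group frequencies count called alleles only", {
  samples <- c("H1", "H2", "H3", "E1", "E2", "N1", "N2")
  groups <- list(hom = c("H1", "H2", "H3"), het = c("E1", "E2"),
                 non = c("N1", "N2"))
  rows <- c(
    paste(c("6", 1000, "v1", "A", "G", ".", "PASS", ".", "GT",
            "1/1", "1/1", "0/1", "0|1", "1/0", "0/0", "./."), collapse = "\t"),
    paste(c("6", 2000, "v2", "A", "G", ".", "PASS", ".", "GT",
            "./.", "./.", "./.", "0/1", "0/1", "0/0", "0/0"), collapse = "\t")
  )
  path <- write_mini_vcf(tempfile(fileext = ".vcf"), rows, samples)
  tbl <- read_region_vcf(path)
  gv <- group_frequencies(tbl, groups)
  # three homozygotes 1/1, 1/1, 0/1: 5 of 6 alleles
  expect_equal(gv$freq_hom[1], 5 / 6)
  expect_equal(gv$freq_het[1], 0.5)     # mixed "|" and "/" separators
  expect_equal(gv$freq_non[1], 0)
  expect_equal(gv$called_non[1], 2)     # "./." excluded from the denominator
  # hom group entirely missing: frequency undefined, fails closed
  expect_true(is.na(gv$freq_hom[2]))
  flagged <- is_compatible(gv, compatibility_rule())
  expect_true(flagged$compatible[1])
  expect_false(flagged$compatible[2])
  expect_equal(flagged$reason[2], "missing")
})

test_that("compatibility bounds are inclusive and report the first failing group", {
  gv <- tibble::tibble(
    chrom = "6", pos = 1:4, id = as.character(1:4), ref = "A", alt = "G",
    allele = 1L, class = "SNP", consequence = NA_character_,
    freq_hom = c(0.833, 1.0, 0.8, 0.79),
    freq_het = c(0.5, 0.5, 0.4, 0.5),
    freq_non = c(0.0, 0.06, 0.05, 0.0),
    called_hom = 6, called_het = 20, called_non = 58
  )
  out <- is_compatible(gv, compatibility_rule())
  expect_equal(out$compatible, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$reason, c(NA, "non", NA, "hom"))
})

test_that("region filtering returns the constructed compatible set with correct reasons", {
  path <- tempfile(fileext = ".vcf")
  truth <- simulate_region_vcf(mini_groups, n_variants = 500,
                               n_compatible = 12, seed = 5, path = path,
                               n_missing = 3)
  res <- suppressMessages(
    filter_region(path, region = "6:55000000-65000000", groups = mini_groups)
  )
  expect_equal(res$summary$n_compatible, 12L)
  v <- res$variants
  tt <- truth[match(v$pos, truth$pos), ]
  expect_equal(v$compatible, tt$compatible)
  expect_equal(v$reason[!v$compatible],
               tt$violation[!tt$compatible & tt$violation != "missing"])
  # all-missing variants are skipped with a message
  expect_message(
    filter_region(path, region = "6:55000000-65000000", groups = mini_groups),
    "missing"
  )
  expect_equal(res$summary$n_tested, 497L)
})

test_that("symbolic structural variants go through the same rule and none need be compatible", {
  path <- tempfile(fileext = ".vcf")
  simulate_region_vcf(mini_groups, n_variants = 57, n_compatible = 0,
                      seed = 6, path = path, sv = TRUE)
  res <- filter_region(path, region = "6:55000000-65000000",
                       groups = mini_groups)
  expect_equal(res$summary$n_compatible, 0L)
  expect_true(all(grepl("^SV_", res$variants$class)))
})

test_that("tightening any threshold never increases the compatible count", {
  path <- tempfile(fileext = ".vcf")
  simulate_region_vcf(mini_groups, n_variants = 300, n_compatible = 20,
                      seed = 7, path = path)
  base <- filter_region(path, groups = mini_groups)$summary$n_compatible
  tighter <- list(
    compatibility_rule(hom_min = 0.9),
    compatibility_rule(het_range = c(0.45, 0.55)),
    compatibility_rule(non_max = 0.01)
  )
  for (rule in tighter) {
    expect_lte(filter_region(path, groups = mini_groups,
                             rule = rule)$summary$n_compatible, base)
  }
})

test_that("record order does not affect the grouped frequencies", {
  path <- tempfile(fileext = ".vcf")
  simulate_region_vcf(mini_groups, n_variants = 50, n_compatible = 6,
                      seed = 8, path = path)
  tbl <- read_region_vcf(path)
  fwd <- is_compatible(group_frequencies(tbl, mini_groups))
  rev <- is_compatible(group_frequencies(tbl[rev(seq_len(nrow(tbl))), ],
                                         mini_groups))
  rev <- rev[order(rev$pos), ]
  fwd <- fwd[order(fwd$pos), ]
  expect_equal(fwd$compatible, rev$compatible)
})

test_that("empty regions and unknown contigs are handled explicitly", {
  path <- tempfile(fileext = ".vcf")
  simulate_region_vcf(mini_groups, n_variants = 20, n_compatible = 2,
                      seed = 9, path = path)
  empty <- filter_region(path, region = "6:1-100", groups = mini_groups)
  expect_equal(empty$summary$n_compatible, 0L)
  expect_error(filter_region(path, region = "99:1-100", groups = mini_groups),
               "absent")
})

test_that("a secondary interval is summarised and multi-allelic records split per allele", {
  path <- tempfile(fileext = ".vcf")
  truth <- simulate_region_vcf(mini_groups, n_variants = 200,
                               n_compatible = 10, seed = 10, path = path)
  seg <- c(57e6, 60e6)
  res <- filter_region(path, groups = mini_groups, segment = seg)
  comp_pos <- truth$pos[truth$compatible]
  expect_equal(res$summary$n_in_segment,
               sum(comp_pos >= seg[1] & comp_pos <= seg[2]))

  # multi-allelic: each alternate allele tested separately
  samples <- c("H1", "E1", "N1")
  grp <- list(hom = "H1", het = "E1", non = "N1")
  row <- paste(c("6", 1234, "mv", "A", "G,T", ".", "PASS", ".", "GT",
                 "1/1", "1/2", "0/0"), collapse = "\t")
  p2 <- write_mini_vcf(tempfile(fileext = ".vcf"), row, samples)
  gv <- group_frequencies(read_region_vcf(p2), grp)
  expect_equal(nrow(gv), 2)
  expect_equal(gv$freq_hom, c(1, 0))
  expect_equal(gv$freq_het, c(0.5, 0.5))
})

test_that("status groups validate disjointness and a non-empty homozygous set", {
  st <- tibble::tibble(sample_id = c("a", "b", "c"), copies = c(2L, 1L, 0L))
  g <- status_groups(st)
  expect_equal(g$hom, "a")
  expect_error(status_groups(tibble::tibble(sample_id = "a", copies = 1L)),
               "homozygous")
  expect_error(status_groups(list(hom = "a", het = "a", non = "b")),
               "disjoint")
})
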