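test_that("donor scoring is maximal at the matrix consensus and demands the GT core", {
  pwm <- donor_pwm()
  bases <- c("A", "C", "G", "T")
  cons <- paste(bases[apply(pwm, 1, which.max)], collapse = "")
  expect_equal(substr(cons, 4, 5), "GT")
  s_cons <- donor_pwm_score(cons, pwm)
  set.seed(31)
  for (i in 1:50) {
    rnd <- paste0(paste(sample(bases, 3, TRUE), collapse = ""), "GT",
                  paste(sample(bases, 4, TRUE), collapse = ""))
    expect_lte(donor_pwm_score(rnd, pwm), s_cons)
  }
  expect_error(donor_pwm_score("CAGGAAAGT"), "GT")
  expect_error(donor_pwm_score("CAGGT"), "9-mer")

  # hand-summed log-odds oracle for a fixed 9-mer
  x <- "AAGGTCAGT"
  manual <- log2(pwm["-3", "A"] / 0.25) + log2(pwm["-2", "A"] / 0.25) +
    log2(pwm["-1", "G"] / 0.25) + log2(pwm["1", "G"] / 0.25) +
    log2(pwm["2", "T"] / 0.25) + log2(pwm["3", "C"] / 0.25) +
    log2(pwm["4", "A"] / 0.25) + log2(pwm["5", "G"] / 0.25) +
    log2(pwm["6", "T"] / 0.25)
  expect_equal(donor_pwm_score(x, pwm), manual, tolerance = 1e-12)
})

test_that("the constructed cryptic-donor gene yields a 9-bp in-frame truncation deleting residues 414-416", {
  sg <- simulate_splice_gene(seed = 4)
  calls <- find_donor_gain(sg$variant, sg$gene, sg$seq, sg$seq_start)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$g_pos, sg$expected$g_pos)
  expect_equal(calls$truncation, 9L)
  expect_equal(calls$frame, "in-frame")
  expect_equal(c(calls$res_start, calls$res_end), c(414L, 416L))
  expect_true(calls$score_alt > calls$score_ref)
  # the deleted interval length equals truncation / 3
  expect_equal(calls$res_end - calls$res_start + 1L, calls$truncation / 3L)
})

test_that("protein deletion agrees with an independent translate-and-diff oracle", {
  sg <- simulate_splice_gene(seed = 4)
  calls <- find_donor_gain(sg$variant, sg$gene, sg$seq, sg$seq_start)
  # oracle: translate full and truncated CDS with seqinr and diff
  alt_seq <- sg$seq
  substr(alt_seq, sg$variant$pos, sg$variant$pos) <- sg$variant$alt
  ex <- sg$gene$exons
  cds_full <- paste0(substr(alt_seq, ex$start[1], ex$end[1]),
                     substr(alt_seq, ex$start[2], ex$end[2]),
                     substr(alt_seq, ex$start[3], ex$end[3]))
  cds_trunc <- paste0(substr(alt_seq, ex$start[1], ex$end[1]),
                      substr(alt_seq, ex$start[2], ex$end[2] - 9),
                      substr(alt_seq, ex$start[3], ex$end[3]))
  pf <- paste(seqinr::translate(seqinr::s2c(cds_full)), collapse = "")
  pt <- paste(seqinr::translate(seqinr::s2c(cds_trunc)), collapse = "")
  expect_equal(nchar(pf) - nchar(pt), 3)
  i <- 1
  while (substr(pf, i, i) == substr(pt, i, i)) i <- i + 1
  expect_equal(i, calls$res_start)
  expect_equal(substr(pf, 1, i - 1), substr(pt, 1, i - 1))
  expect_equal(substr(pf, calls$res_end + 1, nchar(pf)),
               substr(pt, calls$res_start, nchar(pt)))
})

test_that("frameshift truncations are flagged and GT-destroying alleles give no call", {
  # shrink the middle exon by one base: the same cryptic donor now removes 10 bp
  sg <- simulate_splice_gene(seed = 4)
  ex <- sg$gene$exons
  gene10 <- gene_model(tibble::tibble(start = ex$start,
                                      end = c(ex$end[1], ex$end[2] + 1L, ex$end[3])),
                       sg$gene$cds_start, sg$gene$cds_end)
  calls10 <- find_donor_gain(sg$variant, gene10, sg$seq, sg$seq_start)
  drow <- calls10[calls10$g_pos == sg$expected$g_pos, ]
  expect_equal(drow$truncation, 10L)
  expect_equal(drow$frame, "frameshift")
  expect_true(is.na(drow$res_start))

  # a variant destroying the candidate GT cannot be a gain
  kill <- list(pos = sg$expected$g_pos, ref = "G", alt = "A")
  expect_equal(nrow(find_donor_gain(kill, sg$gene, sg$seq, sg$seq_start)), 0)

  # non-exonic variants warn and return nothing
  intronic <- list(pos = sg$gene$exons$end[2] + 50L, ref = "A", alt = "T")
  expect_warning(res <- find_donor_gain(intronic, sg$gene, sg$seq, sg$seq_start),
                 "exon")
  expect_equal(nrow(res), 0)
})

test_that("donor-gain calls are invariant to extra sequence context and work on the minus strand", {
  sg <- simulate_splice_gene(seed = 4)
  pad <- strrep("A", 100)
  wide <- paste0(pad, sg$seq, pad)
  calls_wide <- find_donor_gain(sg$variant, sg$gene, wide, sg$seq_start - 100L)
  calls <- find_donor_gain(sg$variant, sg$gene, sg$seq, sg$seq_start)
  expect_equal(calls_wide, calls)

  # mirror the whole construct onto the minus strand
  L <- nchar(sg$seq)
  flip <- function(p) (sg$seq_start + L - 1) + sg$seq_start - p
  seq_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sg$seq)))
  gene_rc <- gene_model(tibble::tibble(start = rev(flip(sg$gene$exons$end)),
                                       end = rev(flip(sg$gene$exons$start))),
                        cds_start = flip(sg$gene$cds_end),
                        cds_end = flip(sg$gene$cds_start), strand = "-")
  var_rc <- list(pos = flip(sg$variant$pos), ref = "G", alt = "A")
  calls_rc <- find_donor_gain(var_rc, gene_rc, seq_rc, sg$seq_start)
  expect_equal(nrow(calls_rc), 1)
  expect_equal(calls_rc$truncation, 9L)
  expect_equal(calls_rc$g_pos, flip(sg$expected$g_pos))
  expect_equal(c(calls_rc$res_start, calls_rc$res_end), c(414L, 416L))
})

test_that("junction tallies are exact and respect the overhang rule", {
  sg <- simulate_splice_gene(seed = 4)
  sam <- tempfile(fileext = ".sam")
  simulate_junction_reads(5, 24, sg$junction, seed = 9, path = sam)
  t1 <- tally_junctions(sam, sg$junction)
  expect_equal(c(t1$wt_reads, t1$mt_reads, t1$unassigned), c(5L, 24L, 0L))

  sam0 <- tempfile(fileext = ".sam")
  simulate_junction_reads(0, 0, sg$junction, seed = 9, path = sam0)
  t0 <- tally_junctions(sam0, sg$junction)
  expect_equal(c(t0$wt_reads, t0$mt_reads, t0$unassigned), c(0L, 0L, 0L))

  # a read with a 5-base overhang is not counted at min_overhang = 6, but it
  # still overlaps the junction, so it lands in `unassigned`
  sam5 <- tempfile(fileext = ".sam")
  simulate_junction_reads(2, 3, sg$junction, seed = 9, path = sam5,
                          extra_reads = tibble::tibble(junction = "wt",
                                                       left_len = 5,
                                                       right_len = 95))
  t5 <- tally_junctions(sam5, sg$junction, min_overhang = 6)
  expect_equal(c(t5$wt_reads, t5$mt_reads, t5$unassigned), c(2L, 3L, 1L))
  # conservation: wt + mt + unassigned = reads overlapping the junction
  expect_equal(t5$wt_reads + t5$mt_reads + t5$unassigned, 6L)
  t5b <- tally_junctions(sam5, sg$junction, min_overhang = 5)
  expect_equal(t5b$wt_reads, 3L)
})

test_that("junction pairs validate their geometry", {
  expect_error(splice_junction_pair(100, 101), "acceptor_start")
  jp <- splice_junction_pair(100, 300, truncation = 9)
  expect_equal(unname(jp$mt["donor_end"]), 91)
})
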