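#' Donor-site position weight matrix
#'
#' Base frequencies at positions -3..+6 of vertebrate U2 splice-donor sites,
#' shipped with the package (see
#' `inst/extdata/donor_site_frequencies.tsv` for provenance). Scores are
#' log2 odds against a uniform background, so the matrix consensus
#' `CAGGTAAGT` attains the maximal score.
#'
#' @return A 9 x 4 numeric matrix (rows: positions -3..-1, +1..+6; columns
#'   A, C, G, T).
#' @export
donor_pwm <- function() {
  path <- system.file("extdata", "donor_site_frequencies.tsv",
                      package = "recessivescan")
  m <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  out <- as.matrix(m[, c("A", "C", "G", "T")])
  rownames(out) <- m$position
  out
}

#' Score a candidate splice-donor 9-mer
#'
#' Sum over positions -3..+6 of `log2(f / 0.25)`, where `f` is the packaged
#' donor-site base frequency. The candidate must carry the canonical GT at
#' positions +1/+2 (characters 4 and 5 of the 9-mer).
#'
#' @param ninemer A 9-character DNA string (positions -3..+6 of the
#'   candidate donor).
#' @param pwm Matrix from [donor_pwm()].
#' @return Score in bits.
#' @export
donor_pwm_score <- function(ninemer, pwm = donor_pwm()) {
  ninemer <- toupper(ninemer)
  if (nchar(ninemer) != 9) abort("donor context must be a 9-mer (positions -3..+6)")
  if (substr(ninemer, 4, 5) != "GT") {
    abort("candidate donor lacks the canonical GT at positions +1/+2")
  }
  bases <- strsplit(ninemer, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) abort("sequence contains non-ACGT characters")
  sum(log2(pwm[cbind(seq_len(9), match(bases, c("A", "C", "G", "T")))] / 0.25))
}

#' Construct a gene model
#'
#' @param exons Tibble `start`, `end` (1-based inclusive genomic
#'   coordinates), ordered 5' to 3' along the genome, non-overlapping.
#' @param cds_start,cds_end Genomic bounds of the coding sequence.
#' @param strand `"+"` or `"-"`. Minus-strand genes are reverse-complemented
#'   at ingest by [find_donor_gain()].
#' @param gene_id Identifier.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(exons, cds_start, cds_end, strand = "+",
                       gene_id = "gene1") {
  exons <- dplyr::arrange(as_tibble(exons), .data$start)
  stopifnot(all(exons$end >= exons$start))
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort("exons must be non-overlapping and ordered")
  }
  structure(list(exons = exons, cds_start = cds_start, cds_end = cds_end,
                 strand = strand, gene_id = gene_id), class = "gene_model")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Detect exonic splice-donor gains created by a variant
#'
#' Enumerates every exonic GT dinucleotide whose -3..+6 context contains the
#' variant position, scores the context under the reference and alternate
#' alleles with the packaged donor weight matrix, and reports candidate
#' donors whose alternate score reaches `threshold` and exceeds the
#' reference score (i.e. the variant strengthens the site). Use of a
#' reported donor truncates the exon at the base before the GT; the frame
#' effect follows from the truncation length modulo 3, and for in-frame
#' truncations the deleted protein residues are mapped with
#' [protein_deletion()]. Minus-strand genes are reverse-complemented at
#' ingest and positions reported on the genome.
#'
#' @param variant List/row with `pos`, `ref`, `alt` (single-nucleotide).
#' @param gene A [gene_model()].
#' @param seq Reference sequence covering the exon and at least 50 bp of
#'   context, as a character string.
#' @param seq_start Genomic position of the first base of `seq`.
#' @param threshold Minimum alternate-allele score in bits.
#' @param pwm Donor weight matrix.
#' @return A tibble with one row per gained donor: `g_pos` (genomic position
#'   of the G), `score_ref`, `score_alt`, `truncation`, `frame`
#'   (`"in-frame"`/`"frameshift"`), `res_start`, `res_end` (NA unless
#'   in-frame). Empty (with a warning) when the variant is not exonic.
#' @export
find_donor_gain <- function(variant, gene, seq, seq_start = 1L, threshold = 0,
                            pwm = donor_pwm()) {
  seq <- toupper(seq)
  if (nchar(variant$ref) != 1 || nchar(variant$alt) != 1) {
    abort("donor-gain analysis supports single-nucleotide variants")
  }
  if (gene$strand == "-") {
    flip <- seq_start + nchar(seq) - 1L + seq_start  # pos -> flip - pos
    exons <- tibble(start = flip - gene$exons$end, end = flip - gene$exons$start)
    gene_f <- gene_model(exons, flip - gene$cds_end, flip - gene$cds_start,
                         strand = "+", gene_id = gene$gene_id)
    var_f <- list(pos = flip - variant$pos,
                  ref = revcomp_chr(variant$ref), alt = revcomp_chr(variant$alt))
    res <- find_donor_gain(var_f, gene_f, revcomp_chr(seq), seq_start,
                           threshold = threshold, pwm = pwm)
    res$g_pos <- flip - res$g_pos
    return(res)
  }
  vpos <- variant$pos
  ex <- which(gene$exons$start <= vpos & gene$exons$end >= vpos)
  if (length(ex) == 0) {
    warn("variant does not fall inside an exon; no donor-gain candidates")
    return(empty_donor_calls())
  }
  at <- function(pos) pos - seq_start + 1L
  if (substr(seq, at(vpos), at(vpos)) != toupper(variant$ref)) {
    abort("reference allele does not match the supplied sequence")
  }
  alt_seq <- seq
  substr(alt_seq, at(vpos), at(vpos)) <- toupper(variant$alt)
  exon_start <- gene$exons$start[ex]
  exon_end <- gene$exons$end[ex]

  calls <- list()
  for (g in seq(max(exon_start, seq_start + 3L),
                min(exon_end, seq_start + nchar(seq) - 6L))) {
    if (vpos < g - 3L || vpos > g + 5L) next     # variant outside the context
    ctx_alt <- substr(alt_seq, at(g - 3L), at(g + 5L))
    if (substr(ctx_alt, 4, 5) != "GT") next      # gain requires GT in the alt
    score_alt <- donor_pwm_score(ctx_alt, pwm)
    ctx_ref <- substr(seq, at(g - 3L), at(g + 5L))
    score_ref <- if (substr(ctx_ref, 4, 5) == "GT") {
      donor_pwm_score(ctx_ref, pwm)
    } else -Inf
    if (score_alt < threshold || score_alt <= score_ref) next
    trunc <- exon_end - g + 1L
    in_frame <- trunc %% 3L == 0L
    row <- tibble(g_pos = g, exon = ex, score_ref = score_ref,
                  score_alt = score_alt, truncation = trunc,
                  frame = if (in_frame) "in-frame" else "frameshift",
                  res_start = NA_integer_, res_end = NA_integer_)
    if (in_frame) {
      del <- protein_deletion(row, gene, alt_seq, seq_start)
      row$res_start <- del$res_start
      row$res_end <- del$res_end
    }
    calls[[length(calls) + 1L]] <- row
  }
  if (length(calls) == 0) return(empty_donor_calls())
  dplyr::bind_rows(calls)
}

empty_donor_calls <- function() {
  tibble(g_pos = integer(0), exon = integer(0), score_ref = numeric(0),
         score_alt = numeric(0), truncation = integer(0), frame = character(0),
         res_start = integer(0), res_end = integer(0))
}

# concatenated CDS of a plus-strand gene model from a sequence window,
# optionally truncating the last `truncation` bases of exon `exon`'s coding
# part (cryptic-donor usage)
build_cds <- function(gene, seq, seq_start, exon = NULL, truncation = 0L) {
  pieces <- character(nrow(gene$exons))
  for (i in seq_len(nrow(gene$exons))) {
    s <- max(gene$exons$start[i], gene$cds_start)
    e <- min(gene$exons$end[i], gene$cds_end)
    if (s > e) { pieces[i] <- ""; next }
    if (!is.null(exon) && i == exon) e <- e - truncation
    if (s > e) { pieces[i] <- ""; next }
    pieces[i] <- substr(seq, s - seq_start + 1L, e - seq_start + 1L)
  }
  paste(pieces, collapse = "")
}

#' Map an in-frame exon truncation to deleted protein residues
#'
#' Translates the full and the truncated coding sequence and locates the
#' deleted residues after the longest common prefix, returning a 1-based
#' inclusive residue interval whose length equals `truncation / 3`.
#'
#' @param call One row from [find_donor_gain()] (needs `exon`,
#'   `truncation`).
#' @param gene A plus-strand [gene_model()].
#' @param seq Sequence window covering the gene's exons.
#' @param seq_start Genomic position of the first base of `seq`.
#' @return A one-row tibble `res_start`, `res_end`.
#' @export
protein_deletion <- function(call, gene, seq, seq_start = 1L) {
  if (call$truncation %% 3L != 0L) {
    abort("protein deletion is only defined for in-frame truncations")
  }
  full <- build_cds(gene, seq, seq_start)
  trunc <- build_cds(gene, seq, seq_start, exon = call$exon,
                     truncation = call$truncation)
  pf <- translate_cds(full)
  pt <- translate_cds(trunc)
  d <- nchar(pf) - nchar(pt)
  a <- common_prefix_len(pf, pt)
  a <- min(a, nchar(pt))  # deletion cannot start beyond the shorter protein
  tibble(res_start = a + 1L, res_end = a + d)
}

translate_cds <- function(cds) {
  usable <- 3L * (nchar(cds) %/% 3L)
  as.character(Biostrings::translate(Biostrings::DNAString(substr(cds, 1, usable)),
                                     if.fuzzy.codon = "X"))
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(a, "")[[1]][seq_len(n)]
  bv <- strsplit(b, "")[[1]][seq_len(n)]
  mism <- which(av != bv)
  if (length(mism) == 0) n else mism[1] - 1L
}

#' Wild-type and mutant splice-junction pair
#'
#' @param donor_end Genomic position of the last exonic base of the
#'   wild-type (natural) donor exon.
#' @param acceptor_start Genomic position of the first base of the next
#'   exon.
#' @param truncation Bases removed from the exon 3' end by the cryptic
#'   donor.
#' @return A list of class `junction_pair` with `wt` and `mt` junctions.
#' @export
splice_junction_pair <- function(donor_end, acceptor_start, truncation = 9L) {
  stopifnot(truncation >= 1, acceptor_start > donor_end + 1)
  structure(list(
    wt = c(donor_end = donor_end, acceptor_start = acceptor_start),
    mt = c(donor_end = donor_end - truncation, acceptor_start = acceptor_start),
    truncation = truncation
  ), class = "junction_pair")
}

#' Tally junction-spanning reads supporting wild-type vs mutant splicing
#'
#' A read supports a junction when two consecutive aligned reference blocks
#' (CIGAR split on N operations) end exactly at the junction's donor and
#' start exactly at its acceptor, with at least `min_overhang` aligned bases
#' on each side. Reads whose alignment spans the wild-type junction but
#' match neither junction are counted as unassigned, so
#' `wt + mt + unassigned` equals the number of junction-overlapping reads.
#'
#' @param path SAM (or BAM) file of spliced alignments.
#' @param pair A [splice_junction_pair()].
#' @param min_overhang Minimum aligned bases on each side of the junction.
#' @return A tibble `wt_reads`, `mt_reads`, `unassigned`.
#' @export
tally_junctions <- function(path, pair, min_overhang = 6L) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  gal <- GenomicAlignments::readGAlignments(bam)
  if (length(gal) == 0) {
    return(tibble(wt_reads = 0L, mt_reads = 0L, unassigned = 0L))
  }
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
    GenomicAlignments::cigar(gal), pos = GenomicAlignments::start(gal))
  supports <- function(br, junc, oh) {
    if (length(br) < 2) return(FALSE)
    e <- IRanges::end(br); s <- IRanges::start(br); w <- IRanges::width(br)
    idx <- seq_len(length(br) - 1L)
    any(e[idx] == junc[["donor_end"]] & s[idx + 1L] == junc[["acceptor_start"]] &
          w[idx] >= oh & w[idx + 1L] >= oh)
  }
  wt <- vapply(seq_along(blocks), function(i) supports(blocks[[i]], pair$wt, min_overhang), logical(1))
  mt <- vapply(seq_along(blocks), function(i) supports(blocks[[i]], pair$mt, min_overhang), logical(1))
  span_lo <- vapply(seq_along(blocks), function(i) min(IRanges::start(blocks[[i]])), numeric(1))
  span_hi <- vapply(seq_along(blocks), function(i) max(IRanges::end(blocks[[i]])), numeric(1))
  overlapping <- span_lo <= pair$wt[["donor_end"]] &
    span_hi >= pair$wt[["acceptor_start"]]
  tibble(wt_reads = sum(wt), mt_reads = sum(mt),
         unassigned = sum(overlapping & !wt & !mt))
}
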