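#' Haplotype-status sample groups
#'
#' @param status Tibble `sample_id`, `copies`, or a list already holding
#'   `hom`, `het`, `non` character vectors.
#' @return A list `hom`, `het`, `non` of disjoint sample-id vectors; errors
#'   if the homozygous group is empty.
#' @export
status_groups <- function(status) {
  if (is.list(status) && !is.data.frame(status) &&
      all(c("hom", "het", "non") %in% names(status))) {
    groups <- status[c("hom", "het", "non")]
  } else {
    groups <- list(hom = status$sample_id[status$copies == 2L],
                   het = status$sample_id[status$copies == 1L],
                   non = status$sample_id[status$copies == 0L])
  }
  if (anyDuplicated(unlist(groups))) abort("status groups must be disjoint")
  if (length(groups$hom) == 0) {
    abort("recessive-compatibility filtering requires at least one homozygous carrier")
  }
  groups
}

#' Recessive-compatibility thresholds
#'
#' A variant is compatible with recessive inheritance of a haplotype when its
#' alternate-allele frequency is at least `hom_min` among homozygous
#' carriers, inside `het_range` among heterozygous carriers, and at most
#' `non_max` among non-carriers. All bounds are inclusive. Frequencies are
#' pooled over called alleles within each group, which tolerates occasional
#' genotyping errors and mis-assigned haplotype statuses better than exact
#' genotype matching.
#'
#' @param hom_min Minimum alternate-allele frequency in homozygotes.
#' @param het_range Inclusive frequency interval for heterozygotes.
#' @param non_max Maximum frequency in non-carriers.
#' @return A list of class `compatibility_rule`.
#' @export
compatibility_rule <- function(hom_min = 0.8, het_range = c(0.4, 0.6),
                               non_max = 0.05) {
  stopifnot(hom_min >= 0, hom_min <= 1, non_max >= 0, non_max <= 1,
            length(het_range) == 2, het_range[1] <= het_range[2],
            all(het_range >= 0), all(het_range <= 1))
  structure(list(hom_min = hom_min, het_range = het_range, non_max = non_max),
            class = "compatibility_rule")
}

# alt-allele frequency of allele `allele_idx` over called alleles in `gt`
# genotype strings; accepts "|" and "/" separators and any ploidy
alt_freq <- function(gt, allele_idx = 1L) {
  alleles <- unlist(strsplit(gt[!is.na(gt)], "[/|]"))
  alleles <- alleles[alleles != "."]
  if (length(alleles) == 0) return(c(freq = NA_real_, called = 0))
  c(freq = mean(alleles == as.character(allele_idx)), called = length(alleles))
}

#' Per-group alternate-allele frequencies for VCF records
#'
#' Computes, for every variant and every alternate allele, the pooled
#' alternate-allele frequency within the homozygous, heterozygous and
#' non-carrier groups. Missing genotypes are excluded from the denominators;
#' a group with no called alleles gets an `NA` frequency (such variants fail
#' the compatibility rule closed).
#'
#' @param variants Tibble as returned by [read_region_vcf()] (one row per
#'   variant, `gt` list-column of named genotype vectors).
#' @param groups A [status_groups()] list.
#' @return The input tibble expanded to one row per alternate allele, with
#'   columns `allele`, `freq_hom`, `freq_het`, `freq_non`, `called_hom`,
#'   `called_het`, `called_non`.
#' @export
group_frequencies <- function(variants, groups) {
  groups <- status_groups(groups)
  rows <- purrr::pmap(variants, function(...) {
    v <- list(...)
    alts <- strsplit(v$alt, ",")[[1]]
    gt <- v$gt
    purrr::map(seq_along(alts), function(k) {
      fh <- alt_freq(gt[groups$hom], k)
      fe <- alt_freq(gt[groups$het], k)
      fn <- alt_freq(gt[groups$non], k)
      tibble(chrom = v$chrom, pos = v$pos, id = v$id, ref = v$ref,
             alt = alts[k], allele = k, class = v$class,
             consequence = v$consequence,
             freq_hom = fh[["freq"]], freq_het = fe[["freq"]],
             freq_non = fn[["freq"]], called_hom = fh[["called"]],
             called_het = fe[["called"]], called_non = fn[["called"]])
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Test grouped variants against the compatibility rule
#'
#' @param gv Tibble from [group_frequencies()].
#' @param rule A [compatibility_rule()].
#' @return `gv` with logical `compatible` and character `reason` (`NA` when
#'   compatible; otherwise the first failing group, or `"missing"` when a
#'   group has no called alleles).
#' @export
is_compatible <- function(gv, rule = compatibility_rule()) {
  reason <- rep(NA_character_, nrow(gv))
  miss <- is.na(gv$freq_hom) | is.na(gv$freq_het) | is.na(gv$freq_non)
  reason[miss] <- "missing"
  bad_hom <- !miss & gv$freq_hom < rule$hom_min
  reason[bad_hom] <- "hom"
  bad_het <- !miss & is.na(reason) &
    (gv$freq_het < rule$het_range[1] | gv$freq_het > rule$het_range[2])
  reason[bad_het] <- "het"
  bad_non <- !miss & is.na(reason) & gv$freq_non > rule$non_max
  reason[bad_non] <- "non"
  dplyr::mutate(gv, compatible = is.na(reason), reason = reason)
}

#' Read a VCF region into a tidy variant table
#'
#' Thin wrapper around `vcfR` returning one row per variant with a
#' list-column of genotype strings named by sample. Variant class is derived
#' from REF/ALT (`SNP`, `indel`, or the symbolic SV type), and a consequence
#' string is extracted from an `ANN`/`CSQ`/`Consequence` INFO key when
#' present (never computed).
#'
#' @param path VCF file (plain or bgzipped).
#' @param region `"chrom:start-end"` string, or `NULL` for all records. The
#'   chromosome must be declared in the VCF header contigs.
#' @return A tibble `chrom`, `pos`, `id`, `ref`, `alt`, `class`,
#'   `consequence`, `info`, `gt`.
#' @export
read_region_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- if (ncol(v@gt) > 1) vcfR::extract.gt(v, element = "GT") else NULL
  tbl <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    id = fix$ID, ref = fix$REF, alt = fix$ALT,
    info = fix$INFO %||% NA_character_
  )
  tbl$class <- variant_class(tbl$ref, tbl$alt, tbl$info)
  tbl$consequence <- consequence_from_info(tbl$info)
  tbl$gt <- if (is.null(gt)) {
    rep(list(character(0)), nrow(tbl))
  } else {
    lapply(seq_len(nrow(tbl)), function(i) setNames(gt[i, ], colnames(gt)))
  }
  if (!is.null(region)) {
    reg <- parse_region(region)
    contigs <- vcf_header_contigs(v)
    if (length(contigs) > 0 && !(reg$chrom %in% contigs)) {
      abort(sprintf("region chromosome '%s' absent from the VCF header contigs", reg$chrom))
    }
    tbl <- dplyr::filter(tbl, .data$chrom == reg$chrom,
                         .data$pos >= reg$start, .data$pos <= reg$end)
  }
  tbl
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) abort("region must have the form chrom:start-end")
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

vcf_header_contigs <- function(v) {
  meta <- v@meta
  ctg <- meta[grepl("^##contig=", meta)]
  sub(".*ID=([^,>]+).*", "\\1", ctg)
}

variant_class <- function(ref, alt, info) {
  vapply(seq_along(ref), function(i) {
    a1 <- strsplit(alt[i], ",")[[1]][1]
    if (grepl("^<", a1)) {
      sv <- sub(".*SVTYPE=([^;]+).*", "\\1", info[i])
      if (identical(sv, info[i]) || is.na(info[i])) sv <- gsub("[<>]", "", a1)
      return(paste0("SV_", sv))
    }
    if (nchar(ref[i]) == 1 && all(nchar(strsplit(alt[i], ",")[[1]]) == 1)) {
      "SNP"
    } else "indel"
  }, character(1))
}

consequence_from_info <- function(info) {
  vapply(info, function(x) {
    if (is.na(x)) return(NA_character_)
    m <- regmatches(x, regexec("(?:^|;)(?:ANN|CSQ|Consequence)=([^;]+)", x))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Filter a VCF region for variants compatible with recessive inheritance
#'
#' Reads the region, computes per-group alternate-allele frequencies, applies
#' the compatibility rule, and summarises counts by variant class and
#' consequence, plus counts within an optional secondary interval (e.g. a
#' shared-autozygosity segment). The filter is per-variant, so the output is
#' invariant to record order.
#'
#' @inheritParams read_region_vcf
#' @param groups A [status_groups()] input.
#' @param rule A [compatibility_rule()].
#' @param segment Optional `c(start, end)` secondary interval in bp.
#' @return A list with `variants` (grouped, flagged tibble) and `summary`
#'   (totals, counts by class/consequence/failure reason, and `n_in_segment`
#'   when a segment is supplied).
#' @export
filter_region <- function(path, region = NULL, groups, rule = compatibility_rule(),
                          segment = NULL) {
  tbl <- read_region_vcf(path, region)
  groups <- status_groups(groups)
  if (nrow(tbl) == 0) {
    return(list(variants = tibble(), summary = list(
      n_variants = 0L, n_compatible = 0L,
      by_class = integer(0), by_consequence = integer(0),
      by_reason = integer(0),
      n_in_segment = if (is.null(segment)) NULL else 0L
    )))
  }
  all_missing <- vapply(tbl$gt, function(g) {
    length(g) == 0 || all(is.na(g) | g %in% c(".", "./.", ".|."))
  }, logical(1))
  if (any(all_missing)) {
    inform(sprintf("%d variant(s) with all genotypes missing skipped", sum(all_missing)))
  }
  gv <- group_frequencies(tbl[!all_missing, , drop = FALSE], groups)
  gv <- is_compatible(gv, rule)
  comp <- dplyr::filter(gv, .data$compatible)
  summary <- list(
    n_variants = nrow(tbl),
    n_tested = nrow(gv),
    n_compatible = nrow(comp),
    by_class = table(comp$class),
    by_consequence = table(comp$consequence, useNA = "no"),
    by_reason = table(gv$reason[!gv$compatible])
  )
  if (!is.null(segment)) {
    summary$n_in_segment <- sum(comp$pos >= segment[1] & comp$pos <= segment[2])
  }
  list(variants = gv, summary = summary)
}
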