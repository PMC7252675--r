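#' Write a haplotype panel as a phased VCF
#'
#' Plain-text VCF 4.2 with phased `GT` (`"0|1"` style), 1-based positions,
#' and contig header lines.
#'
#' @param panel A `haplotype_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  map <- panel$markers
  contigs <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos_bp) + 1000L, .groups = "drop")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contigs$chrom, contigs$len),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  ref <- map$ref %||% rep("A", nrow(map))
  alt <- map$alt %||% rep("C", nrow(map))
  body <- vapply(seq_len(nrow(map)), function(j) {
    gt <- paste0(panel$H1[, j], "|", panel$H2[, j])
    paste(c(map$chrom[j], map$pos_bp[j], map$snp_id[j], ref[j], alt[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Requires fully phased, biallelic GT fields (`"a|b"`).
#'
#' @param path VCF file.
#' @return A `haplotype_panel`.
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(is.na(gt)) || !all(grepl("^[01]\\|[01]$", gt))) {
    abort("panel VCF must contain fully phased biallelic genotypes (GT like 0|1)")
  }
  H1 <- t(matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt)))
  H2 <- t(matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt)))
  markers <- tibble(snp_id = fix$ID, chrom = fix$CHROM,
                    pos_bp = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT)
  new_haplotype_panel(markers, H1, H2, colnames(gt))
}

#' Write a complete synthetic dataset to a directory
#'
#' Materializes one simulated study: phased panel VCF plus marker map,
#' ejaculate and insemination CSVs, pedigree CSV, candidate-region VCF,
#' junction SAM, and a JSON manifest of the ground truth (QTL window and
#' haplotype, per-bull status, injected QC violations, variance components).
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
write_sim_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_panel(cfg)
  rec <- simulate_records(cfg, sim$status)
  truth <- setNames(rnorm(cfg$n_bulls), sim$status$sample_id)
  ins <- simulate_inseminations(cfg, truth)
  vcf_truth <- simulate_region_vcf(sim$status, n_variants = 500,
                                   n_compatible = 12, seed = cfg$seed,
                                   path = file.path(dir, "region.vcf"))
  jp <- splice_junction_pair(58374000L, 58376000L, truncation = 9L)
  simulate_junction_reads(5, 24, jp, seed = cfg$seed,
                          path = file.path(dir, "junctions.sam"))

  write_panel_vcf(sim$panel, file.path(dir, "panel.vcf"))
  utils::write.csv(sim$panel$markers, file.path(dir, "markers.csv"), row.names = FALSE)
  utils::write.csv(rec$records, file.path(dir, "ejaculates.csv"), row.names = FALSE)
  utils::write.csv(rec$pedigree, file.path(dir, "pedigree.csv"), row.names = FALSE)
  utils::write.csv(ins, file.path(dir, "inseminations.csv"), row.names = FALSE)
  manifest <- list(
    seed = cfg$seed, qtl = sim$qtl,
    status = as.list(setNames(sim$status$copies, sim$status$sample_id)),
    fertility_truth = as.list(truth),
    expected_removals = as.list(rec$manifest$expected_removals),
    h2 = rec$manifest$h2, repeatability = rec$manifest$repeatability,
    sigma_g2 = as.list(rec$manifest$sigma_g2),
    region_vcf_compatible = sum(vcf_truth$compatible)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, records = rec, inseminations = ins,
                 region_truth = vcf_truth, dir = dir))
}
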