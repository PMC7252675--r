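#' Assign per-sample copy number of a named haplotype
#'
#' A phased chromosome contributes one copy only when its allele string over
#' the window matches the target exactly; a single mismatched allele
#' contributes nothing.
#'
#' @param panel A `haplotype_panel`.
#' @param start_index,end_index Window bounds (row indices into the marker
#'   map).
#' @param haplotype Allele string of the target haplotype ("0"/"1"
#'   characters, one per marker in the window).
#' @return A tibble `sample_id`, `copies` (0/1/2).
#' @export
assign_status <- function(panel, start_index, end_index, haplotype) {
  cols <- start_index:end_index
  if (nchar(haplotype) != length(cols)) {
    abort("haplotype string length must equal the window size")
  }
  s1 <- hap_strings(panel$H1, cols)
  s2 <- hap_strings(panel$H2, cols)
  tibble(sample_id = panel$sample_ids,
         copies = as.integer((s1 == haplotype) + (s2 == haplotype)))
}

#' Maximal shared-autozygosity segment among homozygous carriers
#'
#' Starting from the seed window, extends marker by marker to the left and
#' right for as long as every carrier is homozygous and all carriers share
#' the same homozygous genotype. The reported boundaries are the positions of
#' the outermost conforming markers, so markers immediately beyond both
#' boundaries violate the conformity condition (maximality). Missing
#' genotypes are treated as conforming (`missing = "skip"`, the default,
#' appropriate for imputed data) or as terminating the extension
#' (`missing = "break"`).
#'
#' @param panel A `haplotype_panel`.
#' @param carriers Character vector of homozygous-carrier sample ids, or a
#'   status tibble from [assign_status()] (carriers are the `copies == 2`
#'   rows). At least two carriers are required.
#' @param start_index,end_index Seed window bounds (map row indices).
#' @param missing How to treat missing genotypes during extension.
#' @param on_het What to do when a carrier is heterozygous inside the seed
#'   window: `"error"` (default) or `"warn"` (returns the zero-extension
#'   segment).
#' @return A one-row tibble `chrom`, `start_bp`, `end_bp`, `start_index`,
#'   `end_index`, `n_markers`, `n_carriers`, `length_bp`.
#' @export
shared_segment <- function(panel, carriers, start_index, end_index,
                           missing = c("skip", "break"),
                           on_het = c("error", "warn")) {
  missing <- match.arg(missing)
  on_het <- match.arg(on_het)
  if (is.data.frame(carriers)) {
    carriers <- carriers$sample_id[carriers$copies == 2L]
  }
  if (length(carriers) < 2) {
    abort("shared-autozygosity search requires at least two homozygous carriers")
  }
  rows <- match(carriers, panel$sample_ids)
  if (anyNA(rows)) abort("carrier ids not all present in the panel")
  G <- panel$H1[rows, , drop = FALSE] + panel$H2[rows, , drop = FALSE]
  map <- panel$markers
  chrom <- map$chrom[start_index]
  if (map$chrom[end_index] != chrom) abort("seed window spans chromosomes")
  chrom_rows <- which(map$chrom == chrom)
  lo <- min(chrom_rows); hi <- max(chrom_rows)

  conforming <- function(j) {
    g <- G[, j]
    known <- !is.na(g)
    if (!any(known)) return(missing == "skip")
    if (missing == "break" && !all(known)) return(FALSE)
    g <- g[known]
    all(g %in% c(0L, 2L)) && length(unique(g)) == 1L
  }

  seed_ok <- vapply(start_index:end_index, conforming, logical(1))
  if (!all(seed_ok)) {
    msg <- "carrier(s) heterozygous or discordant inside the seed window"
    if (on_het == "error") abort(msg)
    warn(paste0(msg, "; returning the seed window without extension"))
    seg <- c(start_index, end_index)
  } else {
    left <- start_index
    while (left > lo && conforming(left - 1L)) left <- left - 1L
    right <- end_index
    while (right < hi && conforming(right + 1L)) right <- right + 1L
    seg <- c(left, right)
  }
  tibble(
    chrom = chrom,
    start_bp = map$pos_bp[seg[1]], end_bp = map$pos_bp[seg[2]],
    start_index = seg[1], end_index = seg[2],
    n_markers = seg[2] - seg[1] + 1L,
    n_carriers = length(carriers),
    length_bp = map$pos_bp[seg[2]] - map$pos_bp[seg[1]]
  )
}
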