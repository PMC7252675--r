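# shared fixtures, built once per test run
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a mid-sized cohort reused across module tests (full-scale runs live in the
# acceptance suite)
small_cfg <- function(...) {
  sim_config(seed = 42, n_bulls = 250L,
             n_snps_per_chrom = c(900L, 150L, 150L),
             records_per_bull = c(8L, 20L), n_insem_per_bull = 300L, ...)
}

small_sim <- function() fixture("small_sim", function() simulate_panel(small_cfg()))

small_records <- function() {
  fixture("small_records", function() simulate_records(small_cfg(), small_sim()$status))
}

small_scan_inputs <- function() {
  fixture("small_scan_inputs", function() {
    sim <- small_sim()
    rec <- small_records()
    tr <- aggregate_traits(filter_ejaculates(rec$records))
    pcs <- grm_pcs(panel_genotypes(sim$panel), k = 10)
    list(sim = sim,
         pheno = tibble::tibble(sample_id = tr$bull_id, value = tr$motility_pct),
         pcs = pcs, traits = tr)
  })
}

# hand-built tiny panel: explicit haplotypes over one chromosome
toy_panel <- function(H1, H2, chrom = "1", spacing = 1000L) {
  s <- ncol(H1)
  markers <- tibble::tibble(
    snp_id = sprintf("s%03d", seq_len(s)), chrom = chrom,
    pos_bp = seq_len(s) * spacing, ref = "A", alt = "C"
  )
  new_haplotype_panel(markers, H1, H2, sprintf("T%02d", seq_len(nrow(H1))))
}

# independent Hardy-Weinberg oracle: direct probability of every possible
# heterozygote count at fixed allele counts, via log-factorials
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  rare <- min(na, nb)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      lfactorial(na) + lfactorial(nb) - lfactorial(2 * n) + h * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[match(n_ab, hets)] + 1e-12])
}

# independent relationship-coefficient oracle: direct recursion on the sorted
# pedigree
a_recursive_oracle <- function(ped) {
  ped <- pedigree_sort(ped)
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  memo <- new.env(parent = emptyenv())
  a <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    s <- ped$sire[j]; d <- ped$dam[j]
    si <- if (is.na(s)) 0 else idx[[s]]
    di <- if (is.na(d)) 0 else idx[[d]]
    val <- if (i == j) {
      1 + 0.5 * a(si, di)
    } else {
      0.5 * (a(i, si) + a(i, di))
    }
    memo[[key]] <- val
    val
  }
  n <- nrow(ped)
  out <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) for (j in i:n) out[i, j] <- out[j, i] <- a(i, j)
  out
}

random_pedigree <- function(n = 20, seed = 7) {
  set.seed(seed)
  animal <- paste0("A", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    if (runif(1) < 0.7) sire[i] <- animal[sample(i - 1, 1)]
    if (runif(1) < 0.7) {
      cand <- setdiff(animal[seq_len(i - 1)], sire[i])
      if (length(cand)) dam[i] <- sample(cand, 1)
    }
  }
  tibble::tibble(animal = animal, sire = sire, dam = dam)
}

# minimal VCF writer for hand-constructed records
write_mini_vcf <- function(path, rows, samples, chrom = "6", contig_len = 7e7) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, as.integer(contig_len)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  path
}

quarter_of_oracle <- function(d) {
  (as.integer(format(as.Date(d), "%m")) - 1) %/% 3 + 1
}

pcs_ms <- function(pcs, ids) {
  as.matrix(pcs[match(ids, pcs$sample_id), -1, drop = FALSE])
}
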