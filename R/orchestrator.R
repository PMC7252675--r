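#' Pipeline configuration
#'
#' Collects the inputs and settings of the end-to-end analysis. Every input
#' can be an in-memory object (tibble, `haplotype_panel`) or a file path
#' (CSV for tables, VCF for panels); optional stages are skipped when their
#' input is `NULL`.
#'
#' @param records Ejaculate records (tibble or CSV path).
#' @param panel Phased panel (`haplotype_panel` or VCF path).
#' @param pedigree Pedigree (tibble or CSV path); enables the
#'   variance-component stage.
#' @param inseminations Insemination records (tibble or CSV path); enables
#'   the fertility stage.
#' @param region_vcf Candidate-region VCF path; enables the variant
#'   filtration stage.
#' @param junction_sam SAM of junction-spanning reads; with `junction_pair`,
#'   enables the splice-tally stage.
#' @param junction_pair A [splice_junction_pair()].
#' @param trait Record column used as the scan phenotype.
#' @param model Inheritance model for the scan.
#' @param n_pcs Number of GRM principal components.
#' @param window_size,step Scan window geometry.
#' @param filter A [filter_config()].
#' @param rule A [compatibility_rule()].
#' @param region Region string for the variant filtration stage, or `NULL`
#'   for the whole file.
#' @param min_inseminations Minimum inseminations per bull.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(records, panel, pedigree = NULL,
                            inseminations = NULL, region_vcf = NULL,
                            junction_sam = NULL, junction_pair = NULL,
                            trait = "motility_pct", model = "recessive",
                            n_pcs = 10, window_size = 50, step = 15,
                            filter = filter_config(),
                            rule = compatibility_rule(), region = NULL,
                            min_inseminations = 200, seed = 1L) {
  for (p in list(records, panel, inseminations, region_vcf, junction_sam)) {
    if (is.character(p) && !file.exists(p)) {
      abort(sprintf("input file does not exist: %s", p))
    }
  }
  structure(list(records = records, panel = panel, pedigree = pedigree,
                 inseminations = inseminations, region_vcf = region_vcf,
                 junction_sam = junction_sam, junction_pair = junction_pair,
                 trait = trait, model = model, n_pcs = n_pcs,
                 window_size = window_size, step = step, filter = filter,
                 rule = rule, region = region,
                 min_inseminations = min_inseminations, seed = seed),
            class = "pipeline_config")
}

load_table <- function(x) {
  if (is.character(x)) as_tibble(utils::read.csv(x)) else as_tibble(x)
}

load_panel <- function(x) {
  if (is.character(x)) read_panel_vcf(x) else x
}

#' Run the end-to-end mapping pipeline
#'
#' Executes, in order: the ejaculate filter cascade and per-bull trait
#' aggregation, optional fertility-index estimation, optional pedigree REML,
#' the haplotype scan with GRM principal components, status assignment and
#' shared-autozygosity search around the top haplotype, optional
#' recessive-compatibility variant filtration, and an optional junction-read
#' tally. Stage failures are caught: the report marks the stage with its
#' error and all downstream stages as skipped. The pipeline draws no random
#' numbers, so identical configuration and inputs give identical reports.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report`; each stage's element carries its
#'   result, an `error` string, or `"skipped"`. Includes per-stage timings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(seed = config$seed, stages = list(), timings = list())
  failed <- FALSE
  stage <- function(name, enabled, f) {
    if (failed) {
      report$stages[[name]] <<- "skipped"
      return(NULL)
    }
    if (!enabled) {
      report$stages[[name]] <<- "skipped"
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(f(), error = function(e) {
      failed <<- TRUE
      report$stages[[name]] <<- list(error = conditionMessage(e),
                                     code = paste0("E_", toupper(name)))
      NULL
    })
    report$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    if (!is.null(res)) report$stages[[name]] <<- res
    res
  }

  records <- load_table(config$records)
  panel <- load_panel(config$panel)

  qc <- stage("semenqc", TRUE, function() {
    filtered <- filter_ejaculates(records, config$filter,
                                  genotyped_ids = panel$sample_ids)
    traits <- aggregate_traits(filtered)
    list(attrition = attrition(filtered), traits = traits,
         filtered = filtered)
  })

  stage("fertility", !is.null(config$inseminations), function() {
    fert <- estimate_fertility(load_table(config$inseminations),
                               min_inseminations = config$min_inseminations)
    list(index = fert, outliers = attr(fert, "outliers"))
  })

  stage("varcomp", !is.null(config$pedigree), function() {
    fit <- reml_fit(qc$filtered, config$trait, load_table(config$pedigree))
    glance(fit)
  })

  scan <- stage("hapscan", TRUE, function() {
    pcs <- grm_pcs(panel_genotypes(panel), k = config$n_pcs)
    pheno <- tibble(sample_id = qc$traits$bull_id,
                    value = qc$traits[[config$trait]])
    hap_scan(panel, pheno, pcs = pcs, model = config$model,
             window_size = config$window_size, step = config$step)
  })

  seg <- stage("haplosegment", TRUE, function() {
    top <- scan$assoc[which.min(scan$assoc$p), ]
    status <- assign_status(panel, top$start_index, top$end_index,
                            top$haplotype)
    segment <- shared_segment(panel, status, top$start_index, top$end_index)
    list(top = top, status_counts = table(status$copies), status = status,
         segment = segment)
  })

  stage("recfilter", !is.null(config$region_vcf), function() {
    res <- filter_region(config$region_vcf, region = config$region,
                         groups = status_groups(seg$status),
                         rule = config$rule,
                         segment = c(seg$segment$start_bp, seg$segment$end_bp))
    res$summary
  })

  stage("splicekit", !is.null(config$junction_sam) && !is.null(config$junction_pair),
        function() {
    tally_junctions(config$junction_sam, config$junction_pair)
  })

  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    state <- if (identical(st, "skipped")) {
      "skipped"
    } else if (is.list(st) && !is.data.frame(st) && !is.null(st[["error"]])) {
      paste0("FAILED: ", st[["error"]])
    } else "ok"
    cat(sprintf("  %-12s %s\n", nm, state))
  }
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
report_json <- function(report, path) {
  slim <- report
  # drop bulky per-record elements, keep summaries
  if (is.list(slim$stages$semenqc)) slim$stages$semenqc$filtered <- NULL
  if (is.list(slim$stages$haplosegment)) {
    slim$stages$haplosegment$status <- NULL
    slim$stages$haplosegment$status_counts <-
      as.list(slim$stages$haplosegment$status_counts)
  }
  if (inherits(slim$stages$hapscan, "hap_scan")) {
    slim$stages$hapscan <- as.list(glance(slim$stages$hapscan))
  }
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
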