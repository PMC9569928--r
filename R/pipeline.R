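#' Run the modifier-gene discovery pipeline end to end
#'
#' Stage order: gene universe, qualification cascade, then gene burden
#' and family-based contrast analysis on the qualifying set, the
#' QC'd trend-test association scan on all sites, and pathway
#' over-representation of the burden candidates. Any stage can be
#' disabled. Inputs come either from files (`inputs:` block) or from the
#' bundled simulator (`simulate:` block). Reports are written as TSV
#' plus a JSON run report with input digests, per-stage counts and the
#' parameter snapshot.
#'
#' @param config path to a YAML configuration file, or an equivalent
#'   named list. Recognised keys: `out_dir`, `seed`, `simulate`
#'   (`fixture: table2|table4`), `inputs` (`vcf`, `ped`, `gene_lists`,
#'   `gmt`, `ann_field`), `stages` (logical toggles `burden`, `family`,
#'   `assoc`, `enrich`), `filter` ([filter_params()] arguments), `burden`
#'   (`threshold`), `assoc` ([assoc_params()] arguments), `enrich`
#'   (`universe: pathways|mt`, `alpha`).
#' @param out_dir output directory; overrides the config's `out_dir`.
#' @return object of class `pipeline_run` with the per-stage results and
#'   the run report, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  stages <- config$stages %||% list()
  on_stage <- function(nm) isTRUE(stages[[nm]] %||% TRUE)
  report <- list(tool = "mitomod",
                 version = as.character(utils::packageVersion("mitomod")),
                 seed = seed, stages = list(), outputs = list())
  outputs <- list()
  emit <- function(name, df) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv_report(df, path)
    outputs[[name]] <<- path
  }

  ## -- inputs ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    fixture <- config$simulate$fixture %||% "table2"
    cfg <- switch(fixture,
                  table2 = table2_fixture(seed),
                  table4 = table4_fixture(seed),
                  stop("unknown simulate fixture: ", fixture))
    sim <- generate_cohort(cfg, file.path(out_dir, "sim"))
    inputs <- list(vcf = sim$paths$vcf, ped = sim$paths$ped,
                   gene_lists = sim$paths$gene_lists, gmt = sim$paths$gmt)
  } else {
    inputs <- config$inputs %||% stop("config needs an inputs or simulate block")
    for (p in unlist(inputs[c("vcf", "ped", "gene_lists", "gmt")]))
      if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
  }
  report$inputs <- lapply(
    inputs[c("vcf", "ped", "gene_lists", "gmt")],
    function(p) if (is.null(p)) NULL else
      list(path = unname(p), md5 = unname(tools::md5sum(p))))

  message("reading cohort: ", inputs$vcf)
  cohort <- read_cohort(inputs$vcf, inputs$ped,
                        ann_field = inputs$ann_field %||% "CSQ")
  universe <- read_gene_universe(inputs$gene_lists)
  report$stages$cohort <- list(
    samples = nrow(cohort$samples), variants = nrow(cohort$sites),
    probands = sum(cohort$samples$group == "proband"),
    controls = sum(cohort$samples$group == "control"),
    universe_genes = length(universe$genes))
  message(sprintf("cohort: %d samples, %d variants; universe: %d genes",
                  nrow(cohort$samples), nrow(cohort$sites),
                  length(universe$genes)))

  ## -- qualification cascade ------------------------------------------
  fparams <- do.call(filter_params, config$filter %||% list())
  cascade <- apply_cascade(cohort, universe, fparams)
  report$stages$filter <- as.list(cascade$counts)
  message("cascade retained ", nrow(cascade$qualifying$sites), " variant(s)")

  run <- list(cohort = cohort, universe = universe, cascade = cascade)

  ## -- gene burden -----------------------------------------------------
  if (on_stage("burden")) {
    burden <- build_burden_table(cascade$qualifying)
    candidates <- select_candidates(burden,
                                    config$burden$threshold %||% 0.30)
    emit("burden", format_burden_report(burden))
    emit("candidates", format_burden_report(candidates))
    report$stages$burden <- list(genes = nrow(burden),
                                 candidates = nrow(candidates))
    run$burden <- burden; run$candidates <- candidates
    message(nrow(candidates), " candidate gene(s) at |difference| >= ",
            config$burden$threshold %||% 0.30)
  } else report$stages$burden <- "skipped"

  ## -- family-based analysis ------------------------------------------
  if (on_stage("family")) {
    contrasts <- family_contrasts(cascade$qualifying)
    conc <- concurrence_report(contrasts)
    emit("family_contrasts", format_family_report(contrasts))
    emit("concurrence", as.data.frame(conc))
    emit("concurrence_genes", attr(conc, "gene_level"))
    report$stages$family <- list(contrasts = nrow(contrasts),
                                 concurrent_variants = nrow(conc))
    run$contrasts <- contrasts; run$concurrence <- conc
  } else report$stages$family <- "skipped"

  ## -- association scan ------------------------------------------------
  if (on_stage("assoc")) {
    aparams <- do.call(assoc_params, config$assoc %||% list())
    scan <- run_association(cohort, aparams)
    emit("association", data.frame(
      Symbol = scan$results$gene,
      SNP = scan$results$key, HGVSc = scan$results$hgvsc,
      P = scan$results$p, AdjustedP = scan$results$p_adj))
    emit("association_qc", scan$qc_log)
    report$stages$assoc <- list(sites = nrow(scan$qc_log),
                                tested = nrow(scan$results),
                                significant = sum(scan$results$p <
                                                    aparams$alpha))
    run$assoc <- scan
  } else report$stages$assoc <- "skipped"

  ## -- pathway enrichment ----------------------------------------------
  if (on_stage("enrich") && !is.null(inputs$gmt)) {
    if (!on_stage("burden"))
      stop("enrichment needs the burden stage for its candidate list")
    pathways <- read_gmt(inputs$gmt)
    bg <- if (identical(config$enrich$universe, "mt")) universe else NULL
    enrich <- tryCatch(
      run_enrichment(run$candidates$gene, pathways, universe = bg,
                     alpha = config$enrich$alpha %||% 0.05),
      error = function(e) {
        message("enrichment skipped: ", conditionMessage(e)); NULL
      })
    if (!is.null(enrich)) {
      emit("enrichment", format_enrichment_report(enrich))
      report$stages$enrich <- list(pathways = nrow(enrich),
                                   significant = sum(enrich$significant))
      run$enrichment <- enrich
    } else report$stages$enrich <- "failed"
  } else report$stages$enrich <- "skipped"

  report$outputs <- outputs
  report$params <- list(filter = unclass(fparams),
                        burden_threshold = config$burden$threshold %||% 0.30,
                        assoc = if (on_stage("assoc")) unclass(aparams))
  report_path <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  run$report <- report
  run$report_path <- report_path
  class(run) <- "pipeline_run"
  invisible(run)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("mitomod pipeline run\n")
  cat("  cohort:", x$report$stages$cohort$samples, "samples,",
      x$report$stages$cohort$variants, "variants\n")
  if (!is.null(x$candidates))
    cat("  burden candidates:", nrow(x$candidates), "gene(s):",
        paste(utils::head(x$candidates$gene, 10), collapse = ", "), "\n")
  if (!is.null(x$concurrence))
    cat("  concurrent contrast variants:", nrow(x$concurrence), "\n")
  if (!is.null(x$assoc))
    cat("  association: ", nrow(x$assoc$results), "site(s) tested\n")
  if (!is.null(x$enrichment))
    cat("  enriched pathways:", sum(x$enrichment$significant), "of",
        nrow(x$enrichment), "\n")
  cat("  report:", x$report_path, "\n")
  invisible(x)
}
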