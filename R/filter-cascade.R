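## Sequence Ontology vocabulary for the qualification cascade.
## Loss-of-function classes qualify outright under the default score-gate
## scope; missense must clear the deleteriousness gate.
LOF_TERMS <- c("splice_donor_variant", "splice_acceptor_variant",
               "start_lost", "stop_gained", "frameshift_variant")
MISSENSE_TERMS <- "missense_variant"
EXCLUDED_TERMS <- c("5_prime_UTR_variant", "3_prime_UTR_variant",
                    "intron_variant", "synonymous_variant")

#' Parameters of the variant-qualification cascade
#'
#' Controls which variants count as qualifying for the burden and
#' family-based analyses: consequence classes to keep and discard,
#' ClinVar-benign exclusion, and the deleteriousness gate
#' (CADD Phred > `cadd_min` OR REVEL > `revel_min`, strict).
#'
#' @param cadd_min CADD Phred threshold (strict `>`), default 20.
#' @param revel_min REVEL threshold (strict `>`), default 0.5.
#' @param score_gate_scope which included classes the CADD/REVEL gate
#'   applies to: `"missense_only"` (default; loss-of-function classes
#'   bypass the gate, which carries no REVEL score), `"all"`, or `"off"`.
#' @param include_lof,include_missense consequence terms counted as
#'   loss-of-function / missense; edit to extend the synonym vocabulary.
#' @param exclude_consequences terms excluded outright (UTR, intron,
#'   synonymous by default).
#' @param exclude_clinvar variants whose ClinVar significance string
#'   contains any of these substrings (case-insensitive) are excluded.
#' @return object of class `filter_params`.
#' @export
filter_params <- function(cadd_min = 20, revel_min = 0.5,
                          score_gate_scope = c("missense_only", "all", "off"),
                          include_lof = LOF_TERMS,
                          include_missense = MISSENSE_TERMS,
                          exclude_consequences = EXCLUDED_TERMS,
                          exclude_clinvar = c("benign", "likely_benign")) {
  score_gate_scope <- match.arg(score_gate_scope)
  include <- c(include_lof, include_missense)
  if (length(intersect(include, exclude_consequences)))
    stop("include and exclude consequence sets must be disjoint")
  structure(list(cadd_min = cadd_min, revel_min = revel_min,
                 score_gate_scope = score_gate_scope,
                 include_lof = include_lof,
                 include_missense = include_missense,
                 exclude_consequences = exclude_consequences,
                 exclude_clinvar = exclude_clinvar),
            class = "filter_params")
}

clinvar_excluded <- function(clinvar, patterns) {
  if (is.na(clinvar) || clinvar == "") return(FALSE)
  any(vapply(patterns, grepl, logical(1), x = clinvar, ignore.case = TRUE,
             fixed = FALSE))
}

#' Classify variants through the qualification cascade
#'
#' Decision order per variant: gene-universe membership, consequence
#' exclusion, ClinVar-benign exclusion, consequence inclusion, then the
#' CADD/REVEL deleteriousness gate. A variant annotated with both an
#' excluded and an included term is judged by its most severe (included)
#' term. The gate passes on CADD Phred > `cadd_min` OR REVEL >
#' `revel_min`; when both scores are missing the gate fails.
#'
#' @param sites site data.frame of a [mito_cohort()] (columns `gene`,
#'   `consequence`, `clinvar`, `cadd`, `revel`).
#' @param universe a [read_gene_universe()] result.
#' @param params a [filter_params()].
#' @return data.frame with columns `key`, `retained` (logical) and
#'   `reason` (one of `not_in_universe`, `excluded_consequence`,
#'   `clinvar_benign`, `score_gate_failed`, `retained_lof`,
#'   `retained_missense`).
#' @export
classify_variants <- function(sites, universe, params = filter_params()) {
  stopifnot(inherits(universe, "gene_universe"),
            inherits(params, "filter_params"))
  score_pass <- function(cadd, revel) {
    if (is.na(cadd) && is.na(revel)) return(FALSE)
    isTRUE(cadd > params$cadd_min) || isTRUE(revel > params$revel_min)
  }
  reason <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    gene <- sites$gene[i]
    cons <- strsplit(sites$consequence[i] %||% "", "&", fixed = TRUE)[[1]]
    has_lof <- any(cons %in% params$include_lof)
    has_mis <- any(cons %in% params$include_missense)
    has_excl <- any(cons %in% params$exclude_consequences)
    reason[i] <- if (is.na(gene) || !(toupper(gene) %in% universe$genes)) {
      "not_in_universe"
    } else if (has_excl && !has_lof && !has_mis) {
      # an included term outranks a co-annotated excluded one
      "excluded_consequence"
    } else if (clinvar_excluded(sites$clinvar[i], params$exclude_clinvar)) {
      "clinvar_benign"
    } else if (!has_lof && !has_mis) {
      "excluded_consequence"
    } else {
      gated <- switch(params$score_gate_scope,
                      off = FALSE,
                      all = TRUE,
                      missense_only = !has_lof)
      if (gated && !score_pass(sites$cadd[i], sites$revel[i]))
        "score_gate_failed"
      else if (has_lof) "retained_lof" else "retained_missense"
    }
  }
  data.frame(key = sites$key, retained = startsWith(reason, "retained"),
             reason = reason, stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the qualification cascade to a cohort
#'
#' @param cohort a [mito_cohort()].
#' @param universe a [read_gene_universe()] result.
#' @param params a [filter_params()].
#' @return list with `qualifying` (the cohort subset to retained sites),
#'   `decisions` (per-variant classification) and `counts` (per-reason
#'   tally summing to the input site count).
#' @export
apply_cascade <- function(cohort, universe, params = filter_params()) {
  stopifnot(inherits(cohort, "mito_cohort"))
  dec <- classify_variants(cohort$sites, universe, params)
  lvls <- c("not_in_universe", "excluded_consequence", "clinvar_benign",
            "score_gate_failed", "retained_lof", "retained_missense")
  counts <- table(factor(dec$reason, levels = lvls))
  list(qualifying = subset_sites(cohort, which(dec$retained)),
       decisions = dec,
       counts = stats::setNames(as.integer(counts), lvls))
}
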