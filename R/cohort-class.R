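#' Multi-family exome cohort container
#'
#' Bundles the pedigree/phenotype table with bi-allelic annotated variant
#' sites and per-sample genotype matrices. Every analysis stage (filter
#' cascade, burden, family contrasts, association) operates on this object.
#'
#' @param samples data.frame with columns `sample_id`, `family_id`,
#'   `group` (`"proband"` or `"control"`) and `sex`
#'   (`"male"`, `"female"`, `"unknown"`).
#' @param sites data.frame with one row per bi-allelic variant: columns
#'   `chrom`, `pos`, `ref`, `alt` plus annotation columns `gene`,
#'   `consequence` (Sequence Ontology terms, `&`-separated), `clinvar`
#'   (raw significance string or `NA`), `cadd` (CADD Phred or `NA`),
#'   `revel` (`[0,1]` or `NA`), `hgvsc` (or `NA`).
#' @param dosage integer matrix (sites x samples) of alternate-allele
#'   counts: 0/1/2 for diploid calls, 0/1 for haploid, `NA` for missing.
#' @param gq,dp,af numeric matrices with the same shape: genotype quality
#'   (Phred), read depth, and alternate-allele read fraction (`NA` when
#'   depth is zero or the field is absent).
#' @return an object of class `mito_cohort`.
#' @export
mito_cohort <- function(samples, sites, dosage, gq = NULL, dp = NULL,
                        af = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "family_id", "group", "sex")
  if (!all(need %in% names(samples)))
    stop("samples must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in cohort")
  if (any(is.na(samples$group)) || !all(samples$group %in% c("proband", "control")))
    stop("group must be 'proband' or 'control' for every sample")
  if (!all(samples$sex %in% c("male", "female", "unknown")))
    stop("sex must be 'male', 'female' or 'unknown'")

  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  for (col in c("gene", "consequence", "clinvar", "hgvsc"))
    if (is.null(sites[[col]])) sites[[col]] <- NA_character_
  for (col in c("cadd", "revel"))
    if (is.null(sites[[col]])) sites[[col]] <- NA_real_
  key <- variant_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  if (anyDuplicated(key))
    stop("duplicate variant key (chrom,pos,ref,alt); split and deduplicate upstream")
  sites$key <- key
  rownames(sites) <- key

  shape_ok <- function(m) !is.null(m) &&
    nrow(m) == nrow(sites) && ncol(m) == nrow(samples)
  if (!shape_ok(dosage)) stop("dosage must be a sites x samples matrix")
  blank <- function(m) {
    if (is.null(m))
      m <- matrix(NA_real_, nrow(sites), nrow(samples))
    else if (!shape_ok(m)) stop("gq/dp/af matrices must match dosage shape")
    dimnames(m) <- list(key, samples$sample_id)
    m
  }
  dimnames(dosage) <- list(key, samples$sample_id)
  structure(
    list(samples = samples, sites = sites, dosage = dosage,
         gq = blank(gq), dp = blank(dp), af = blank(af)),
    class = "mito_cohort")
}

#' @export
print.mito_cohort <- function(x, ...) {
  grp <- table(factor(x$samples$group, c("proband", "control")))
  cat("mito_cohort:", nrow(x$samples), "samples in",
      length(unique(x$samples$family_id)), "families (",
      grp[["proband"]], "probands /", grp[["control"]], "controls ),",
      nrow(x$sites), "variant sites\n")
  cat("  genes annotated:", length(unique(stats::na.omit(x$sites$gene))), "\n")
  invisible(x)
}

#' Subset a cohort to a set of variant sites
#'
#' @param cohort a [mito_cohort()].
#' @param keys character vector of `chrom:pos:ref:alt` keys (or logical /
#'   integer index into the site table).
#' @return a `mito_cohort` restricted to those sites.
#' @export
subset_sites <- function(cohort, keys) {
  stopifnot(inherits(cohort, "mito_cohort"))
  if (is.character(keys)) {
    miss <- setdiff(keys, cohort$sites$key)
    if (length(miss)) stop("unknown variant keys: ", paste(miss, collapse = ", "))
    idx <- match(keys, cohort$sites$key)
  } else idx <- keys
  mito_cohort(cohort$samples, cohort$sites[idx, , drop = FALSE],
              cohort$dosage[idx, , drop = FALSE],
              cohort$gq[idx, , drop = FALSE],
              cohort$dp[idx, , drop = FALSE],
              cohort$af[idx, , drop = FALSE])
}

sample_ids <- function(cohort, group = NULL, family = NULL) {
  s <- cohort$samples
  if (!is.null(group)) s <- s[s$group %in% group, , drop = FALSE]
  if (!is.null(family)) s <- s[s$family_id %in% family, , drop = FALSE]
  s$sample_id
}
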