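#' Intra-family genotype-contrast filter
#'
#' Scans every qualifying variant in every family for a dose contrast
#' between affected probands and unaffected carrier controls: pattern A,
#' homozygous-alternate proband vs heterozygous control; pattern B,
#' heterozygous proband vs homozygous-reference control. Under the
#' default `control_rule = "max"` a proband is compared against the
#' maximum control dosage observed in the family, so a contrast requires
#' the proband's dosage to strictly exceed every control's. The closed
#' default pattern set {(2,1), (1,0)} can be relaxed to admit any strict
#' dosage excess (e.g. proband 2 vs control 0).
#'
#' @param qualifying a [mito_cohort()] restricted to qualifying variants.
#' @param patterns `"strict"` (default, patterns A/B only) or
#'   `"any_excess"` (any proband dosage strictly above the control
#'   reference).
#' @param control_rule `"max"` (default) compares against the family's
#'   maximum control dosage; `"any_pair"` admits a contrast when any
#'   single proband/control pair matches a pattern.
#' @return data.frame of class `family_contrasts`, one row per
#'   (variant, family) contrast: `key`, `gene`, `hgvsc`, `family_id`,
#'   `pattern` (`A_homalt_vs_het`, `B_het_vs_homref`, or
#'   `excess_relaxed`), `proband_ids` (comma-joined), `proband_dosage`,
#'   `control_dosage`.
#' @export
family_contrasts <- function(qualifying,
                             patterns = c("strict", "any_excess"),
                             control_rule = c("max", "any_pair")) {
  stopifnot(inherits(qualifying, "mito_cohort"))
  patterns <- match.arg(patterns)
  control_rule <- match.arg(control_rule)
  fams <- unique(qualifying$samples$family_id)
  out <- list()
  for (fam in fams) {
    pro <- sample_ids(qualifying, "proband", fam)
    ctl <- sample_ids(qualifying, "control", fam)
    if (!length(ctl)) {
      warning("family ", fam, " has no control member; skipped")
      next
    }
    if (!length(pro)) next
    for (i in seq_len(nrow(qualifying$sites))) {
      dp <- qualifying$dosage[i, pro]
      dc <- qualifying$dosage[i, ctl]
      dp <- dp[!is.na(dp)]; dc <- dc[!is.na(dc)]
      if (!length(dp) || !length(dc)) next
      hit <- if (control_rule == "max") {
        m <- max(dc)
        d <- dp[dp > m]
        if (length(d)) cbind(proband = max(d), control = m) else NULL
      } else {
        prs <- expand.grid(proband = dp, control = dc)
        prs <- prs[prs$proband > prs$control, , drop = FALSE]
        if (nrow(prs)) as.matrix(prs) else NULL
      }
      if (is.null(hit)) next
      pat <- apply(hit, 1, function(h) {
        if (h["proband"] == 2 && h["control"] == 1) "A_homalt_vs_het"
        else if (h["proband"] == 1 && h["control"] == 0) "B_het_vs_homref"
        else if (patterns == "any_excess") "excess_relaxed"
        else NA_character_
      })
      ok <- which(!is.na(pat))
      if (!length(ok)) next
      pick <- ok[which.max(hit[ok, "proband"])]
      d_pro <- hit[pick, "proband"]
      contributing <- pro[!is.na(qualifying$dosage[i, pro]) &
                            qualifying$dosage[i, pro] == d_pro]
      out[[length(out) + 1L]] <- data.frame(
        key = qualifying$sites$key[i],
        gene = qualifying$sites$gene[i],
        hgvsc = qualifying$sites$hgvsc[i],
        family_id = fam, pattern = pat[pick],
        proband_ids = paste(contributing, collapse = ","),
        proband_dosage = unname(d_pro),
        control_dosage = unname(hit[pick, "control"]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(key = character(), gene = character(), hgvsc = character(),
               family_id = character(), pattern = character(),
               proband_ids = character(), proband_dosage = integer(),
               control_dosage = integer())
  rownames(res) <- NULL
  class(res) <- c("family_contrasts", "data.frame")
  res
}

#' Cross-family concurrence of matched contrast variants
#'
#' Groups intra-family contrasts by variant identity and reports the
#' variants whose contrast recurs in at least two families (concurrence
#' count > 1), plus the number of families contrasting *any* variant of
#' the same gene. The companion gene-level table (attribute
#' `"gene_level"`) lists every gene with its distinct supporting
#' families, which surfaces genes hit through different variants in
#' different families.
#'
#' @param contrasts a [family_contrasts()] result.
#' @param min_count minimum number of supporting families for the
#'   variant-level report (default 2).
#' @return data.frame of class `concurrence_report`: `key`, `gene`,
#'   `hgvsc`, `families` (comma-joined), `count`, `gene_level_count`,
#'   sorted by decreasing count then gene. Attribute `"gene_level"` holds
#'   the per-gene summary (`gene`, `families`, `count`).
#' @export
concurrence_report <- function(contrasts, min_count = 2) {
  gene_fams <- lapply(split(contrasts$family_id, contrasts$gene),
                      function(f) sort(unique(f)))
  gene_level <- data.frame(
    gene = names(gene_fams),
    families = vapply(gene_fams, paste, character(1), collapse = ","),
    count = lengths(gene_fams), stringsAsFactors = FALSE)
  gene_level <- gene_level[order(-gene_level$count, gene_level$gene), ,
                           drop = FALSE]
  rownames(gene_level) <- NULL

  by_key <- split(contrasts, contrasts$key)
  rows <- lapply(by_key, function(g) {
    fams <- sort(unique(g$family_id))
    data.frame(key = g$key[1], gene = g$gene[1], hgvsc = g$hgvsc[1],
               families = paste(fams, collapse = ","),
               count = length(fams),
               gene_level_count = length(gene_fams[[g$gene[1]]]),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows) %||%
    data.frame(key = character(), gene = character(), hgvsc = character(),
               families = character(), count = integer(),
               gene_level_count = integer())
  rep <- rep[rep$count >= min_count, , drop = FALSE]
  rep <- rep[order(-rep$count, rep$gene), , drop = FALSE]
  rownames(rep) <- NULL
  attr(rep, "gene_level") <- gene_level
  class(rep) <- c("concurrence_report", "data.frame")
  rep
}

#' @export
print.concurrence_report <- function(x, ...) {
  cat("Cross-family concurrence:", nrow(x),
      "variant(s) contrasting in >1 family\n")
  print(as.data.frame(x), ...)
  gl <- attr(x, "gene_level")
  cat("Gene-level support:", sum(gl$count > 1), "gene(s) in >1 family\n")
  invisible(x)
}

#' Format family contrasts for the TSV report
#'
#' @param contrasts a [family_contrasts()] result.
#' @return data.frame with columns Gene, Chromosome, Family, Pattern,
#'   HGVSc, ProbandGenotype, ControlGenotype.
#' @export
format_family_report <- function(contrasts) {
  gt <- function(d) c("0/0", "0/1", "1/1")[d + 1]
  data.frame(Gene = contrasts$gene,
             Chromosome = sub(":.*", "", contrasts$key),
             Family = contrasts$family_id,
             Pattern = contrasts$pattern,
             HGVSc = contrasts$hgvsc,
             ProbandGenotype = gt(contrasts$proband_dosage),
             ControlGenotype = gt(contrasts$control_dosage),
             stringsAsFactors = FALSE)
}
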