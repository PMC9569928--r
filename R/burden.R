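#' Affected sample rate of one gene in one group
#'
#' Fraction of the group's samples carrying at least one alternate allele
#' (dosage >= 1) of any qualifying variant of the gene. Missing genotypes
#' count as non-carrier; the denominator is always the full group size.
#'
#' @param qualifying a [mito_cohort()] restricted to qualifying variants.
#' @param gene gene symbol.
#' @param group `"proband"` or `"control"`.
#' @return rate in `[0, 1]`.
#' @export
affected_sample_rate <- function(qualifying, gene, group) {
  ids <- sample_ids(qualifying, group = group)
  if (!length(ids)) stop("group '", group, "' has no samples")
  idx <- which(!is.na(qualifying$sites$gene) &
                 toupper(qualifying$sites$gene) == toupper(gene))
  if (!length(idx)) return(0)
  d <- qualifying$dosage[idx, ids, drop = FALSE]
  carriers <- colSums(d >= 1, na.rm = TRUE) > 0
  sum(carriers) / length(ids)
}

#' Per-gene burden table of group rates and their difference
#'
#' One row per gene with at least one qualifying variant: the affected
#' sample rate in the control and proband groups and the proband-minus-
#' control difference (computed on unrounded rates). Rows are ordered by
#' decreasing `|difference|`, ties broken alphabetically.
#'
#' @param qualifying a [mito_cohort()] restricted to qualifying variants.
#' @return data.frame of class `burden_table` with columns `gene`,
#'   `chrom`, `control_rate`, `proband_rate`, `difference`.
#' @export
build_burden_table <- function(qualifying) {
  stopifnot(inherits(qualifying, "mito_cohort"))
  groups <- unique(qualifying$samples$group)
  if (!all(c("proband", "control") %in% groups))
    stop("cohort must contain both a proband and a control group")
  genes <- unique(stats::na.omit(qualifying$sites$gene))
  rows <- lapply(genes, function(g) {
    cr <- affected_sample_rate(qualifying, g, "control")
    pr <- affected_sample_rate(qualifying, g, "proband")
    chrom <- qualifying$sites$chrom[
      which(!is.na(qualifying$sites$gene) & qualifying$sites$gene == g)[1]]
    data.frame(gene = g, chrom = chrom, control_rate = cr, proband_rate = pr,
               difference = pr - cr, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows) %||%
    data.frame(gene = character(), chrom = character(),
               control_rate = numeric(), proband_rate = numeric(),
               difference = numeric())
  tab <- tab[order(-abs(tab$difference), tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("burden_table", "data.frame")
  tab
}

#' @export
print.burden_table <- function(x, digits = 2, ...) {
  cat("Gene burden table:", nrow(x), "gene(s)\n")
  y <- as.data.frame(x)
  for (col in c("control_rate", "proband_rate", "difference"))
    y[[col]] <- round_half_away(y[[col]], digits)
  print(utils::head(y, 15), ...)
  if (nrow(y) > 15) cat("... and", nrow(y) - 15, "more rows\n")
  invisible(x)
}

#' Select candidate modifier genes from a burden table
#'
#' Keeps genes whose absolute rate difference, rounded half-away-from-zero
#' to two decimals, is at least `threshold`. Rounding before comparison
#' means a difference printed as 0.30 passes a 0.30 threshold even when
#' the unrounded value is 0.2857.
#'
#' @param table a [build_burden_table()] result.
#' @param threshold minimum `|difference|` in `(0, 1]`; default 0.30.
#' @return the selected rows of `table`.
#' @export
select_candidates <- function(table, threshold = 0.30) {
  stopifnot(threshold > 0, threshold <= 1)
  sel <- table[abs(round_half_away(table$difference, 2)) >= threshold, ,
               drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Format a burden table for the TSV report
#'
#' @param table a [build_burden_table()] result.
#' @return data.frame with columns Symbol, Chromosome, ControlRate,
#'   ProbandRate, Difference (rates rounded to 2 decimals).
#' @export
format_burden_report <- function(table) {
  data.frame(Symbol = table$gene, Chromosome = table$chrom,
             ControlRate = round_half_away(table$control_rate, 2),
             ProbandRate = round_half_away(table$proband_rate, 2),
             Difference = round_half_away(table$difference, 2),
             stringsAsFactors = FALSE)
}
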