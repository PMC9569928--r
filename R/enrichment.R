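#' Hypergeometric over-representation test for one pathway
#'
#' Upper-tail hypergeometric probability of drawing at least `k` pathway
#' genes when `n` candidate genes are sampled from a universe of `N`
#' genes of which `K` belong to the pathway. Candidates outside the
#' universe are dropped with a warning; the pathway is intersected with
#' the universe.
#'
#' @param candidates character vector of candidate gene symbols.
#' @param pathway character vector of pathway member symbols.
#' @param universe character vector of background symbols.
#' @return list with `k`, `K`, `n`, `N`, `p` and `overlap` (the candidate
#'   genes in the pathway).
#' @export
ora_test <- function(candidates, pathway, universe) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty gene universe")
  candidates <- unique(toupper(candidates))
  pathway <- unique(toupper(pathway))
  if (length(out <- setdiff(candidates, universe))) {
    warning(length(out), " candidate gene(s) outside the universe dropped: ",
            paste(utils::head(out, 5), collapse = ", "))
    candidates <- intersect(candidates, universe)
  }
  pathway <- intersect(pathway, universe)
  if (!length(pathway)) stop("pathway has no genes in the universe")
  overlap <- intersect(candidates, pathway)
  k <- length(overlap); K <- length(pathway)
  n <- length(candidates); N <- length(universe)
  p <- if (k == 0) 1 else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = min(1, p), overlap = sort(overlap))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment; output order matches the
#' input order. Values must lie in (0, 1].
#'
#' @param pvalues numeric vector of raw p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Pathway over-representation of the candidate gene list
#'
#' Runs [ora_test()] for every pathway in a collection and adjusts the
#' p-values with [bh_adjust()]. The background defaults to the union of
#' all pathway genes; pass the mitochondria-related gene universe to
#' restrict it.
#'
#' @param candidates candidate gene symbols (e.g. the
#'   [select_candidates()] genes).
#' @param pathways a [read_gmt()] collection.
#' @param universe background symbols; default: union of pathway genes.
#' @param alpha significance level applied to the adjusted p (0.05).
#' @return data.frame of class `enrichment_table`: one row per pathway
#'   with `pathway_id`, `pathway_name`, `k`, `K`, `n`, `N`, `genes`
#'   (slash-joined overlap), `p`, `adj_p`, `significant`; ordered by
#'   `adj_p`.
#' @export
run_enrichment <- function(candidates, pathways, universe = NULL,
                           alpha = 0.05) {
  stopifnot(inherits(pathways, "pathway_collection"))
  if (!length(pathways)) stop("empty pathway collection; nothing to test")
  if (is.null(universe))
    universe <- unique(toupper(unlist(lapply(pathways, `[[`, "genes"))))
  else if (inherits(universe, "gene_universe")) universe <- universe$genes
  rows <- lapply(names(pathways), function(id) {
    pw <- pathways[[id]]
    if (!length(intersect(toupper(pw$genes), toupper(universe))))
      return(NULL)
    t <- suppressWarnings(ora_test(candidates, pw$genes, universe))
    data.frame(pathway_id = id, pathway_name = pw$name, k = t$k, K = t$K,
               n = t$n, N = t$N, genes = paste(t$overlap, collapse = "/"),
               p = t$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no pathway overlaps the universe")
  tab$adj_p <- bh_adjust(tab$p)
  tab$significant <- tab$adj_p < alpha
  tab <- tab[order(tab$adj_p, tab$p, tab$pathway_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Format an enrichment table for the TSV report
#'
#' @param tab a [run_enrichment()] result.
#' @return data.frame with columns Pathway, Symbols, AdjustedP.
#' @export
format_enrichment_report <- function(tab) {
  data.frame(Pathway = tab$pathway_name, Symbols = tab$genes,
             AdjustedP = tab$adj_p, stringsAsFactors = FALSE)
}
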