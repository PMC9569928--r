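#' Build the mitochondria-related nuclear gene universe
#'
#' Reads one or more plain-text gene lists (one symbol per line; blank
#' lines and `#` comments ignored) and returns their union. Symbols are
#' upper-cased before deduplication, so case conventions may differ
#' between source lists. Typical sources are a curated mitochondrial
#' canonical-pathway list and a MitoCarta-style inventory.
#'
#' @param list_paths character vector of file paths; names (or basenames)
#'   label the per-source counts.
#' @return object of class `gene_universe`: list with `genes` (sorted
#'   unique symbols) and `source_counts` (named integer vector).
#' @export
read_gene_universe <- function(list_paths) {
  if (!length(list_paths)) stop("at least one gene list is required")
  labels <- names(list_paths)
  if (is.null(labels)) labels <- rep("", length(list_paths))
  labels <- ifelse(labels == "",
                   tools::file_path_sans_ext(basename(list_paths)), labels)
  per_source <- lapply(list_paths, function(p) {
    x <- readLines(p, warn = FALSE)
    x <- trimws(x)
    x <- x[x != "" & !startsWith(x, "#")]
    unique(toupper(x))
  })
  genes <- sort(unique(unlist(per_source)))
  if (!length(genes)) stop("gene universe is empty")
  structure(list(genes = genes,
                 source_counts = stats::setNames(lengths(per_source), labels)),
            class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("gene_universe:", length(x$genes), "symbols from",
      length(x$source_counts), "source list(s)\n")
  for (nm in names(x$source_counts))
    cat("  -", nm, ":", x$source_counts[[nm]], "symbols\n")
  invisible(x)
}

#' Read pathway definitions in GMT format
#'
#' Tab-separated lines: pathway id, description, then member gene symbols.
#' Genes are upper-cased and deduplicated per pathway; lines with fewer
#' than three fields are skipped with a warning.
#'
#' @param path GMT file path.
#' @return object of class `pathway_collection`: named list of pathways,
#'   each a list with `name` and `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  pathways <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      warning("GMT line with fewer than 3 fields skipped: ",
              substr(ln, 1, 40))
      next
    }
    genes <- unique(toupper(trimws(f[-(1:2)])))
    genes <- genes[genes != ""]
    if (!length(genes)) next
    pathways[[f[1]]] <- list(name = f[2], genes = genes)
  }
  structure(pathways, class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("pathway_collection:", length(x), "pathway(s)\n")
  invisible(x)
}
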