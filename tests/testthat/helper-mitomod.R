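# In-code fixtures shared across test files.

# gene_universe without touching the filesystem
make_universe <- function(genes) {
  structure(list(genes = sort(unique(toupper(genes))),
                 source_counts = c(test = length(genes))),
            class = "gene_universe")
}

# minimal qualifying site annotation, overridable per field
make_site <- function(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                      gene = "GENE1", consequence = "missense_variant",
                      clinvar = NA, cadd = 30, revel = NA, hgvsc = NA) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             consequence = consequence, clinvar = clinvar, cadd = cadd,
             revel = revel, hgvsc = hgvsc, stringsAsFactors = FALSE)
}

# cohort with explicit dosage rows; samples default to 2 families with
# proband/control split given by `groups`
make_cohort <- function(dosage, groups, families = NULL, sex = NULL,
                        sites = NULL, gq = NULL, dp = NULL, af = NULL) {
  dosage <- rbind(dosage)
  ns <- ncol(dosage)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(ns)),
    family_id = families %||% rep("F1", ns),
    group = groups,
    sex = sex %||% rep("female", ns),
    stringsAsFactors = FALSE)
  if (is.null(sites))
    sites <- do.call(rbind, lapply(seq_len(nrow(dosage)), function(i)
      make_site(pos = 100 + i)))
  mito_cohort(samples, sites, dosage, gq = gq, dp = dp, af = af)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# choose()-based full-enumeration oracle for the exact HWE test,
# independent of the recurrence used by the implementation
hwe_oracle <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  rare <- min(2 * hom_ref + het, 2 * hom_alt + het)
  hs <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  w <- vapply(hs, function(h) {
    a <- (rare - h) / 2
    b <- (2 * n - rare - h) / 2
    choose(n, a) * choose(n - a, h) * 2^h
  }, numeric(1))
  p <- w / sum(w)
  sum(p[p <= p[hs == het] * (1 + 1e-12)])
}

# label-permutation estimate of the trend-test p (statistic recomputed
# from scratch, not via ca_trend_test)
perm_trend_p <- function(tab, B = 2000, weights = 0:2) {
  g <- rep(weights, colSums(tab))
  n1 <- sum(tab[1, ])
  N <- length(g)
  m <- colSums(tab)
  Vt <- (n1 * (N - n1) / N) * (N * sum(weights^2 * m) - sum(weights * m)^2)
  if (Vt == 0) return(1)
  Tobs <- N * sum(weights * tab[1, ]) - n1 * sum(weights * m)
  obs <- Tobs^2 / Vt
  hits <- 0
  for (b in seq_len(B)) {
    Tb <- N * sum(g[sample.int(N, n1)]) - n1 * sum(weights * m)
    if (Tb^2 / Vt >= obs - 1e-9) hits <- hits + 1
  }
  hits / B
}
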