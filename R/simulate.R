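#' Gene specifications for the cohort simulator
#'
#' Three planting modes mirror the structures the pipeline looks for:
#' `sim_gene_rates()` plants one qualifying variant whose carrier
#' frequency differs between probands and controls (gene-burden signal);
#' `sim_gene_contrast()` plants intra-family dose contrasts (pattern
#' `"A"`: homozygous-alternate proband vs heterozygous control; `"B"`:
#' heterozygous proband vs homozygous-reference control) in named
#' families, either as one shared variant or one distinct variant per
#' family; `sim_gene_null()` plants a variant carried at the same rate in
#' both groups.
#'
#' @param symbol gene symbol.
#' @param chrom chromosome label (e.g. `"chr1"`).
#' @param p_proband,p_control carrier probabilities per group.
#' @param rate shared carrier probability for a null gene.
#' @param families family ids (as in the PED) receiving a contrast.
#' @param patterns `"A"` or `"B"`, one per family.
#' @param shared if `TRUE` (default) all families contrast the same
#'   variant; if `FALSE` each family gets its own variant.
#' @param hgvsc optional HGVSc string(s), recycled over variants.
#' @return a gene-spec list consumed by [cohort_sim_config()].
#' @name sim_genes
NULL

#' @rdname sim_genes
#' @export
sim_gene_rates <- function(symbol, chrom, p_proband, p_control) {
  list(symbol = symbol, chrom = chrom, mode = "group_rates",
       p_proband = p_proband, p_control = p_control)
}

#' @rdname sim_genes
#' @export
sim_gene_contrast <- function(symbol, chrom, families, patterns,
                              shared = TRUE, hgvsc = NULL) {
  stopifnot(length(patterns) == length(families),
            all(patterns %in% c("A", "B")))
  list(symbol = symbol, chrom = chrom, mode = "family_contrast",
       families = as.character(families), patterns = patterns,
       shared = shared, hgvsc = hgvsc)
}

#' @rdname sim_genes
#' @export
sim_gene_null <- function(symbol, chrom, rate) {
  list(symbol = symbol, chrom = chrom, mode = "null", rate = rate)
}

#' Configuration of a synthetic multi-family cohort
#'
#' Describes a seed-deterministic cohort with the structure of a
#' multi-family incomplete-penetrance exome study: a handful of families
#' each holding affected probands and unaffected carrier controls,
#' planted modifier genes, and annotated background variants that the
#' qualification cascade should discard.
#'
#' @param probands_per_family,controls_per_family integer vectors, one
#'   entry per family.
#' @param male_fraction_probands,male_fraction_controls fraction of
#'   males per group (assigned deterministically as rounded counts).
#' @param genes list of [sim_gene_rates()] / [sim_gene_contrast()] /
#'   [sim_gene_null()] specs.
#' @param n_background_variants number of non-qualifying background
#'   variants cycling through disqualifying annotation classes
#'   (synonymous, intronic, UTR, ClinVar-benign missense, sub-threshold
#'   missense, out-of-universe missense).
#' @param carrier_mode `"exact"`: carrier counts equal
#'   `round(rate x group size)` exactly, carrier identity seeded-random;
#'   `"stochastic"`: independent Bernoulli carriers.
#' @param filler_genes extra symbols padding the two gene-universe source
#'   lists.
#' @param pathways list of `list(id=, name=, genes=)` written to the GMT.
#' @param seed integer seed governing all randomness.
#' @return object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(probands_per_family = c(2, 1, 1, 2, 1),
                              controls_per_family = c(2, 2, 2, 2, 2),
                              male_fraction_probands = 6 / 7,
                              male_fraction_controls = 2 / 10,
                              genes = list(),
                              n_background_variants = 30,
                              carrier_mode = c("exact", "stochastic"),
                              filler_genes = sprintf("MTFIL%02d", 1:20),
                              pathways = NULL,
                              seed = 1L) {
  stopifnot(length(probands_per_family) == length(controls_per_family),
            all(probands_per_family >= 0), all(controls_per_family >= 0),
            sum(probands_per_family) >= 1, sum(controls_per_family) >= 1)
  structure(list(probands_per_family = probands_per_family,
                 controls_per_family = controls_per_family,
                 male_fraction_probands = male_fraction_probands,
                 male_fraction_controls = male_fraction_controls,
                 genes = genes,
                 n_background_variants = n_background_variants,
                 carrier_mode = match.arg(carrier_mode),
                 filler_genes = filler_genes,
                 pathways = pathways, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

## deterministic sex assignment: first `round(frac * n)` members male
assign_sex <- function(n, frac) {
  k <- round_half_away(frac * n, 0)
  c(rep("male", k), rep("female", n - k))
}

#' Generate a synthetic annotated cohort
#'
#' Builds the in-memory [mito_cohort()] described by the configuration
#' and (optionally) writes the full input bundle — VCF 4.2, 6-column PED,
#' two gene-universe source lists and a GMT — so the files round-trip
#' through [read_cohort()] unchanged. All planted modifier variants carry
#' qualifying annotations (missense, CADD Phred > 20) and call-quality
#' fields that pass default genotype QC; background variants carry
#' disqualifying annotations. Identical configurations (same seed)
#' produce byte-identical files.
#'
#' @param config a [cohort_sim_config()].
#' @param dir output directory (created if needed); `NULL` skips file
#'   output.
#' @return list of class `sim_cohort`: `cohort` (the [mito_cohort()]),
#'   `universe_genes` (symbols in the two source lists), and `paths`
#'   (named file paths, when `dir` is given).
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(config$seed)

  nf <- length(config$probands_per_family)
  fam_ids <- sprintf("F%d", seq_len(nf))
  samples <- do.call(rbind, lapply(seq_len(nf), function(f) {
    np <- config$probands_per_family[f]
    nc <- config$controls_per_family[f]
    data.frame(
      sample_id = c(sprintf("%s_P%d", fam_ids[f], seq_len(np)),
                    sprintf("%s_C%d", fam_ids[f], seq_len(nc))),
      family_id = fam_ids[f],
      group = c(rep("proband", np), rep("control", nc)),
      stringsAsFactors = FALSE)
  }))
  samples$sex <- NA_character_
  for (grp in c("proband", "control")) {
    idx <- which(samples$group == grp)
    frac <- if (grp == "proband") config$male_fraction_probands
            else config$male_fraction_controls
    samples$sex[idx] <- assign_sex(length(idx), frac)
  }
  ns <- nrow(samples)
  pro <- samples$sample_id[samples$group == "proband"]
  ctl <- samples$sample_id[samples$group == "control"]

  pos_counter <- new.env()
  next_pos <- function(chrom) {
    cur <- get0(chrom, pos_counter, ifnotfound = 1e6)
    assign(chrom, cur + 997, pos_counter)  # co-prime step, distinct sites
    as.integer(cur)
  }
  sites <- list(); dosages <- list()
  add_variant <- function(chrom, gene, consequence, dosage, clinvar = NA,
                          cadd = NA, revel = NA, hgvsc = NA,
                          ref = "A", alt = "G") {
    pos <- next_pos(chrom)
    sites[[length(sites) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
      consequence = consequence, clinvar = clinvar, cadd = cadd,
      revel = revel,
      hgvsc = if (is.na(hgvsc)) sprintf("c.%d%s>%s", pos %% 2000 + 1,
                                        ref, alt) else hgvsc,
      stringsAsFactors = FALSE)
    dosages[[length(dosages) + 1L]] <<- dosage
  }
  qual_cadd <- function() round(20.5 + stats::runif(1) * 15, 1)
  carriers <- function(ids, rate) {
    if (config$carrier_mode == "exact") {
      k <- round_half_away(rate * length(ids), 0)
      if (k > length(ids)) stop("more carriers than group members")
      sample(ids, k)
    } else ids[stats::runif(length(ids)) < rate]
  }

  for (g in config$genes) {
    if (g$mode %in% c("group_rates", "null")) {
      d <- stats::setNames(integer(ns), samples$sample_id)
      pp <- if (g$mode == "null") g$rate else g$p_proband
      pc <- if (g$mode == "null") g$rate else g$p_control
      d[carriers(pro, pp)] <- 1L
      d[carriers(ctl, pc)] <- 1L
      add_variant(g$chrom, g$symbol, "missense_variant", d,
                  cadd = qual_cadd(), hgvsc = g$hgvsc %||% NA)
    } else {  # family_contrast
      plant <- function(fams, pats, hg) {
        d <- stats::setNames(integer(ns), samples$sample_id)
        for (j in seq_along(fams)) {
          fam <- fams[j]
          is_fam <- samples$family_id == fam
          d[is_fam & samples$group == "proband"] <-
            if (pats[j] == "A") 2L else 1L
          d[is_fam & samples$group == "control"] <-
            if (pats[j] == "A") 1L else 0L
        }
        add_variant(g$chrom, g$symbol, "missense_variant", d,
                    cadd = qual_cadd(), hgvsc = hg)
      }
      hg <- g$hgvsc
      if (isTRUE(g$shared)) {
        plant(g$families, g$patterns, if (is.null(hg)) NA else hg[1])
      } else {
        for (j in seq_along(g$families))
          plant(g$families[j], g$patterns[j],
                if (is.null(hg)) NA else hg[min(j, length(hg))])
      }
    }
  }

  ## background variants: cycle through disqualifying annotation classes
  universe_syms <- unique(c(vapply(config$genes, `[[`, "", "symbol"),
                            config$filler_genes))
  bg_classes <- list(
    list(cons = "synonymous_variant", clin = NA, cadd = NA, in_univ = TRUE),
    list(cons = "intron_variant", clin = NA, cadd = NA, in_univ = TRUE),
    list(cons = "5_prime_UTR_variant", clin = NA, cadd = NA, in_univ = TRUE),
    list(cons = "missense_variant", clin = "Benign/Likely_benign",
         cadd = 30, in_univ = TRUE),
    list(cons = "missense_variant", clin = NA, cadd = 8, in_univ = TRUE),
    list(cons = "missense_variant", clin = NA, cadd = 30, in_univ = FALSE))
  for (b in seq_len(config$n_background_variants)) {
    cl <- bg_classes[[(b - 1) %% length(bg_classes) + 1]]
    gene <- if (cl$in_univ)
      universe_syms[(b - 1) %% length(universe_syms) + 1]
    else sprintf("OUTSIDE%02d", b)
    d <- stats::setNames(as.integer(stats::runif(ns) < 0.3),
                         samples$sample_id)
    chrom <- sprintf("chr%d", (b - 1) %% 22 + 1)
    add_variant(chrom, gene, cl$cons, d, clinvar = cl$clin, cadd = cl$cadd,
                revel = if (is.na(cl$cadd)) NA else 0.1)
  }

  sites_df <- do.call(rbind, sites)
  dosage <- do.call(rbind, dosages)
  nv <- nrow(sites_df)
  gq <- matrix(as.numeric(30 + floor(stats::runif(nv * ns) * 70)), nv, ns)
  dp <- matrix(as.numeric(20 + floor(stats::runif(nv * ns) * 40)), nv, ns)
  af <- matrix(NA_real_, nv, ns)
  af[dosage == 0] <- 0
  af[dosage == 2] <- 1
  af[dosage == 1] <- round(0.35 + stats::runif(sum(dosage == 1,
                                                   na.rm = TRUE)) * 0.3, 3)
  cohort <- mito_cohort(samples, sites_df, dosage, gq, dp, af)

  ## two overlapping source lists that jointly cover every universe gene
  half <- ceiling(length(universe_syms) / 2)
  list_a <- universe_syms[seq_len(min(length(universe_syms),
                                      half + 3))]  # overlap of 3+
  list_b <- universe_syms[half:length(universe_syms)]
  pathways <- config$pathways %||% list(
    list(id = "pw_cofactors", name = "Biosynthesis of cofactors",
         genes = c(universe_syms[seq_len(min(3, length(universe_syms)))],
                   config$filler_genes[1:2])),
    list(id = "pw_null", name = "Unrelated pathway",
         genes = config$filler_genes[3:10]))

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(vcf = file.path(dir, "cohort.vcf"),
                  ped = file.path(dir, "cohort.ped"),
                  gene_lists = c(file.path(dir, "mt_canonical.txt"),
                                 file.path(dir, "mitocarta.txt")),
                  gmt = file.path(dir, "pathways.gmt"))
    write_cohort_vcf(cohort, paths$vcf)
    ped <- data.frame(samples$family_id, samples$sample_id, 0, 0,
                      match(samples$sex, c("unknown", "male", "female")) - 1,
                      ifelse(samples$group == "proband", 2, 1))
    utils::write.table(ped, paths$ped, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines(list_a, paths$gene_lists[1])
    writeLines(list_b, paths$gene_lists[2])
    writeLines(vapply(pathways, function(p)
      paste(c(p$id, p$name, p$genes), collapse = "\t"), character(1)),
      paths$gmt)
  }
  structure(list(cohort = cohort, universe_genes = universe_syms,
                 source_lists = list(list_a, list_b), pathways = pathways,
                 paths = paths, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort (seed", x$config$seed, ")\n")
  print(x$cohort)
  invisible(x)
}

#' Worked-example fixture: ten genes with known group-rate differences
#'
#' Encodes a 5-family cohort (7 probands, 10 carrier controls) carrying
#' ten modifier genes planted in exact-count mode so that the burden
#' stage reproduces, after 2-decimal rounding, control/proband affected
#' sample rates of e.g. 0.70/0.29 (difference -0.41) for AK4 and
#' 0.60/1.00 (+0.40) for NSUN4, alongside background variants the
#' cascade must discard.
#'
#' @param seed integer seed.
#' @return a [cohort_sim_config()].
#' @export
table2_fixture <- function(seed = 20221006L) {
  specs <- list(
    # symbol, chrom, control carriers /10, proband carriers /7
    c("AK4", "chr1", 7, 2), c("NSUN4", "chr1", 6, 7),
    c("RDH13", "chr19", 5, 1), c("COQ3", "chr6", 5, 6),
    c("FAHD1", "chr16", 1, 3), c("CHPT1", "chr12", 7, 7),
    c("METAP1D", "chr2", 7, 7), c("MRM1", "chr17", 3, 0),
    c("NCOA6", "chr20", 3, 0), c("TOP3A", "chr17", 3, 0))
  genes <- lapply(specs, function(s)
    sim_gene_rates(s[1], s[2], p_proband = as.numeric(s[4]) / 7,
                   p_control = as.numeric(s[3]) / 10))
  # balanced null genes: qualifying variants with no group difference
  genes <- c(genes, list(sim_gene_null("SFXN1", "chr5", 0.5),
                         sim_gene_null("MRPL44", "chr2", 0.4)))
  pathways <- list(
    list(id = "pw_cofactor", name = "Biosynthesis of cofactors",
         genes = c("AK4", "RDH13", "COQ3", "MTFIL01", "MTFIL02")),
    list(id = "pw_quinone",
         name = "Ubiquinone and other terpenoid-quinone biosynthesis",
         genes = c("COQ3", "MTFIL03")),
    list(id = "pw_thiamine", name = "Thiamine metabolism",
         genes = c("AK4", "MTFIL04")),
    list(id = "pw_null_a", name = "Unrelated pathway A",
         genes = sprintf("MTFIL%02d", 5:12)),
    list(id = "pw_null_b", name = "Unrelated pathway B",
         genes = sprintf("MTFIL%02d", 13:20)))
  cohort_sim_config(genes = genes, n_background_variants = 30,
                    carrier_mode = "exact", pathways = pathways,
                    seed = seed)
}

#' Family-contrast fixture with planted cross-family concurrence
#'
#' Plants the three contrast structures the concurrence report
#' distinguishes: a variant contrasting in two families (reported,
#' count 2), one gene hit through two different variants in two families
#' (variant-level counts 1, gene-level count 2), and a single-family
#' contrast (suppressed). Patterns mix homozygous-vs-het (A) and
#' het-vs-reference (B) dose contrasts.
#'
#' @param seed integer seed.
#' @return a [cohort_sim_config()].
#' @export
table4_fixture <- function(seed = 20221006L) {
  genes <- list(
    sim_gene_contrast("METAP1D", "chr2", families = c("F1", "F2"),
                      patterns = c("B", "A"), shared = TRUE,
                      hgvsc = "c.41G>T"),
    sim_gene_contrast("ME3", "chr11", families = c("F2", "F4"),
                      patterns = c("B", "A"), shared = TRUE,
                      hgvsc = "c.972G>C"),
    sim_gene_contrast("NSUN4", "chr1", families = c("F4", "F5"),
                      patterns = c("A", "B"), shared = TRUE,
                      hgvsc = "c.4A>G"),
    sim_gene_contrast("ACACB", "chr12", families = c("F1", "F4"),
                      patterns = c("B", "B"), shared = FALSE,
                      hgvsc = c("c.1029del", "c.1951G>A")),
    sim_gene_contrast("NIPSNAP3B", "chr9", families = "F3",
                      patterns = "A", shared = TRUE, hgvsc = "c.280G>C"))
  cohort_sim_config(genes = genes, n_background_variants = 12, seed = seed)
}
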