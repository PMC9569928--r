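#' Genotype- and site-level QC parameters for the association scan
#'
#' Thresholds follow common exome-GWAS practice: genotype calls are
#' masked on low genotype quality, low ploidy-appropriate depth, or an
#' out-of-range heterozygous allele fraction; whole sites are dropped on
#' low minor-allele frequency, high missingness, Hardy-Weinberg
#' disequilibrium, or a strongly negative inbreeding coefficient (an
#' excess-heterozygosity artifact guard). All inequalities are strict as
#' stated: e.g. GQ < 20 masks, MAF > 0.10 retains.
#'
#' @param gq_min genotype quality below which a call is masked (20).
#' @param dp_min_diploid,dp_min_haploid read-depth minima (10 / 5).
#' @param het_af_bounds inclusive allele-fraction band for heterozygous
#'   calls, default `c(0.2, 0.8)`.
#' @param inbreeding_min lowest acceptable per-site inbreeding
#'   coefficient F (-0.8).
#' @param maf_min minor allele frequency that must be exceeded (0.10).
#' @param missing_max missing rate that must not be reached (0.10).
#' @param hwe_min_p exact HWE p-value below which a site is excluded
#'   (1e-5).
#' @param alpha significance level for reporting (0.05).
#' @param male_x_dosage `"two"` (default) scores a hemizygous alternate
#'   male X call as two trend units (genotype class DD); `"one"` scores
#'   it as one.
#' @return object of class `assoc_params`.
#' @export
assoc_params <- function(gq_min = 20, dp_min_diploid = 10,
                         dp_min_haploid = 5, het_af_bounds = c(0.2, 0.8),
                         inbreeding_min = -0.8, maf_min = 0.10,
                         missing_max = 0.10, hwe_min_p = 1e-5,
                         alpha = 0.05, male_x_dosage = c("two", "one")) {
  stopifnot(length(het_af_bounds) == 2, het_af_bounds[1] < het_af_bounds[2],
            maf_min >= 0, maf_min <= 0.5, missing_max >= 0,
            missing_max <= 1, hwe_min_p > 0, hwe_min_p <= 1)
  structure(list(gq_min = gq_min, dp_min_diploid = dp_min_diploid,
                 dp_min_haploid = dp_min_haploid,
                 het_af_bounds = het_af_bounds,
                 inbreeding_min = inbreeding_min, maf_min = maf_min,
                 missing_max = missing_max, hwe_min_p = hwe_min_p,
                 alpha = alpha, male_x_dosage = match.arg(male_x_dosage)),
            class = "assoc_params")
}

#' Mask low-quality genotype calls
#'
#' Sets dosage to missing where GQ is below `gq_min`, depth is below the
#' ploidy-appropriate minimum (haploid for male X/Y calls, diploid
#' otherwise), or a heterozygous call's alternate-allele fraction falls
#' outside `het_af_bounds`. A quality metric that is itself missing never
#' masks a call. Already-missing dosages stay missing, so masking is
#' idempotent.
#'
#' @param cohort a [mito_cohort()].
#' @param params an [assoc_params()].
#' @return the cohort with masked dosage entries.
#' @export
apply_genotype_qc <- function(cohort, params = assoc_params()) {
  stopifnot(inherits(cohort, "mito_cohort"))
  d <- cohort$dosage
  hap <- outer(cohort$sites$chrom, cohort$samples$sex, is_haploid_call)
  dp_min <- ifelse(hap, params$dp_min_haploid, params$dp_min_diploid)
  low_gq <- !is.na(cohort$gq) & cohort$gq < params$gq_min
  low_dp <- !is.na(cohort$dp) & cohort$dp < dp_min
  het <- !is.na(d) & d == 1 & !hap
  bad_af <- het & !is.na(cohort$af) &
    (cohort$af < params$het_af_bounds[1] |
       cohort$af > params$het_af_bounds[2])
  d[low_gq | low_dp | bad_af] <- NA_integer_
  cohort$dosage <- d
  cohort
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Plain (not mid-p) two-sided exact conditional test: given the minor
#' allele count, the p-value is the sum of probabilities of all
#' heterozygote counts whose conditional probability does not exceed that
#' of the observed configuration. Probabilities are built by recurrence
#' from the distribution mode.
#'
#' @param hom_ref,het,hom_alt genotype counts.
#' @return list with `p` and `probs` (named vector of conditional
#'   probabilities over attainable heterozygote counts).
#' @export
hwe_exact_test <- function(hom_ref, het, hom_alt) {
  stopifnot(hom_ref >= 0, het >= 0, hom_alt >= 0)
  n <- hom_ref + het + hom_alt
  if (n == 0) stop("no genotypes")
  rare <- min(2 * hom_ref + het, 2 * hom_alt + het)
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  probs <- stats::setNames(numeric(length(hets)), hets)
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1
  probs[as.character(mid)] <- 1
  h <- mid  # downward recurrence: P(h-2) from P(h)
  while (h - 2 >= hets[1]) {
    probs[as.character(h - 2)] <- probs[as.character(h)] * h * (h - 1) /
      ((rare - h + 2) * (2 * n - rare - h + 2))
    h <- h - 2
  }
  h <- mid  # upward recurrence: P(h+2) from P(h)
  while (h + 2 <= hets[length(hets)]) {
    probs[as.character(h + 2)] <- probs[as.character(h)] *
      (rare - h) * (2 * n - rare - h) / ((h + 2) * (h + 1))
    h <- h + 2
  }
  probs <- probs / sum(probs)
  p_obs <- probs[as.character(het)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele count")
  list(p = min(1, sum(probs[probs <= p_obs * (1 + 1e-12)])), probs = probs)
}

#' Per-site statistics after genotype QC
#'
#' Minor allele frequency over non-missing alleles (haploid male X/Y
#' calls contribute one allele), missing rate over all cohort samples,
#' the site inbreeding coefficient F = 1 - observed-het/expected-het with
#' expected het = 2pqn over non-missing diploid samples, and the exact
#' HWE p-value from the diploid genotype counts. F is 0 for monomorphic
#' sites and the HWE p is 1 when fewer than two diploid genotypes remain.
#'
#' @param cohort a QC-masked [mito_cohort()].
#' @param i site row index.
#' @return list with `maf`, `missing_rate`, `hwe_p`, `inbreeding_f`, and
#'   the diploid genotype `counts` (hom_ref, het, hom_alt).
#' @export
site_stats <- function(cohort, i) {
  d <- cohort$dosage[i, ]
  hap <- is_haploid_call(cohort$sites$chrom[i], cohort$samples$sex)
  missing_rate <- mean(is.na(d))
  ok <- !is.na(d)
  if (!any(ok)) return(NULL)
  alleles <- ifelse(hap, 1, 2)[ok]
  alt <- sum(pmin(d[ok], alleles))
  af <- alt / sum(alleles)
  maf <- min(af, 1 - af)

  dd <- d[ok & !hap]
  counts <- c(hom_ref = sum(dd == 0), het = sum(dd == 1),
              hom_alt = sum(dd == 2))
  n <- sum(counts)
  if (n >= 1) {
    p <- (2 * counts[["hom_alt"]] + counts[["het"]]) / (2 * n)
    exp_het <- 2 * p * (1 - p) * n
    inbreeding_f <- if (exp_het > 0) 1 - counts[["het"]] / exp_het else 0
    hwe_p <- if (n >= 2)
      hwe_exact_test(counts[["hom_ref"]], counts[["het"]],
                     counts[["hom_alt"]])$p
    else 1
  } else {
    inbreeding_f <- 0; hwe_p <- 1
  }
  list(maf = maf, missing_rate = missing_rate, hwe_p = hwe_p,
       inbreeding_f = inbreeding_f, counts = counts)
}

#' Site retention decision from its QC statistics
#'
#' Retains a site iff MAF > `maf_min`, missing rate < `missing_max`,
#' exact HWE p >= `hwe_min_p`, and inbreeding F >= `inbreeding_min`
#' (all comparisons strict as written).
#'
#' @param stats a [site_stats()] result.
#' @param params an [assoc_params()].
#' @return logical.
#' @export
apply_site_filters <- function(stats, params = assoc_params()) {
  if (is.null(stats)) return(FALSE)
  stats$maf > params$maf_min &&
    stats$missing_rate < params$missing_max &&
    stats$hwe_p >= params$hwe_min_p &&
    stats$inbreeding_f >= params$inbreeding_min
}

#' Cochran-Armitage trend test on a 2x3 genotype table
#'
#' Tests for a dose trend in genotype frequencies between two groups,
#' scoring genotype classes dd/Dd/DD with weights 0/1/2 by default. The
#' two-sided p-value comes from the 1-df chi-square reference; the
#' statistic is 0 (p = 1) when genotype proportions are identical or the
#' table is degenerate.
#'
#' @param counts 2x3 integer matrix: rows = groups, columns = genotype
#'   classes in weight order.
#' @param weights genotype scores, default `c(0, 1, 2)`.
#' @return list of class `ca_trend` with `statistic` (1-df chi-square
#'   scale), `p`, and `counts`.
#' @export
ca_trend_test <- function(counts, weights = c(0, 1, 2)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2, ncol(counts) == length(weights),
            all(counts >= 0))
  n1 <- sum(counts[1, ]); n2 <- sum(counts[2, ])
  if (n1 < 1 || n2 < 1) stop("both groups need at least one genotype")
  N <- n1 + n2
  m <- colSums(counts)
  Tstat <- N * sum(weights * counts[1, ]) - n1 * sum(weights * m)
  Vt <- (n1 * n2 / N) *
    (N * sum(weights^2 * m) - sum(weights * m)^2)
  stat <- if (Vt > 0) Tstat^2 / Vt else 0
  res <- list(statistic = stat,
              p = if (stat == 0) 1 else
                stats::pchisq(stat, df = 1, lower.tail = FALSE),
              counts = counts)
  class(res) <- "ca_trend"
  res
}

#' @export
print.ca_trend <- function(x, ...) {
  cat("Cochran-Armitage trend test: chi-square =",
      format(x$statistic, digits = 4), ", df = 1, p =",
      format(x$p, digits = 4), "\n")
  invisible(x)
}

#' Genotype-association scan across all sites
#'
#' Applies genotype QC, per-site statistics and site filters, then runs
#' the Cochran-Armitage trend test proband-vs-control at every retained
#' site. Hemizygous male X calls are scored per
#' `assoc_params(male_x_dosage=)`. Sites where either group has no
#' non-missing call are skipped and logged.
#'
#' @param cohort a [mito_cohort()] (all sites, before genotype QC).
#' @param params an [assoc_params()].
#' @return list of class `assoc_scan`: `results` (retained sites with
#'   MAF, missingness, HWE p, F, trend statistic, raw p and BH-adjusted
#'   p, ordered by p) and `qc_log` (every site's statistics, retention
#'   flag and drop reason).
#' @export
run_association <- function(cohort, params = assoc_params()) {
  masked <- apply_genotype_qc(cohort, params)
  pro <- sample_ids(masked, "proband")
  ctl <- sample_ids(masked, "control")
  res <- list(); log <- list()
  for (i in seq_len(nrow(masked$sites))) {
    st <- site_stats(masked, i)
    keep <- apply_site_filters(st, params)
    reason <- if (is.null(st)) "all_missing"
      else if (!keep) "site_filter" else ""
    row <- data.frame(
      key = masked$sites$key[i], gene = masked$sites$gene[i],
      hgvsc = masked$sites$hgvsc[i],
      maf = if (is.null(st)) NA else st$maf,
      missing_rate = if (is.null(st)) 1 else st$missing_rate,
      hwe_p = if (is.null(st)) NA else st$hwe_p,
      inbreeding_f = if (is.null(st)) NA else st$inbreeding_f,
      stringsAsFactors = FALSE)
    if (keep) {
      cls <- function(ids) {
        d <- masked$dosage[i, ids]
        hap <- is_haploid_call(masked$sites$chrom[i],
                               masked$samples$sex[match(ids, masked$samples$sample_id)])
        d <- ifelse(hap & d == 1 & params$male_x_dosage == "two", 2, d)
        d <- d[!is.na(d)]
        c(sum(d == 0), sum(d == 1), sum(d == 2))
      }
      tab <- rbind(proband = cls(pro), control = cls(ctl))
      if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) {
        reason <- "empty_group"
      } else {
        ct <- ca_trend_test(tab)
        row$statistic <- ct$statistic
        row$p <- ct$p
        res[[length(res) + 1L]] <- row
      }
    }
    row$retained <- reason == ""
    row$reason <- reason
    log[[length(log) + 1L]] <- row[, c("key", "gene", "maf", "missing_rate",
                                       "hwe_p", "inbreeding_f", "retained",
                                       "reason")]
  }
  results <- do.call(rbind, res) %||%
    data.frame(key = character(), gene = character(), hgvsc = character(),
               maf = numeric(), missing_rate = numeric(), hwe_p = numeric(),
               inbreeding_f = numeric(), statistic = numeric(),
               p = numeric())
  if (nrow(results)) {
    results$p_adj <- stats::p.adjust(results$p, method = "BH")
    results <- results[order(results$p, results$key), , drop = FALSE]
  } else results$p_adj <- numeric()
  rownames(results) <- NULL
  qc_log <- do.call(rbind, log)
  rownames(qc_log) <- NULL
  structure(list(results = results, qc_log = qc_log, params = params),
            class = "assoc_scan")
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat("Association scan:", nrow(x$qc_log), "site(s),",
      nrow(x$results), "passed QC;",
      sum(x$results$p < x$params$alpha), "with p <", x$params$alpha, "\n")
  print(utils::head(x$results, 10), ...)
  invisible(x)
}
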