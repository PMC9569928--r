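test_that("genotype QC masks on the documented strict boundaries", {
  grp <- c("proband", "control")
  mk <- function(d, gq, dp, af, sex = c("female", "female"),
                 chrom = "chr7") {
    make_cohort(rbind(d), grp, sex = sex,
                sites = make_site(chrom = chrom),
                gq = rbind(gq), dp = rbind(dp), af = rbind(af))
  }
  qc <- function(co) unname(apply_genotype_qc(co)$dosage[1, ])
  # GQ: < 20 masks, exactly 20 survives
  expect_equal(qc(mk(c(1, 1), c(19, 20), c(30, 30), c(0.5, 0.5))),
               c(NA, 1L))
  # diploid depth: < 10 masks, exactly 10 survives
  expect_equal(qc(mk(c(1, 1), c(99, 99), c(9, 10), c(0.5, 0.5))),
               c(NA, 1L))
  # het allele fraction: outside [0.2, 0.8] masks, the bounds survive
  expect_equal(qc(mk(c(1, 1), c(99, 99), c(30, 30), c(0.19, 0.2))),
               c(NA, 1L))
  expect_equal(qc(mk(c(1, 1), c(99, 99), c(30, 30), c(0.8, 0.81))),
               c(1L, NA))
  # hom-alt calls are exempt from the AF band
  expect_equal(qc(mk(c(2, 2), c(99, 99), c(30, 30), c(0.95, 1))),
               c(2L, 2L))
  # haploid male X: depth 4 masks, 5 survives (diploid would need 10)
  expect_equal(qc(mk(c(1, 1), c(99, 99), c(4, 5), c(1, 1),
                     sex = c("male", "male"), chrom = "chrX")),
               c(NA, 1L))
  # a female X call stays diploid
  expect_equal(qc(mk(c(1, 1), c(99, 99), c(5, 10), c(0.5, 0.5),
                     sex = c("female", "female"), chrom = "chrX")),
               c(NA, 1L))
})

test_that("QC masking is idempotent and never alters surviving dosages", {
  set.seed(11)
  n <- 20
  co <- make_cohort(rbind(sample(0:2, n, TRUE), sample(0:2, n, TRUE)),
                    rep(c("proband", "control"), each = n / 2),
                    sites = rbind(make_site(pos = 1), make_site(pos = 2)),
                    gq = matrix(runif(2 * n, 0, 60), 2),
                    dp = matrix(runif(2 * n, 0, 30), 2),
                    af = matrix(runif(2 * n), 2))
  m1 <- apply_genotype_qc(co)
  m2 <- apply_genotype_qc(m1)
  expect_identical(m1$dosage, m2$dosage)
  kept <- !is.na(m1$dosage)
  expect_identical(m1$dosage[kept], co$dosage[kept])
})

test_that("exact HWE test matches the full-enumeration oracle", {
  # worked example: counts (1 hom-ref, 4 het, 0 hom-alt), n = 5
  expect_equal(hwe_exact_test(1, 4, 0)$p, 90 / 210)
  expect_equal(hwe_exact_test(1, 4, 0)$p, hwe_oracle(1, 4, 0))
  # single attainable configuration
  expect_equal(hwe_exact_test(0, 0, 10)$p, 1)
  expect_equal(hwe_exact_test(5, 0, 0)$p, 1)
  set.seed(21)
  for (i in 1:100) {
    n <- sample(2:25, 1)
    cnt <- as.vector(stats::rmultinom(1, n, runif(3) + 0.05))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3])$p,
                 hwe_oracle(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-12, info = paste(cnt, collapse = "/"))
  }
})

test_that("HWE conditional probabilities sum to one for n up to 50", {
  set.seed(22)
  for (i in 1:60) {
    n <- sample(2:50, 1)
    cnt <- as.vector(stats::rmultinom(1, n, runif(3) + 0.05))
    pr <- hwe_exact_test(cnt[1], cnt[2], cnt[3])$probs
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  }
})

test_that("site statistics: MAF folds, relabeling invariance, inbreeding F", {
  grp <- rep(c("proband", "control"), each = 5)
  co <- make_cohort(rbind(c(2, 2, 2, 1, 1, 0, 0, 0, 0, 0)), grp)
  st <- site_stats(co, 1)
  expect_equal(st$maf, min(8 / 20, 12 / 20))
  expect_equal(st$missing_rate, 0)
  # swapping ref/alt (dosage d -> 2 - d) leaves maf and hwe_p unchanged
  co2 <- make_cohort(rbind(2 - c(2, 2, 2, 1, 1, 0, 0, 0, 0, 0)), grp)
  st2 <- site_stats(co2, 1)
  expect_equal(st2$maf, st$maf)
  expect_equal(st2$hwe_p, st$hwe_p)
  # all-het site: F = 1 - 1/(2pq) with p = q = 0.5 -> -1
  coh <- make_cohort(rbind(rep(1, 10)), grp)
  expect_equal(site_stats(coh, 1)$inbreeding_f, -1)
  expect_false(apply_site_filters(site_stats(coh, 1), assoc_params()))
  # missing genotypes enter the missing rate, not the allele counts
  com <- make_cohort(rbind(c(NA, NA, 1, 1, 0, 0, 0, 0, 0, 0)), grp)
  stm <- site_stats(com, 1)
  expect_equal(stm$missing_rate, 0.2)
  expect_equal(stm$maf, 2 / 16)
})

test_that("site filters apply strict thresholds on every statistic", {
  base <- list(maf = 0.3, missing_rate = 0, hwe_p = 0.5, inbreeding_f = 0)
  with_field <- function(nm, v) { s <- base; s[[nm]] <- v; s }
  p <- assoc_params()
  expect_true(apply_site_filters(base, p))
  # MAF must exceed 0.10
  expect_false(apply_site_filters(with_field("maf", 0.10), p))
  expect_false(apply_site_filters(with_field("maf", 0.05), p))
  expect_true(apply_site_filters(with_field("maf", 0.1001), p))
  # missing rate must stay below 0.10
  expect_false(apply_site_filters(with_field("missing_rate", 0.10), p))
  expect_true(apply_site_filters(with_field("missing_rate", 0.0999), p))
  # HWE p below 1e-5 excludes; exactly 1e-5 is retained
  expect_false(apply_site_filters(with_field("hwe_p", 1e-6), p))
  expect_true(apply_site_filters(with_field("hwe_p", 1e-5), p))
  # inbreeding F below -0.8 excludes; exactly -0.8 is retained
  expect_false(apply_site_filters(with_field("inbreeding_f", -0.81), p))
  expect_true(apply_site_filters(with_field("inbreeding_f", -0.8), p))
})

test_that("trend statistic: null tables, symmetry, affine weight invariance", {
  # identical genotype proportions
  t0 <- rbind(c(2, 4, 1), c(4, 8, 2))
  ct <- ca_trend_test(t0)
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p, 1)
  # swapping the group rows leaves the statistic unchanged
  t1 <- rbind(c(1, 2, 4), c(6, 3, 1))
  expect_equal(ca_trend_test(t1[2:1, ])$statistic,
               ca_trend_test(t1)$statistic)
  # affine weight transforms w -> a w + b (a > 0) are irrelevant
  for (ab in list(c(2, 0), c(1, 5), c(0.3, -2))) {
    expect_equal(ca_trend_test(t1, weights = ab[1] * (0:2) + ab[2])$statistic,
                 ca_trend_test(t1)$statistic, tolerance = 1e-12)
  }
  # degenerate single-column table
  expect_equal(ca_trend_test(rbind(c(0, 5, 0), c(0, 9, 0)))$p, 1)
})

test_that("trend test agrees with the independent base-R implementation", {
  set.seed(31)
  for (i in 1:25) {
    tab <- rbind(as.vector(stats::rmultinom(1, 7, runif(3) + 0.1)),
                 as.vector(stats::rmultinom(1, 10, runif(3) + 0.1)))
    if (sum(colSums(tab) > 0) < 2) next
    ct <- ca_trend_test(tab)
    pt <- suppressWarnings(stats::prop.trend.test(tab[1, ], colSums(tab),
                                                  score = 0:2))
    expect_equal(ct$statistic, unname(pt$statistic), tolerance = 1e-10)
    if (ct$statistic > 0)
      expect_equal(ct$p, pt$p.value, tolerance = 1e-10)
  }
})

test_that("asymptotic trend p approaches the permutation p at large n", {
  set.seed(32)
  for (i in 1:4) {
    p1 <- runif(1, 0.2, 0.5); p2 <- runif(1, 0.2, 0.5)
    tab <- rbind(tabulate(stats::rbinom(140, 2, p1) + 1, 3),
                 tabulate(stats::rbinom(200, 2, p2) + 1, 3))
    pa <- ca_trend_test(tab)$p
    pp <- perm_trend_p(tab, B = 2000)
    se <- max(sqrt(pp * (1 - pp) / 2000), 1 / 2000)
    expect_lt(abs(pa - pp), 3 * se + 0.01)
  }
})

test_that("association scan masks, filters and scores hemizygous males", {
  # autosomal site with a clean dose trend plus an X site with male calls
  groups <- rep(c("proband", "control"), c(7, 10))
  sex <- rep(c("male", "female"), c(8, 9))
  sites <- rbind(make_site(pos = 1, chrom = "chr2"),
                 make_site(pos = 1, chrom = "chrX"))
  d <- rbind(c(2, 2, 2, 1, 1, 1, 1, rep(0, 5), rep(1, 5)),
             c(rep(1, 8), rep(0, 4), rep(1, 5)))
  co <- make_cohort(d, groups, sex = sex, sites = sites)
  scan <- run_association(co)
  expect_equal(nrow(scan$qc_log), 2)
  res2 <- run_association(co, assoc_params(male_x_dosage = "one"))
  xkey <- "chrX:1:A:G"
  if (xkey %in% scan$results$key && xkey %in% res2$results$key) {
    st2 <- scan$results$statistic[scan$results$key == xkey]
    st1 <- res2$results$statistic[res2$results$key == xkey]
    expect_false(isTRUE(all.equal(st1, st2)))
  }
  # BH column never below the raw p
  expect_true(all(scan$results$p_adj >= scan$results$p - 1e-12))
})
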