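universe <- make_universe(c("GENE1", "GENE2", "AK4"))

classify_one <- function(site, params = filter_params(), univ = universe) {
  site$key <- with(site, paste(chrom, pos, ref, alt, sep = ":"))
  classify_variants(site, univ, params)
}

test_that("cascade decisions follow the documented order and reasons", {
  cases <- list(
    # high-CADD missense in a universe gene is retained
    list(make_site(cadd = 25.1), TRUE, "retained_missense"),
    # synonymous excluded regardless of score
    list(make_site(consequence = "synonymous_variant", cadd = 30),
         FALSE, "excluded_consequence"),
    # ClinVar likely-benign beats a qualifying score
    list(make_site(clinvar = "Likely_benign", cadd = 30),
         FALSE, "clinvar_benign"),
    # composite ClinVar strings count as benign
    list(make_site(clinvar = "Benign/Likely_benign", cadd = 30),
         FALSE, "clinvar_benign"),
    # loss-of-function bypasses the score gate under the default scope
    list(make_site(consequence = "stop_gained", cadd = 5),
         TRUE, "retained_lof"),
    list(make_site(consequence = "frameshift_variant", cadd = NA),
         TRUE, "retained_lof"),
    # gene outside the universe loses first
    list(make_site(gene = "NOTMT", cadd = 30), FALSE, "not_in_universe"),
    # missense below both score thresholds fails the gate
    list(make_site(cadd = 19.9, revel = 0.4), FALSE, "score_gate_failed"),
    # either score above its threshold passes (OR gate)
    list(make_site(cadd = 5, revel = 0.51), TRUE, "retained_missense"),
    # both scores missing fails; one informative score decides
    list(make_site(cadd = NA, revel = NA), FALSE, "score_gate_failed"),
    list(make_site(cadd = NA, revel = 0.6), TRUE, "retained_missense"),
    # mixed consequence set judged by its included (more severe) term
    list(make_site(consequence = "missense_variant&intron_variant",
                   cadd = 25), TRUE, "retained_missense"),
    # UTR/intron-only terms are excluded
    list(make_site(consequence = "5_prime_UTR_variant"),
         FALSE, "excluded_consequence"),
    list(make_site(consequence = "intron_variant"),
         FALSE, "excluded_consequence"))
  for (cs in cases) {
    d <- classify_one(cs[[1]])
    expect_equal(d$retained, cs[[2]], info = cs[[1]]$consequence)
    expect_equal(d$reason, cs[[3]], info = paste(cs[[1]], collapse = " "))
  }
})

test_that("thresholds are strict and the score-gate scope is configurable", {
  # strict inequalities: exactly 20 / exactly 0.5 fail
  expect_false(classify_one(make_site(cadd = 20, revel = NA))$retained)
  expect_false(classify_one(make_site(cadd = NA, revel = 0.5))$retained)
  expect_true(classify_one(make_site(cadd = 20.001))$retained)
  # scope "all": LoF must also clear the gate
  p_all <- filter_params(score_gate_scope = "all")
  d <- classify_one(make_site(consequence = "stop_gained", cadd = 5), p_all)
  expect_equal(d$reason, "score_gate_failed")
  expect_true(classify_one(make_site(consequence = "stop_gained", cadd = 30),
                           p_all)$retained)
  # scope "off": sub-threshold missense passes
  p_off <- filter_params(score_gate_scope = "off")
  expect_true(classify_one(make_site(cadd = 5), p_off)$retained)
})

test_that("cascade counts are conserved and the cascade is idempotent", {
  sim <- generate_cohort(table2_fixture(seed = 5))
  univ <- make_universe(sim$universe_genes)
  casc <- apply_cascade(sim$cohort, univ)
  expect_equal(sum(casc$counts), nrow(sim$cohort$sites))
  expect_setequal(casc$decisions$reason[casc$decisions$retained],
                  c("retained_missense"))
  # re-applying to the qualifying subset changes nothing
  casc2 <- apply_cascade(casc$qualifying, univ)
  expect_equal(casc2$qualifying$sites$key, casc$qualifying$sites$key)
  expect_equal(sum(casc2$counts), nrow(casc$qualifying$sites))
  # empty input
  empty <- subset_sites(sim$cohort, integer())
  casc0 <- apply_cascade(empty, univ)
  expect_equal(sum(casc0$counts), 0)
  expect_equal(nrow(casc0$qualifying$sites), 0)
})

test_that("raising score thresholds never enlarges the qualifying set", {
  sim <- generate_cohort(table2_fixture(seed = 6))
  univ <- make_universe(sim$universe_genes)
  prev <- NULL
  for (cadd_min in c(5, 15, 20, 25, 40)) {
    q <- apply_cascade(sim$cohort, univ,
                       filter_params(cadd_min = cadd_min))$qualifying
    if (!is.null(prev)) expect_true(all(q$sites$key %in% prev))
    prev <- q$sites$key
  }
  prev <- NULL
  for (revel_min in c(0.05, 0.3, 0.8)) {
    q <- apply_cascade(sim$cohort, univ,
                       filter_params(revel_min = revel_min,
                                     cadd_min = 1e6))$qualifying
    if (!is.null(prev)) expect_true(all(q$sites$key %in% prev))
    prev <- q$sites$key
  }
})
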