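---
title: "Methods: screening nuclear modifier genes in multi-family exome cohorts"
author: "mitomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening nuclear modifier genes in multi-family exome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomod)
```

## The problem and the design

Leber's hereditary optic neuropathy (LHON) is maternally transmitted
through mitochondrial DNA point mutations, but most carriers never develop
optic neuropathy. The leading explanation for this incomplete penetrance is
modification by nuclear-encoded genes. `mitomod` implements a screening
strategy suited to the data such studies actually have: a handful of
families in which both affected probands and unaffected carrier relatives
were exome sequenced. Because cases and controls share family background,
crude population-stratification artifacts are damped, at the price of
non-independent samples and very small n. The pipeline is therefore a
*candidate screen* — a deterministic filtering and contrast machinery plus
simple association statistics — not an inferential fine-mapping method.

Five analysis stages run in a fixed order: gene-universe construction,
variant qualification, then (on the qualifying set) gene burden and
family-based contrasts, an association scan on all sites, and pathway
over-representation of the burden candidates.

## Gene universe and variant qualification

The analysis is deliberately restricted to nuclear genes with
mitochondria-related function, supplied as two plain-text symbol lists
(typically a curated mitochondrial canonical-pathway list and a
MitoCarta-style inventory). `read_gene_universe()` upper-cases, dedupes and
unions them; no alias reconciliation is attempted, because symbol-alias
mapping would require a reference the input lists do not carry, and a
false merge is worse for a screen than a duplicate.

`classify_variants()` applies one decision per variant, in a fixed order
that makes the per-reason counts interpretable as a funnel: universe
membership, consequence exclusion (UTR / intron / synonymous), ClinVar
benign exclusion, consequence inclusion, deleteriousness gate. Two
vocabulary decisions matter:

* A variant annotated with both an excluded and an included consequence
  (e.g. `missense_variant&intron_variant` from overlapping transcripts) is
  judged by its most severe, i.e. included, term.
* ClinVar matching is substring-based and case-insensitive, so composite
  significance strings such as `Benign/Likely_benign` are excluded.

The deleteriousness gate retains missense variants when CADD Phred > 20
**or** REVEL > 0.5, both strict. The disjunctive reading and the
`missense_only` default scope (`filter_params(score_gate_scope=)`) follow
from how these scores are defined: REVEL only scores missense variants, so
gating loss-of-function classes on it would empty them; those classes
qualify on their consequence alone. A conjunctive or an all-classes gate is
available (`"all"`, `"off"`) for sensitivity analysis. When both scores are
missing the gate fails — an unscored missense variant carries no evidence
of deleteriousness.

## Gene burden: the affected sample rate

For a gene g and group G the burden statistic is

$$ r_g(G) = \frac{\#\{s \in G : s \text{ carries} \ge 1 \text{ qualifying
variant of } g\}}{|G|}, $$

with carriage meaning dosage ≥ 1 — heterozygous and homozygous carriers
count equally, and a sample with several qualifying variants of one gene
counts once. Missing genotypes count as non-carriers against the full
group denominator; with 7 probands and 10 controls this makes every
reportable rate an exact multiple of 1/7 or 1/10, which is also why the
package reports rates rounded to two decimals. Candidate genes are those
with |proband − control rate difference| at or above 0.30 *after* rounding
half-away-from-zero; selection on rounded values keeps boundary genes
whose unrounded difference is, say, 0.2957. The 0.30 default is a
screening knob, not a significance threshold: at these group sizes it
yields a shortlist of roughly ten genes, and no variance estimate is
attached to the difference by design.

## Family-based contrasts and concurrence

Within each family, `family_contrasts()` looks for a dose effect between
probands and the family's carrier controls at each qualifying variant. Two
patterns are accepted by default: proband homozygous-alternate vs control
heterozygous (2 vs 1), and proband heterozygous vs control
homozygous-reference (1 vs 0). Because families may have several controls,
the proband is compared against the **maximum** control dosage — the
strictest reading, requiring the proband to exceed every control; an
any-pair mode is provided. The closed pattern set deliberately excludes a
(2, 0) jump; a relaxed any-strict-excess mode admits it when wanted.
Families lacking a control, or with missing calls at the variant, are
uninformative and skipped (the no-control case with a warning).

`concurrence_report()` counts, per variant key (chrom:pos:ref:alt), the
families showing a contrast, and reports keys with count ≥ 2. Since a gene
can be hit through different variants in different families, a gene-level
table counts distinct families contrasting *any* variant of the gene;
such split-variant genes are reported there rather than being silently
merged into variant counts.

## Association scan

Genotype-level QC masks calls with GQ < 20, depth below 10 (diploid) or 5
(haploid: male X and Y calls), or a heterozygous allele fraction outside
[0.2, 0.8]; a metric that is itself absent never masks. Site-level QC then
requires MAF > 0.10, missing rate < 0.10, exact Hardy–Weinberg p ≥ 1e−5,
and a site inbreeding coefficient F = 1 − obs-het/exp-het (expected het
2pqn over non-missing diploids) of at least −0.8 — the F floor guards
against excess-heterozygosity artifacts. All inequalities are applied
strictly as written; the boundary value itself always survives a "<"
exclusion rule.

The exact HWE test is the plain (not mid-p) two-sided conditional test:
probabilities of all heterozygote counts compatible with the observed
minor-allele count are built by recurrence from the distribution mode
(numerically stable for any n here), normalised, and summed over
configurations no more probable than the observed one (with a 1 + 1e−12
tie guard). Monomorphic sites have a single attainable configuration and
p = 1; sites with fewer than two diploid genotypes skip the test.

Retained sites get the Cochran–Armitage trend test with scores 0/1/2,
two-sided p from the 1-df chi-square reference, and statistic 0 / p 1 for
identical group proportions or degenerate single-class tables. Hemizygous
male X alternate calls score as two trend units by default (an allele-dose
reading; `male_x_dosage = "one"` gives the genotype-class reading). Raw p
against α = 0.05 is the headline column, with BH-adjusted values emitted
alongside. Two caveats are inherent to the design and reproduced, not
endorsed: relatives are tested without kinship correction, and at 17
samples the chi-square reference is an approximation — the test suite
shows the statistic agrees exactly with an independent implementation and
that the asymptotic p converges to a label-permutation p at large n
(groups of 140/200), but at n = 17 the permutation distribution is
coarsely discrete and the two p-values can differ by several hundredths.

## Pathway over-representation

`ora_test()` is the upper-tail hypergeometric probability
$P(X \ge k)$ for k of n candidates falling in a K-gene pathway within an
N-gene background, adjusted across pathways by Benjamini–Hochberg.
The default background is the union of all genes in the loaded GMT —
the choice that makes a self-contained analysis reproducible — and can be
switched to the mitochondrial gene universe. Absolute adjusted p-values
depend strongly on the pathway-database release, so cross-study
comparisons should be made on overlap sets, not p-values. Note that
re-adjusting already-adjusted values is not a no-op for step-up BH except
in fully tied cases; the package treats adjustment as a one-shot
transformation of raw p-values.

## The synthetic cohort generator

`generate_cohort()` exists because family-level exome genotypes are
protected data; it emulates the *statistical structure* the pipeline
assumes, so that every stage is testable end to end. The default design
mirrors the motivating study scale: 5 families, 7 probands (6/7 male) and
10 carrier controls (2/10 male). Three planting modes map one-to-one onto
the signals the stages detect: group-differential carrier rates (burden),
intra-family dose contrasts of both patterns, shared or split across
variants (family analysis), and equal-rate null genes. Background variants
cycle through the disqualifying annotation classes so the cascade funnel
is exercised. In exact-count mode, carrier counts equal
round(rate × group size) for every seed — carrier identity, not number, is
random — which is what lets the bundled `table2_fixture()` reproduce its
ten (control rate, proband rate, difference) triples deterministically.
Planted calls receive GQ ∈ [30, 100), DP ∈ [20, 60) and heterozygous
allele fractions in [0.35, 0.65], inside all QC boundaries by
construction.

What the simulator does **not** model: linkage disequilibrium,
recombination, realistic site-frequency spectra, mtDNA heteroplasmy, and
read-level errors. Passing tests on these cohorts therefore demonstrate
the correctness of the decision logic and statistics, not the power or
error rates to expect on real exomes. The one calibration-style check is
deliberately simple: a planted modifier (carrier rates 0.9/0.2) among 99
balanced null genes ranks in the burden top 5 in ≥ 80% of 20 seeded
replicates at study-scale group sizes.

## Numerical and interface choices

* Rounding is half-away-from-zero (with an epsilon guard against binary
  representation of exact halves), because reported rates are
  human-facing decimals and banker's rounding would surprise.
* Variant identity is `(chrom, pos, ref, alt)` with 1-based VCF
  coordinates; multi-allelic records are split into bi-allelic entries at
  read time and never re-merged.
* Annotations travel in a single pipe-delimited INFO field whose
  sub-field names are declared in the header `Format:` line and remappable
  via `ann_field_map()`, decoupling the pipeline from any specific
  annotation tool.
* Burden rows sort by |difference| descending with alphabetical
  tie-break; concurrence rows by count then gene; association rows by p.
  All table writers emit plain TSV, and `run_pipeline()` adds a JSON run
  report with input MD5 digests, per-stage counts and the full parameter
  snapshot, so a run is auditable from its output directory alone.
* Test-suite problem sizes are chosen to keep the full suite under a
  minute on one core: exhaustive HWE checks to n ≤ 25 (distribution
  propriety spot-checked to n = 50), exhaustive ORA designs to N = 12,
  permutation comparisons at B = 2000, and law-of-large-numbers checks on
  10,000-member groups.

## Known limitations

* No kinship or population-structure correction anywhere — faithful to
  the screening design, but p-values from related samples are optimistic.
* No gene-symbol alias harmonisation between universe sources.
* The burden difference has no attached uncertainty; it is a ranking
  statistic.
* The family filter is a deterministic pattern match, not a segregation
  test; it cannot weigh pedigree structure or phase.
* Annotation consumption only: the package never computes consequences or
  scores, so its decisions are only as good as the upstream annotation.
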