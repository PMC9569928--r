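test_that("PED parsing maps sex and phenotype codes and drops odd rows", {
  ped <- tempfile(fileext = ".ped")
  writeLines(c("F1\tS1\t0\t0\t1\t2",
               "F1\tS2\t0\t0\t2\t1",
               "F2\tS3\t0\t0\t0\t1",
               "F2\tS4\t0\t0\t1\t-9"), ped)
  expect_warning(tab <- read_ped(ped), "phenotype")
  expect_equal(tab$sample_id, c("S1", "S2", "S3"))
  expect_equal(tab$group, c("proband", "control", "control"))
  expect_equal(tab$sex, c("male", "female", "unknown"))
})

test_that("gene universe is an upper-cased, order-insensitive, idempotent union", {
  a <- tempfile(); b <- tempfile()
  writeLines(c("ak4", "NSUN4", "Coq3"), a)
  writeLines(c("COQ3", "rdh13"), b)
  u <- read_gene_universe(c(mt = a, carta = b))
  expect_equal(u$genes, c("AK4", "COQ3", "NSUN4", "RDH13"))
  expect_equal(unname(u$source_counts), c(3L, 2L))
  # order-insensitive and idempotent
  expect_equal(read_gene_universe(c(b, a))$genes, u$genes)
  expect_equal(read_gene_universe(c(a, a))$genes,
               read_gene_universe(a)$genes)
  # disjoint lists just concatenate
  writeLines("ZZZ1", a); writeLines("ZZZ2", b)
  expect_equal(read_gene_universe(c(a, b))$genes, c("ZZZ1", "ZZZ2"))
})

test_that("universe of two overlapping source lists has the union size", {
  # 838- and 1135-symbol lists sharing 700 symbols must union to 1273
  shared <- sprintf("SH%04d", 1:700)
  a <- tempfile(); b <- tempfile()
  writeLines(c(shared, sprintf("A%04d", 1:138)), a)
  writeLines(c(shared, sprintf("B%04d", 1:435)), b)
  u <- read_gene_universe(c(a, b))
  expect_length(u$genes, 1273)
  expect_equal(unname(u$source_counts), c(838L, 1135L))
})

test_that("GMT parsing deduplicates genes and skips short lines", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("pw1\tfirst pathway\tA\tB\tC",
               "pw2\tsecond\tD\tE\tF\tG\tH",
               "bad_line\tonly-two-fields",
               "pw3\tdup genes\tX\tX\tY"), gmt)
  expect_warning(pc <- read_gmt(gmt), "fewer than 3")
  expect_length(pc, 3)
  expect_equal(pc$pw3$genes, c("X", "Y"))
  expect_length(pc$pw2$genes, 5)
  # empty file: empty collection, enrichment refuses downstream
  empty <- tempfile(); writeLines(character(), empty)
  pc0 <- read_gmt(empty)
  expect_length(pc0, 0)
  expect_error(run_enrichment("A", pc0), "empty pathway collection")
})

test_that("cohort round-trips through VCF write and read", {
  sim <- generate_cohort(table2_fixture(seed = 11), dir = tempdir())
  co <- read_cohort(sim$paths$vcf, sim$paths$ped)
  orig <- sim$cohort
  expect_equal(co$sites$key, orig$sites$key)
  expect_equal(unname(co$dosage), unname(orig$dosage))
  expect_equal(co$sites$gene, orig$sites$gene)
  expect_equal(co$sites$consequence, orig$sites$consequence)
  expect_equal(co$sites$cadd, orig$sites$cadd)
  expect_equal(co$sites$revel, orig$sites$revel)
  expect_equal(co$sites$clinvar, orig$sites$clinvar)
  expect_equal(unname(co$af), unname(orig$af))
  expect_equal(co$samples, orig$samples, ignore_attr = TRUE)
  # writing the re-read cohort again reproduces the file byte for byte
  v2 <- tempfile(fileext = ".vcf")
  write_cohort_vcf(co, v2)
  expect_identical(readLines(v2), readLines(sim$paths$vcf))
})

test_that("multi-allelic records split into per-alt entries", {
  dir <- tempfile(); dir.create(dir)
  vcf <- file.path(dir, "m.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description="x. ',
           'Format: Allele|SYMBOL|Consequence|ClinVar|CADD_PHRED|REVEL|HGVSc">'),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    paste0("chr1\t500\t.\tA\tG,T\t.\tPASS\t",
           "CSQ=G|GENE1|missense_variant|.|25|.|.,",
           "T|GENE1|synonymous_variant|.|.|.|.\tGT\t1/2\t0/1"),
    "chr1\t900\t.\tC\tT\t.\tPASS\tCSQ=T|GENE2|stop_gained|.|.|.|.\tGT\t./.\t1/1"),
    vcf)
  ped <- file.path(dir, "m.ped")
  writeLines(c("F1\tS1\t0\t0\t1\t2", "F1\tS2\t0\t0\t2\t1"), ped)
  co <- read_cohort(vcf, ped)
  expect_equal(nrow(co$sites), 3)
  expect_equal(co$sites$alt[1:2], c("G", "T"))
  expect_equal(co$sites$consequence[1:2],
               c("missense_variant", "synonymous_variant"))
  # GT 1/2 means one copy of each alt; S2 0/1 carries alt G only
  expect_equal(unname(co$dosage["chr1:500:A:G", ]), c(1L, 1L))
  expect_equal(unname(co$dosage["chr1:500:A:T", ]), c(1L, 0L))
  # missing genotype preserved as missing
  expect_true(is.na(co$dosage["chr1:900:C:T", "S1"]))
  expect_equal(unname(co$dosage["chr1:900:C:T", "S2"]), 2L)
})

test_that("sample intersection rules: drop with warning, fatal on no overlap", {
  sim <- generate_cohort(table2_fixture(seed = 12), dir = tempdir())
  ped2 <- tempfile(fileext = ".ped")
  writeLines(c(readLines(sim$paths$ped), "F9\tGHOST\t0\t0\t1\t2"), ped2)
  expect_warning(co <- read_cohort(sim$paths$vcf, ped2), "GHOST")
  expect_equal(nrow(co$samples), 17)
  writeLines(c("F9\tGHOST\t0\t0\t1\t2"), ped2)
  expect_error(read_cohort(sim$paths$vcf, ped2), "no overlap")
})

test_that("records with malformed annotation are skipped and counted", {
  dir <- tempfile(); dir.create(dir)
  vcf <- file.path(dir, "bad.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description="x. ',
           'Format: Allele|SYMBOL|Consequence|ClinVar|CADD_PHRED|REVEL|HGVSc">'),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tG\t.\tPASS\tCSQ=G|GENE1|missense_variant|.|25|.|.\tGT\t0/1",
    "chr1\t200\t.\tA\tG\t.\tPASS\tDP=5\tGT\t0/1"), vcf)
  ped <- file.path(dir, "bad.ped")
  writeLines("F1\tS1\t0\t0\t1\t2", ped)
  expect_warning(co <- read_cohort(vcf, ped), "malformed")
  expect_equal(nrow(co$sites), 1)
  expect_equal(attr(co, "skipped"), "chr1:200:A:G")
})
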