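#' Default annotation sub-field map
#'
#' Names the sub-fields of the pipe-delimited per-consequence annotation
#' string (VEP-CSQ dialect) that the pipeline consumes. Override entries to
#' match the annotation tool that produced the VCF.
#'
#' @param allele,gene,consequence,clinvar,cadd,revel,hgvsc sub-field names
#'   as they appear in the `Format:` declaration of the INFO header line.
#' @return named character vector used by [read_cohort()].
#' @export
ann_field_map <- function(allele = "Allele", gene = "SYMBOL",
                          consequence = "Consequence", clinvar = "ClinVar",
                          cadd = "CADD_PHRED", revel = "REVEL",
                          hgvsc = "HGVSc") {
  c(allele = allele, gene = gene, consequence = consequence,
    clinvar = clinvar, cadd = cadd, revel = revel, hgvsc = hgvsc)
}

#' Read a PED-style pedigree/phenotype file
#'
#' Six whitespace-separated columns: family ID, sample ID, father, mother,
#' sex (1 = male, 2 = female, 0 = unknown), phenotype (2 = proband,
#' 1 = unaffected carrier control). Rows with any other phenotype code are
#' dropped with a warning.
#'
#' @param path PED file path.
#' @return data.frame with columns `sample_id`, `family_id`, `group`, `sex`.
#' @export
read_ped <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(ped) < 6) stop("PED file must have >= 6 columns: ", path)
  ped <- ped[, 1:6]
  names(ped) <- c("family_id", "sample_id", "father", "mother", "sex", "pheno")
  bad <- !(ped$pheno %in% c(1, 2))
  if (any(bad)) {
    warning(sum(bad), " PED row(s) with phenotype outside {1,2} dropped")
    ped <- ped[!bad, , drop = FALSE]
  }
  data.frame(
    sample_id = as.character(ped$sample_id),
    family_id = as.character(ped$family_id),
    group = ifelse(ped$pheno == 2, "proband", "control"),
    sex = c("unknown", "male", "female")[match(ped$sex, c(0, 1, 2),
                                               nomatch = 1)],
    stringsAsFactors = FALSE)
}

## Format: declaration of the pipe-delimited annotation INFO field
csq_format <- function(meta, field) {
  line <- grep(sprintf("^##INFO=<ID=%s[,>]", field), meta, value = TRUE)
  if (!length(line)) return(NULL)
  m <- regmatches(line[1], regexpr('Format: ?[^"]+', line[1]))
  if (!length(m)) return(NULL)
  strsplit(trimws(sub("^Format: ?", "", m)), "|", fixed = TRUE)[[1]]
}

parse_num <- function(x) suppressWarnings(as.numeric(x))

## Split one raw CSQ string into a per-allele annotation lookup.
## Returns a function(alt) -> named list or NULL when no entry matches.
csq_lookup <- function(raw, fmt, map) {
  if (is_missing_chr(raw)) return(function(alt) NULL)
  entries <- strsplit(strsplit(raw, ",", fixed = TRUE)[[1]], "|", fixed = TRUE)
  idx <- function(nm) match(map[[nm]], fmt)
  grab <- function(e, nm) {
    i <- idx(nm)
    if (is.na(i) || i > length(e) || is_missing_chr(e[i])) NA_character_
    else e[i]
  }
  function(alt) {
    ai <- idx("allele")
    hit <- if (is.na(ai)) entries else {
      alle <- vapply(entries, function(e)
        if (ai <= length(e)) e[ai] else NA_character_, character(1))
      entries[!is.na(alle) & alle == alt]
    }
    if (!length(hit)) hit <- entries  # single shared annotation fallback
    if (!length(hit)) return(NULL)
    e <- hit[[1]]
    list(gene = grab(e, "gene"),
         consequence = grab(e, "consequence"),
         clinvar = grab(e, "clinvar"),
         cadd = parse_num(grab(e, "cadd")),
         revel = parse_num(grab(e, "revel")),
         hgvsc = grab(e, "hgvsc"))
  }
}

## alternate-allele dosage of one GT string for allele number `allele_idx`
gt_dosage <- function(gt, allele_idx) {
  if (is_missing_chr(gt)) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(alleles == as.character(allele_idx))
}

#' Read an annotated multi-sample VCF plus pedigree into a cohort
#'
#' Restricts to samples present in both files, splits multi-allelic records
#' into one bi-allelic entry per alternate allele, and pulls the per-variant
#' annotation (gene symbol, consequence terms, ClinVar significance,
#' CADD Phred, REVEL, HGVSc) out of a pipe-delimited INFO field. Genotype
#' dosage, GQ, DP and alternate-allele fraction are taken from the FORMAT
#' fields `GT`, `GQ`, `DP` and `AF` (AF falls back to `AD` alt/total when
#' absent). Records whose annotation cannot be parsed are skipped and
#' counted.
#'
#' @param vcf_path VCF 4.2 file (plain or bgzipped).
#' @param ped_path PED file, see [read_ped()].
#' @param ann_field INFO key carrying the annotation (default `"CSQ"`).
#' @param ann_map sub-field name map, see [ann_field_map()].
#' @return a [mito_cohort()]; attribute `"skipped"` holds the keys of
#'   records dropped for malformed annotation.
#' @export
read_cohort <- function(vcf_path, ped_path, ann_field = "CSQ",
                        ann_map = ann_field_map()) {
  ped <- read_ped(ped_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  vcf_samples <- colnames(vcf@gt)[-1]

  keep <- intersect(ped$sample_id, vcf_samples)
  if (!length(keep))
    stop("no overlap between VCF samples and PED sample IDs")
  if (length(drop <- setdiff(ped$sample_id, vcf_samples)))
    warning("PED sample(s) absent from VCF dropped: ",
            paste(drop, collapse = ", "))
  samples <- ped[match(keep, ped$sample_id), , drop = FALSE]

  fix <- vcf@fix
  fmt <- csq_format(vcf@meta, ann_field)
  info_raw <- vcfR::extract.info(vcf, ann_field)
  gt <- vcfR::extract.gt(vcf, "GT")[, keep, drop = FALSE]
  gq <- suppressWarnings(vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE))
  af_chr <- tryCatch(vcfR::extract.gt(vcf, "AF"), error = function(e) NULL)
  ad_chr <- tryCatch(vcfR::extract.gt(vcf, "AD"), error = function(e) NULL)
  pick <- function(m) if (is.null(m)) NULL else m[, keep, drop = FALSE]
  gq <- pick(gq); dp <- pick(dp); af_chr <- pick(af_chr); ad_chr <- pick(ad_chr)

  rows <- list(); skipped <- character()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    lookup <- csq_lookup(if (is.null(fmt)) NA else info_raw[r], fmt, ann_map)
    for (a in seq_along(alts)) {
      key_r <- variant_key(fix[r, "CHROM"], fix[r, "POS"], fix[r, "REF"],
                           alts[a])
      ann <- lookup(alts[a])
      if (is.null(ann) || is.na(ann$consequence)) {
        warning("record ", key_r, " skipped: malformed or missing annotation")
        skipped <- c(skipped, key_r)
        next
      }
      dos <- vapply(gt[r, ], gt_dosage, integer(1), allele_idx = a)
      afv <- rep(NA_real_, length(keep))
      if (!is.null(af_chr)) {
        afv <- vapply(af_chr[r, ], function(x) {
          if (is_missing_chr(x)) return(NA_real_)
          v <- parse_num(strsplit(x, ",", fixed = TRUE)[[1]])
          if (length(v) >= a) v[a] else v[1]
        }, numeric(1))
      } else if (!is.null(ad_chr)) {
        afv <- vapply(ad_chr[r, ], function(x) {
          if (is_missing_chr(x)) return(NA_real_)
          v <- parse_num(strsplit(x, ",", fixed = TRUE)[[1]])
          if (length(v) < a + 1 || sum(v, na.rm = TRUE) == 0) return(NA_real_)
          v[a + 1] / sum(v, na.rm = TRUE)
        }, numeric(1))
      }
      rows[[key_r]] <- list(
        site = data.frame(chrom = fix[r, "CHROM"],
                          pos = as.integer(fix[r, "POS"]),
                          ref = fix[r, "REF"], alt = alts[a],
                          gene = ann$gene, consequence = ann$consequence,
                          clinvar = ann$clinvar, cadd = ann$cadd,
                          revel = ann$revel, hgvsc = ann$hgvsc,
                          stringsAsFactors = FALSE),
        dosage = dos,
        gq = if (is.null(gq)) rep(NA_real_, length(keep)) else gq[r, ],
        dp = if (is.null(dp)) rep(NA_real_, length(keep)) else dp[r, ],
        af = afv)
    }
  }
  if (length(skipped))
    message(length(skipped), " record(s) skipped for malformed annotation")
  if (!length(rows)) stop("no parsable variant records in ", vcf_path)

  bind <- function(fld, mode) {
    m <- do.call(rbind, lapply(rows, function(x) as.vector(x[[fld]], mode)))
    rownames(m) <- NULL
    m
  }
  cohort <- mito_cohort(
    samples = samples[, c("sample_id", "family_id", "group", "sex")],
    sites = do.call(rbind, c(lapply(rows, `[[`, "site"),
                             make.row.names = FALSE)),
    dosage = bind("dosage", "integer"),
    gq = bind("gq", "numeric"), dp = bind("dp", "numeric"),
    af = bind("af", "numeric"))
  attr(cohort, "skipped") <- skipped
  cohort
}

fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                    scientific = FALSE))

#' Write a cohort back to an annotated VCF 4.2 text file
#'
#' Emits one bi-allelic record per site with the annotation carried in a
#' pipe-delimited INFO field (same dialect [read_cohort()] parses) and
#' per-sample `GT:GQ:DP:AF`. Male calls on the sex chromosomes are written
#' haploid.
#'
#' @param cohort a [mito_cohort()].
#' @param path output path.
#' @param ann_field INFO key for the annotation string.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, ann_field = "CSQ") {
  s <- cohort$sites
  samp <- cohort$samples
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf(paste0('##INFO=<ID=%s,Number=.,Type=String,Description=',
                   '"Consequence annotations. Format: Allele|SYMBOL|',
                   'Consequence|ClinVar|CADD_PHRED|REVEL|HGVSc">'), ann_field),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Alt allele fraction">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samp$sample_id), collapse = "\t"))
  dot <- function(x) ifelse(is.na(x) | x == "", ".", x)
  info <- sprintf("%s=%s|%s|%s|%s|%s|%s|%s", ann_field, s$alt, dot(s$gene),
                  dot(s$consequence), dot(s$clinvar), fmt_num(s$cadd),
                  fmt_num(s$revel), dot(s$hgvsc))
  recs <- vapply(seq_len(nrow(s)), function(i) {
    hap <- is_haploid_call(s$chrom[i], samp$sex)
    gts <- vapply(seq_len(nrow(samp)), function(j) {
      d <- cohort$dosage[i, j]
      gt <- if (hap[j]) {
        if (is.na(d)) "." else as.character(min(d, 1L))
      } else {
        if (is.na(d)) "./." else c("0/0", "0/1", "1/1")[d + 1]
      }
      paste(gt, fmt_num(cohort$gq[i, j]), fmt_num(cohort$dp[i, j]),
            fmt_num(cohort$af[i, j]), sep = ":")
    }, character(1))
    paste(c(s$chrom[i], s$pos[i], ".", s$ref[i], s$alt[i], ".", "PASS",
            info[i], "GT:GQ:DP:AF", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, recs), path)
  invisible(path)
}
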