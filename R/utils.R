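#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding used for all reported rates and differences:
#' 0.285 rounds to 0.29 and -0.285 to -0.29, unlike [base::round()]'s
#' round-half-even rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  # nudge by an epsilon so values that are exactly .5 after floating-point
  # representation (e.g. 0.285 stored as 0.28499999...) still round up
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Write a data frame as a tab-separated report
#'
#' @param x data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_missing_chr <- function(x) is.na(x) | x == "" | x == "." | x == "NA"

## chromosome helpers: sex-chromosome calls in males are haploid
norm_chrom <- function(chrom) sub("^chr", "", chrom, ignore.case = TRUE)

is_haploid_call <- function(chrom, sex) {
  cn <- norm_chrom(chrom)
  (cn %in% c("X", "Y")) & sex == "male" | (cn == "Y")
}
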