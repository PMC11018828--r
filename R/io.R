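#' Write a trio cohort as a phased VCF 4.2
#'
#' Emits GT with `|` separators (haplotype 1 then haplotype 2), one sample
#' column per individual in pedigree order. Deterministic byte output for a
#' fixed cohort.
#'
#' @param cohort A `trio_cohort`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(cohort, path) {
  v <- cohort$variants
  iids <- cohort$pedigree$iid
  H <- cohort$haplotypes
  h1 <- H[paste0(iids, "|1"), , drop = FALSE]
  h2 <- H[paste0(iids, "|2"), , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = ncol(H))  # variants x samples
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cispen",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", iids), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Parses GT fields (via `vcfR`) into a haplotype matrix with two rows per
#' sample (`"<id>|1"`, `"<id>|2"`). Unphased genotypes (`/` separators) are
#' an error.
#'
#' @param path VCF path.
#' @return Integer matrix, haplotypes x variants, with a `variants`
#'   attribute (chrom, pos, ref, alt).
#' @export
read_phased_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("unphased genotypes in ", path, "; phased input ('|') required")
  }
  ids <- colnames(gt)
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  H <- matrix(0L, nrow = 2L * length(ids), ncol = nrow(gt))
  H[seq(1, nrow(H), 2), ] <- t(a1)
  H[seq(2, nrow(H), 2), ] <- t(a2)
  rownames(H) <- as.vector(rbind(paste0(ids, "|1"), paste0(ids, "|2")))
  fix <- vcfR::getFIX(vcf)
  colnames(H) <- fix[, "ID"]
  attr(H, "variants") <- data.frame(
    variant_id = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE)
  H
}

#' Read alt-allele dosages from a VCF
#'
#' Dosage is taken from the DS FORMAT field when `field = "DS"`, or as the
#' alt-allele count of the GT field when `field = "GT"` (phased or
#' unphased).
#'
#' @param path VCF path.
#' @param field `"GT"` (default) or `"DS"`.
#' @return Numeric matrix, samples x variants, with a `variants` attribute.
#' @export
read_vcf_dosage <- function(path, field = c("GT", "DS")) {
  field <- match.arg(field)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (field == "DS") {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    D <- t(ds)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    D <- t(matrix(as.integer(substr(gt, 1, 1)) + as.integer(substr(gt, 3, 3)),
                  nrow = nrow(gt), dimnames = dimnames(gt)))
  }
  colnames(D) <- fix[, "ID"]
  attr(D, "variants") <- data.frame(
    variant_id = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE)
  D
}

#' Write / read a 6-column PED/FAM pedigree
#'
#' Columns: family id, individual id, father, mother, sex (1 = male,
#' 2 = female), phenotype (1 = unaffected, 2 = affected).
#'
#' @param pedigree Data frame with columns `fid`, `iid`, `father`,
#'   `mother`, `sex`, `phenotype`.
#' @param path File path.
#' @return `read_ped()` returns the pedigree data frame.
#' @export
write_ped <- function(pedigree, path) {
  utils::write.table(pedigree[, c("fid", "iid", "father", "mother", "sex",
                                  "phenotype")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ped
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("fid", "iid", "father", "mother",
                                        "sex", "phenotype"),
                          colClasses = c("character", "character", "character",
                                         "character", "integer", "integer"))
  df
}

#' Write rare-variant placements / ground truth as TSV
#'
#' @param df Data frame (`rare_variants` of a cohort, or `truth$trios`).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
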