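#' Genotype call container for array QC
#'
#' @param calls Integer matrix samples x variants; values 0, 1, 2 or NA
#'   (missing).
#' @param variants Data frame with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`; `is_indel` and `is_palindromic` are derived from the alleles
#'   when absent.
#' @param batch Optional per-sample batch labels (genotyping batch), used
#'   for differential-missingness and allele-frequency batch filters.
#' @return A `genotype_calls` object.
#' @export
genotype_calls <- function(calls, variants, batch = NULL) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c(0L, 1L, 2L, NA))) {
    stop("calls must be 0, 1, 2 or NA")
  }
  if (ncol(calls) != nrow(variants)) {
    stop("calls columns must match variants rows")
  }
  # duplicated marker ids are allowed here: snp_qc flags them for removal
  if (is.null(variants$is_indel)) {
    variants$is_indel <- nchar(variants$ref) != 1L | nchar(variants$alt) != 1L
  }
  if (is.null(variants$is_palindromic)) {
    pal <- c(A = "T", T = "A", C = "G", G = "C")
    variants$is_palindromic <- !variants$is_indel &
      pal[variants$ref] == variants$alt & !is.na(pal[variants$ref])
    variants$is_palindromic[is.na(variants$is_palindromic)] <- FALSE
  }
  colnames(calls) <- variants$variant_id
  if (!is.null(batch)) {
    stopifnot(length(batch) == nrow(calls))
  }
  structure(list(calls = calls, variants = variants, batch = batch),
            class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat(sprintf("genotype_calls: %d samples x %d variants\n",
              nrow(x$calls), nrow(x$variants)))
  invisible(x)
}

#' Array QC thresholds
#'
#' Defaults follow standard array pipelines for trio cohorts: samples with
#' >= 5% missing genotypes removed, heterozygosity rate outside
#' (0.158, 0.17) removed, trios with > 200 Mendelian errors removed;
#' SNP-level filters remove markers with missing rate > 5%, MAF < 1%, HWE
#' exact p < 1e-6, Mendelian errors in > 1% of trios, batch differential
#' missingness p < 1e-50 or batch allele-frequency difference > 0.05; and
#' post-imputation variants are kept at imputation r-squared >= 0.8.
#'
#' @param sample_missing_max,het_rate_min,het_rate_max,trio_mendel_max
#'   Sample/trio filters (see Details above).
#' @param snp_missing_max,snp_maf_min,hwe_p_min,snp_mendel_trio_frac_max
#'   Per-SNP filters.
#' @param batch_diff_p_min,batch_af_diff_max Batch filters.
#' @param impute_r2_min Imputation-quality floor (kept when r2 >= this).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_missing_max = 0.05,
                          het_rate_min = 0.158,
                          het_rate_max = 0.17,
                          trio_mendel_max = 200L,
                          snp_missing_max = 0.05,
                          snp_maf_min = 0.01,
                          hwe_p_min = 1e-6,
                          snp_mendel_trio_frac_max = 0.01,
                          batch_diff_p_min = 1e-50,
                          batch_af_diff_max = 0.05,
                          impute_r2_min = 0.8) {
  th <- list(sample_missing_max = sample_missing_max,
             het_rate_min = het_rate_min, het_rate_max = het_rate_max,
             trio_mendel_max = as.integer(trio_mendel_max),
             snp_missing_max = snp_missing_max, snp_maf_min = snp_maf_min,
             hwe_p_min = hwe_p_min,
             snp_mendel_trio_frac_max = snp_mendel_trio_frac_max,
             batch_diff_p_min = batch_diff_p_min,
             batch_af_diff_max = batch_af_diff_max,
             impute_r2_min = impute_r2_min)
  fr <- c("sample_missing_max", "snp_missing_max", "snp_maf_min",
          "snp_mendel_trio_frac_max", "het_rate_min", "het_rate_max")
  bad <- vapply(th[fr], function(x) x < 0 || x > 1, logical(1))
  if (any(bad)) stop("fractions must lie in [0, 1]: ",
                     paste(fr[bad], collapse = ", "))
  if (th$het_rate_min >= th$het_rate_max) {
    stop("het_rate_min must be below het_rate_max")
  }
  class(th) <- "qc_thresholds"
  th
}

new_qc_report <- function(kept_samples, removed_samples, kept_variants,
                          removed_variants, trio_mendel = NULL) {
  structure(list(kept_samples = kept_samples,
                 removed_samples = removed_samples,
                 kept_variants = kept_variants,
                 removed_variants = removed_variants,
                 trio_mendel = trio_mendel,
                 summary = c(table(c(removed_samples$reason,
                                     removed_variants$reason)))),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples kept / %d removed; %d variants kept / %d removed\n",
              length(x$kept_samples), nrow(x$removed_samples),
              length(x$kept_variants), nrow(x$removed_variants)))
  if (length(x$summary)) print(x$summary)
  invisible(x)
}

#' Sample-level QC: missingness then heterozygosity
#'
#' Removes samples with a missing-call fraction at or above
#' `sample_missing_max` (primary reason `"missingness"`); among the
#' remainder, removes samples whose heterozygosity rate (het calls /
#' non-missing calls) is strictly below `het_rate_min` or strictly above
#' `het_rate_max` (reason `"heterozygosity"`). The order is fixed:
#' missingness first, so an all-missing sample never has its (undefined)
#' het rate evaluated.
#'
#' @param calls A [genotype_calls()] object.
#' @param thresholds A [qc_thresholds()] list.
#' @return A `qc_report`.
#' @export
sample_qc <- function(calls, thresholds = qc_thresholds()) {
  stopifnot(inherits(calls, "genotype_calls"), ncol(calls$calls) >= 1)
  G <- calls$calls
  ids <- rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  miss <- rowMeans(is.na(G))
  rm_miss <- miss >= thresholds$sample_missing_max
  het <- rowSums(G == 1L, na.rm = TRUE) / rowSums(!is.na(G))
  rm_het <- !rm_miss & (het < thresholds$het_rate_min |
                          het > thresholds$het_rate_max)
  removed <- data.frame(
    id = c(ids[rm_miss], ids[rm_het]),
    reason = c(rep("missingness", sum(rm_miss)),
               rep("heterozygosity", sum(rm_het))),
    stringsAsFactors = FALSE)
  new_qc_report(kept_samples = ids[!(rm_miss | rm_het)],
                removed_samples = removed,
                kept_variants = calls$variants$variant_id,
                removed_variants = data.frame(id = character(0),
                                              reason = character(0)))
}

# 3x3x3 lookup: is child genotype impossible given parents (biallelic)?
# gamete sets: 0 -> {0}, 1 -> {0,1}, 2 -> {1}
.mendel_impossible <- local({
  gam <- list(`0` = 0L, `1` = 0L:1L, `2` = 1L)
  arr <- array(TRUE, dim = c(3, 3, 3))
  for (m in 0:2) for (f in 0:2) {
    kids <- unique(outer(gam[[m + 1L]], gam[[f + 1L]], `+`))
    for (k in kids) arr[k + 1L, m + 1L, f + 1L] <- FALSE
  }
  arr
})

#' Count Mendelian errors in a trio
#'
#' Counts variants at which the unphased child genotype is impossible given
#' the parental genotypes under biallelic Mendelian inheritance. Variants
#' with any missing call in the trio are skipped.
#'
#' @param child,mother,father Aligned integer vectors of genotype calls
#'   (0/1/2/NA) over the same variants.
#' @return Integer error count.
#' @export
#' @examples
#' mendelian_error_count(child = c(2, 1), mother = c(0, 0), father = c(0, 2))
mendelian_error_count <- function(child, mother, father) {
  if (length(child) != length(mother) || length(child) != length(father)) {
    stop("child, mother and father call vectors must be aligned (equal length)")
  }
  ok <- !(is.na(child) | is.na(mother) | is.na(father))
  sum(.mendel_impossible[cbind(child[ok] + 1L, mother[ok] + 1L,
                               father[ok] + 1L)])
}

# per-variant logical matrix of Mendelian errors, trios x variants
mendel_error_matrix <- function(G, trios) {
  ci <- match(trios$child, rownames(G))
  mi <- match(trios$mother, rownames(G))
  fi <- match(trios$father, rownames(G))
  if (any(is.na(c(ci, mi, fi)))) stop("trio ids missing from call matrix")
  t(vapply(seq_len(nrow(trios)), function(t) {
    c_ <- G[ci[t], ]; m <- G[mi[t], ]; f <- G[fi[t], ]
    err <- rep(FALSE, ncol(G))
    ok <- !(is.na(c_) | is.na(m) | is.na(f))
    err[ok] <- .mendel_impossible[cbind(c_[ok] + 1L, m[ok] + 1L, f[ok] + 1L)]
    err
  }, logical(ncol(G))))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact p value conditional on the allele counts: the probabilities of all
#' heterozygote counts with the same parity and allele counts that are no
#' more probable than the observed count are summed (standard exact
#' formulation, not mid-p). Computed with a ratio recurrence over
#' admissible heterozygote counts for numerical stability.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Exact p value.
#' @export
#' @examples
#' hwe_exact_test(50, 21, 29)
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype required")
  n_rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (n_rare == 0) return(1)
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  # relative probabilities by recurrence:
  # P(h+2)/P(h) = 4 * hom_rare(h) * hom_common(h) / ((h+2) * (h+1))
  probs <- numeric(length(hets))
  probs[1] <- 1
  if (length(hets) > 1) {
    for (i in seq_len(length(hets) - 1L)) {
      h <- hets[i]
      hom_rare <- (n_rare - h) / 2
      hom_common <- n - h - hom_rare
      probs[i + 1L] <- probs[i] * 4 * hom_rare * hom_common /
        ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

#' SNP-level QC
#'
#' Removes variants in a fixed order, each with a single primary reason:
#' palindromic (A/T, C/G), duplicated position (identical chrom:pos:ref:alt
#' keys), multiallelic (same position, different alleles), indel; then
#' missing rate > `snp_missing_max`, MAF < `snp_maf_min`, HWE exact
#' p < `hwe_p_min` (computed on founders when trios are given), Mendelian
#' errors in more than `snp_mendel_trio_frac_max` of trios, and — when
#' batch labels are present — batch differential missingness (2x2 Fisher
#' exact p < `batch_diff_p_min`) or batch allele-frequency difference
#' above `batch_af_diff_max`.
#'
#' @param calls A [genotype_calls()] object.
#' @param trios Optional data frame with columns `child`, `mother`,
#'   `father` (sample ids) for the per-SNP Mendelian filter and
#'   founders-only HWE.
#' @param thresholds A [qc_thresholds()] list.
#' @return A `qc_report`.
#' @export
snp_qc <- function(calls, trios = NULL, thresholds = qc_thresholds()) {
  stopifnot(inherits(calls, "genotype_calls"))
  v <- calls$variants
  G <- calls$calls
  nv <- nrow(v)
  reason <- rep(NA_character_, nv)
  mark <- function(idx, why) {
    idx <- idx[is.na(reason[idx])]
    reason[idx] <<- why
  }
  mark(which(v$is_palindromic), "palindromic")
  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  mark(which(key %in% key[duplicated(key)]), "duplicated")
  poskey <- paste(v$chrom, v$pos, sep = ":")
  multi <- poskey %in% poskey[duplicated(poskey)] &
    !(key %in% key[duplicated(key)])
  mark(which(multi), "multiallelic")
  mark(which(v$is_indel), "indel")

  live <- is.na(reason)
  miss <- colMeans(is.na(G))
  mark(which(live & miss > thresholds$snp_missing_max), "missingness")

  live <- is.na(reason)
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  mark(which(live & !is.na(maf) & maf < thresholds$snp_maf_min), "maf")

  live <- is.na(reason)
  founders <- if (!is.null(trios)) {
    unique(c(trios$mother, trios$father))
  } else {
    rownames(G)
  }
  Gf <- G[rownames(G) %in% founders, , drop = FALSE]
  hwe_p <- vapply(which(live), function(j) {
    x <- Gf[, j]
    hwe_exact_test(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                   sum(x == 2L, na.rm = TRUE))
  }, numeric(1))
  mark(which(live)[hwe_p < thresholds$hwe_p_min], "hwe")

  if (!is.null(trios) && nrow(trios) > 0) {
    live <- is.na(reason)
    errs <- mendel_error_matrix(G, trios)
    frac <- colMeans(errs)
    mark(which(live & frac > thresholds$snp_mendel_trio_frac_max), "mendelian")
  }

  if (!is.null(calls$batch) && length(unique(calls$batch)) == 2L) {
    b <- calls$batch
    lv <- unique(b)
    live <- is.na(reason)
    for (j in which(live)) {
      m1 <- sum(is.na(G[b == lv[1], j])); n1 <- sum(b == lv[1])
      m2 <- sum(is.na(G[b == lv[2], j])); n2 <- sum(b == lv[2])
      p <- stats::fisher.test(matrix(c(m1, n1 - m1, m2, n2 - m2), 2))$p.value
      if (p < thresholds$batch_diff_p_min) {
        reason[j] <- "batch_missingness"
        next
      }
      af1 <- mean(G[b == lv[1], j], na.rm = TRUE) / 2
      af2 <- mean(G[b == lv[2], j], na.rm = TRUE) / 2
      if (is.finite(af1) && is.finite(af2) &&
          abs(af1 - af2) > thresholds$batch_af_diff_max) {
        reason[j] <- "batch_af"
      }
    }
  }

  removed <- data.frame(id = v$variant_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  trio_mendel <- NULL
  if (!is.null(trios) && nrow(trios) > 0) {
    errs <- mendel_error_matrix(G, trios)
    trio_mendel <- data.frame(child = trios$child,
                              n_mendel_errors = rowSums(errs))
  }
  new_qc_report(kept_samples = rownames(G),
                removed_samples = data.frame(id = character(0),
                                             reason = character(0)),
                kept_variants = v$variant_id[is.na(reason)],
                removed_variants = removed,
                trio_mendel = trio_mendel)
}

#' Apply a QC report to a genotype_calls object
#'
#' @param calls A [genotype_calls()] object.
#' @param report A `qc_report` from [sample_qc()] or [snp_qc()].
#' @return The filtered `genotype_calls` object.
#' @export
apply_qc <- function(calls, report) {
  keep_s <- rownames(calls$calls) %in% report$kept_samples
  keep_v <- calls$variants$variant_id %in% report$kept_variants
  genotype_calls(calls$calls[keep_s, keep_v, drop = FALSE],
                 calls$variants[keep_v, , drop = FALSE],
                 batch = if (!is.null(calls$batch)) calls$batch[keep_s])
}

#' Trio-level Mendelian-error filter
#'
#' Flags trios whose offspring shows more than `trio_mendel_max` Mendelian
#' errors across the call set.
#'
#' @inheritParams snp_qc
#' @return Data frame with `child`, `n_mendel_errors`, `removed`.
#' @export
trio_mendel_qc <- function(calls, trios, thresholds = qc_thresholds()) {
  errs <- mendel_error_matrix(calls$calls, trios)
  n <- rowSums(errs)
  data.frame(child = trios$child, n_mendel_errors = n,
             removed = n > thresholds$trio_mendel_max,
             stringsAsFactors = FALSE)
}

#' Imputation-quality filter
#'
#' Keeps variants with imputation r-squared at or above `impute_r2_min`
#' (inclusive bound), and — when `require_maf = TRUE` — MAF above
#' `snp_maf_min`.
#'
#' @param meta Data frame with `variant_id`, `r2` and optionally `maf`.
#' @param thresholds A [qc_thresholds()] list.
#' @param require_maf Also apply the MAF floor.
#' @return Character vector of kept variant ids.
#' @export
imputation_filter <- function(meta, thresholds = qc_thresholds(),
                              require_maf = FALSE) {
  if (nrow(meta) == 0) return(character(0))
  if (is.null(meta$r2) || any(is.na(meta$r2))) {
    bad <- if (is.null(meta$r2)) meta$variant_id else meta$variant_id[is.na(meta$r2)]
    stop("missing imputation r2 for variant(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  keep <- meta$r2 >= thresholds$impute_r2_min
  if (require_maf) {
    if (is.null(meta$maf)) stop("require_maf = TRUE but no maf column")
    keep <- keep & meta$maf > thresholds$snp_maf_min
  }
  meta$variant_id[keep]
}
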