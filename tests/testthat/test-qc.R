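# builds a clean call matrix whose samples sit inside the het-rate window
clean_calls <- function(n_samples = 6, n_variants = 100, seed = 1) {
  set.seed(seed)
  # ~16.5% heterozygotes per sample, no missingness
  calls <- t(vapply(seq_len(n_samples), function(i) {
    g <- rep(0L, n_variants)
    g[sample(n_variants, round(0.165 * n_variants))] <- 1L
    g[sample(which(g == 0L), 10)] <- 2L
    g
  }, integer(n_variants)))
  rownames(calls) <- paste0("s", seq_len(n_samples))
  variants <- data.frame(variant_id = paste0("v", seq_len(n_variants)),
                         chrom = "1", pos = seq_len(n_variants),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_calls(calls, variants)
}

test_that("sample QC removes by missingness first, then heterozygosity", {
  gc <- clean_calls(6, 100)
  gc$calls["s1", 1:6] <- NA            # 6% missing
  gc$calls["s2", ] <- NA               # everything missing
  gc$calls["s3", ] <- 0L               # het rate 0
  gc$calls["s3", 1:2] <- 1L            # 2% well below 0.158
  rep <- sample_qc(gc, qc_thresholds())
  expect_equal(rep$removed_samples$reason[rep$removed_samples$id == "s1"],
               "missingness")
  expect_equal(rep$removed_samples$reason[rep$removed_samples$id == "s2"],
               "missingness")
  expect_equal(rep$removed_samples$reason[rep$removed_samples$id == "s3"],
               "heterozygosity")
  expect_true(all(c("s4", "s5", "s6") %in% rep$kept_samples))
  # het rate inside (0.158, 0.17) is kept: s4..s6 are at ~0.165
  expect_false("s4" %in% rep$removed_samples$id)
  # reconciliation: kept + removed = input
  expect_equal(sort(c(rep$kept_samples, rep$removed_samples$id)),
               sort(rownames(gc$calls)))
  # idempotence
  rep2 <- sample_qc(apply_qc(gc, rep), qc_thresholds())
  expect_equal(nrow(rep2$removed_samples), 0L)
})

test_that("Mendelian counter agrees with exhaustive gamete enumeration", {
  expect_equal(mendelian_error_count(2, 0, 0), 1)
  expect_equal(mendelian_error_count(1, 0, 2), 0)
  combos <- expand.grid(child = 0:2, mother = 0:2, father = 0:2)
  got <- mapply(mendelian_error_count, combos$child, combos$mother,
                combos$father)
  want <- mapply(function(c, m, f) as.integer(oracle_mendel_impossible(c, m, f)),
                 combos$child, combos$mother, combos$father)
  expect_equal(got, want)
  # missing calls are skipped; misaligned input errors
  expect_equal(mendelian_error_count(c(2, NA), c(0, 0), c(0, 0)), 1)
  expect_error(mendelian_error_count(c(1, 1), c(1), c(1, 1)), "aligned")
})

test_that("HWE exact test matches closed-form enumeration", {
  expect_equal(hwe_exact_test(0, 0, 5), 1)
  expect_equal(hwe_exact_test(1, 0, 1), oracle_hwe_enum(1, 0, 1),
               tolerance = 1e-12)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(50, 21, 29), oracle_hwe_enum(50, 21, 29),
               tolerance = 1e-12)
  set.seed(3)
  for (r in 1:20) {
    n <- sample(2:80, 3, replace = TRUE)
    expect_equal(hwe_exact_test(n[1], n[2], n[3]),
                 oracle_hwe_enum(n[1], n[2], n[3]), tolerance = 1e-12)
  }
})

test_that("HWE p values are at most nominal under the null", {
  set.seed(17)
  p <- replicate(2000, {
    g <- rbinom(100, 2, 0.3)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  frac <- mean(p < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("SNP QC removes variants in the documented order with one reason", {
  set.seed(5)
  n <- 60
  variants <- data.frame(
    variant_id = paste0("v", 1:8),
    chrom = "1",
    pos = c(1, 2, 3, 3, 4, 5, 6, 7),
    ref = c("A", "C", "G", "G", "A", "AT", "A", "A"),
    alt = c("T", "G", "T", "A", "G", "A", "G", "G"),
    stringsAsFactors = FALSE)
  variants <- rbind(variants, variants[3, ])  # exact duplicate of v3
  calls <- matrix(rbinom(n * 9, 2, 0.3), nrow = n,
                  dimnames = list(paste0("s", 1:n), NULL))
  calls[, 7] <- rbinom(n, 2, 0.005)           # MAF << 1%
  gc <- genotype_calls(calls, variants)
  rep <- snp_qc(gc, thresholds = qc_thresholds())
  rr <- rep$removed_variants
  expect_equal(rr$reason[rr$id == "v1"], "palindromic")   # A/T
  expect_equal(rr$reason[rr$id == "v2"], "palindromic")   # C/G
  expect_equal(sort(rr$reason[rr$id == "v3"]), c("duplicated", "duplicated"))
  expect_equal(rr$reason[rr$id == "v4"], "multiallelic")  # shares pos 3
  expect_equal(rr$reason[rr$id == "v6"], "indel")
  expect_true("v7" %in% rr$id[rr$reason == "maf"])
  expect_false("v5" %in% rr$id)
  expect_false("v8" %in% rr$id)
  # idempotence on the kept output
  rep2 <- snp_qc(apply_qc(gc, rep), thresholds = qc_thresholds())
  expect_equal(nrow(rep2$removed_variants), 0L)
  # reconciliation
  expect_equal(length(rep$kept_variants) + nrow(rr), nrow(gc$variants))
})

test_that("per-SNP Mendelian and HWE filters respond to trio evidence", {
  # 100 trios; SNP 1 carries Mendelian errors in 2% of trios, SNP 2 clean
  set.seed(8)
  n_trio <- 100
  ids <- c(paste0("c", 1:n_trio), paste0("m", 1:n_trio), paste0("f", 1:n_trio))
  calls <- matrix(rbinom(length(ids) * 2, 2, 0.4), ncol = 2,
                  dimnames = list(ids, NULL))
  # make SNP 2 Mendelian-consistent: child = one gamete from each parent
  gm <- rbinom(n_trio, 1, calls[paste0("m", 1:n_trio), 2] / 2)
  gf <- rbinom(n_trio, 1, calls[paste0("f", 1:n_trio), 2] / 2)
  calls[paste0("c", 1:n_trio), 2] <- gm + gf
  calls[paste0("c", 1:2), 1] <- 2L
  calls[paste0("m", 1:2), 1] <- 0L
  calls[paste0("f", 1:2), 1] <- 0L
  # keep SNP1 otherwise unremarkable: no other errors
  for (t in 3:n_trio) {
    calls[paste0("m", t), 1] <- 1L
    calls[paste0("f", t), 1] <- 1L
    calls[paste0("c", t), 1] <- 1L
  }
  variants <- data.frame(variant_id = c("m1", "m2"), chrom = "1", pos = 1:2,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  trios <- data.frame(child = paste0("c", 1:n_trio),
                      mother = paste0("m", 1:n_trio),
                      father = paste0("f", 1:n_trio))
  gc <- genotype_calls(calls, variants)
  th <- qc_thresholds(hwe_p_min = 0)  # isolate the Mendelian filter
  rep <- snp_qc(gc, trios, th)
  expect_equal(rep$removed_variants$reason[rep$removed_variants$id == "m1"],
               "mendelian")
  expect_false("m2" %in% rep$removed_variants$id)
  expect_equal(rep$trio_mendel$n_mendel_errors[1:2], c(1, 1))
  # trio-level Mendelian QC flags offspring above the error budget
  tm <- trio_mendel_qc(gc, trios, qc_thresholds(trio_mendel_max = 0))
  expect_true(all(tm$removed[1:2]))
  expect_false(any(tm$removed[-(1:2)]))
})

test_that("batch filters detect extreme differential missingness and AF", {
  set.seed(12)
  n <- 600
  calls <- matrix(rbinom(n * 3, 2, 0.4), nrow = n,
                  dimnames = list(paste0("s", 1:n), NULL))
  batch <- rep(c("pilot", "main"), each = n / 2)
  calls[batch == "pilot", 1] <- NA          # all missing in one batch
  calls[batch == "pilot", 2] <- rbinom(n / 2, 2, 0.05)
  calls[batch == "main", 2] <- rbinom(n / 2, 2, 0.45)
  variants <- data.frame(variant_id = c("b1", "b2", "b3"), chrom = "1",
                         pos = 1:3, ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  gc <- genotype_calls(calls, variants, batch = batch)
  th <- qc_thresholds(snp_missing_max = 0.6, hwe_p_min = 0, snp_maf_min = 0)
  rep <- snp_qc(gc, thresholds = th)
  rr <- rep$removed_variants
  expect_equal(rr$reason[rr$id == "b1"], "batch_missingness")
  expect_equal(rr$reason[rr$id == "b2"], "batch_af")
  expect_false("b3" %in% rr$id)
})

test_that("imputation filter keeps r2 >= 0.8 inclusively", {
  meta <- data.frame(variant_id = c("a", "b", "c"),
                     r2 = c(0.8, 0.79, 0.95), maf = c(0.2, 0.2, 0.005),
                     stringsAsFactors = FALSE)
  expect_equal(imputation_filter(meta), c("a", "c"))
  expect_equal(imputation_filter(meta, require_maf = TRUE), "a")
  expect_equal(imputation_filter(meta[0, ]), character(0))
  meta$r2[2] <- NA
  expect_error(imputation_filter(meta), "b")
})
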