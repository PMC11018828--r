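make_gene_table <- function() {
  data.frame(
    gene = c("EBF3", "RECG", "CONSG", "PLAIN"),
    pli = c(0.99, 0.2, 0.95, 0.1),
    ddg2p_inheritance = c("dominant", "recessive", "none", "none"),
    ddg2p_mechanism = c("LoF", "LoF", "none", "none"),
    ddg2p_confidence = c("confirmed", "probable", "other", "other"),
    stringsAsFactors = FALSE)
}

base_record <- function(...) {
  rec <- data.frame(
    proband = "P1", gene = "EBF3", chrom = "10", pos = 131665510,
    ref = "G", alt = "A", consequence = "PTV", is_indel = FALSE,
    mpc = NA_real_, gnomad_af = 0, cohort_af = 0, heterozygous = TRUE,
    inheritance = "maternal", clinician_rating = "unrated",
    clinical_filter_class = "inherited_ptv_dominant_lof", pli = 0.99,
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

test_that("classification applies frequency gates and category rules", {
  genes <- make_gene_table()
  # inherited stop-gain in a confirmed dominant LoF gene
  v <- classify_damaging(base_record(), genes)
  expect_true(v$dominant_lof)
  expect_false(v$recessive_lof)
  expect_true(v$constrained)  # EBF3 pli 0.99 and PTV
  expect_true(v$ptv)
  # missense with MPC 2.5 in a constrained non-DD gene
  v2 <- classify_damaging(base_record(gene = "CONSG", consequence = "missense",
                                      mpc = 2.5), genes)
  expect_true(v2$constrained)
  expect_false(v2$dominant_lof)
  expect_false(v2$ptv)
  # common variant fails the gnomAD gate entirely
  v3 <- classify_damaging(base_record(gnomad_af = 1e-3), genes)
  expect_false(any(v3$dominant_lof, v3$recessive_lof, v3$constrained))
  # boundary semantics: gnomAD strict, cohort inclusive
  v4 <- classify_damaging(base_record(gnomad_af = 1e-5), genes)
  expect_false(v4$dominant_lof)
  v5 <- classify_damaging(base_record(cohort_af = 1e-4), genes)
  expect_true(v5$dominant_lof)
  # de novo and non-het records are never candidates
  expect_false(classify_damaging(base_record(inheritance = "de_novo"),
                                 genes)$dominant_lof)
  expect_false(classify_damaging(base_record(heterozygous = FALSE),
                                 genes)$dominant_lof)
  # recessive category
  v6 <- classify_damaging(base_record(gene = "RECG", pli = 0.2), genes)
  expect_true(v6$recessive_lof)
  expect_false(v6$constrained)
})

test_that("missing MPC excludes missense from the constrained category with a warning", {
  genes <- make_gene_table()
  expect_warning(
    v <- classify_damaging(base_record(gene = "CONSG", consequence = "missense",
                                       mpc = NA_real_), genes),
    "MPC")
  expect_false(v$constrained)
  # MPC below 2 also fails, silently
  v2 <- classify_damaging(base_record(gene = "CONSG", consequence = "missense",
                                      mpc = 1.9), genes)
  expect_false(v2$constrained)
})

test_that("classification is pure and monotone in the MAF gates", {
  genes <- make_gene_table()
  set.seed(31)
  recs <- do.call(rbind, lapply(1:40, function(i) {
    base_record(proband = paste0("P", i),
                gene = sample(genes$gene, 1),
                consequence = sample(c("PTV", "missense", "other"), 1),
                mpc = sample(c(NA, 1, 2.5), 1),
                gnomad_af = sample(c(0, 5e-6, 2e-5, 1e-3), 1),
                cohort_af = sample(c(0, 1e-4, 5e-4), 1),
                inheritance = sample(c("maternal", "paternal", "de_novo"), 1))
  }))
  a <- suppressWarnings(classify_damaging(recs, genes))
  b <- suppressWarnings(classify_damaging(recs, genes))
  expect_identical(a, b)
  tight <- suppressWarnings(
    classify_damaging(recs, genes, damaging_thresholds(gnomad_af_max = 1e-6)))
  for (cat in c("dominant_lof", "recessive_lof", "constrained")) {
    expect_true(all(!(tight[[cat]] & !a[[cat]])))
  }
})

test_that("multi-indel genes are dropped per proband, SNVs untouched", {
  recs <- rbind(
    base_record(proband = "P1", gene = "G1", is_indel = TRUE, pos = 1),
    base_record(proband = "P1", gene = "G1", is_indel = TRUE, pos = 2),
    base_record(proband = "P1", gene = "G2", is_indel = TRUE, pos = 3),
    base_record(proband = "P2", gene = "G1", is_indel = FALSE, pos = 4),
    base_record(proband = "P2", gene = "G1", is_indel = FALSE, pos = 5))
  out <- suppressMessages(indel_dedup_filter(recs))
  expect_equal(nrow(out), 3L)
  expect_false(any(out$proband == "P1" & out$gene == "G1"))
  expect_true(any(out$proband == "P1" & out$gene == "G2"))
  expect_equal(sum(out$proband == "P2"), 2L)
  expect_equal(nrow(indel_dedup_filter(recs[0, ])), 0L)
})

test_that("PPV estimation counts rated variants only", {
  recs <- rbind(
    base_record(clinician_rating = "definitely_pathogenic",
                clinical_filter_class = "A"),
    base_record(clinician_rating = "likely_pathogenic",
                clinical_filter_class = "A"),
    base_record(clinician_rating = "benign", clinical_filter_class = "A"),
    base_record(clinician_rating = "uncertain", clinical_filter_class = "A"),
    base_record(clinician_rating = "unrated", clinical_filter_class = "A"),
    base_record(clinician_rating = "unrated", clinical_filter_class = "B"),
    base_record(clinician_rating = "definitely_pathogenic",
                clinical_filter_class = "C"),
    base_record(clinician_rating = "definitely_pathogenic",
                clinical_filter_class = "C"),
    base_record(clinician_rating = "definitely_pathogenic",
                clinical_filter_class = "C"))
  ppv <- estimate_ppv(recs)
  expect_equal(ppv$ppv[ppv$class == "A"], 0.5)
  expect_true(is.na(ppv$ppv[ppv$class == "B"]))
  expect_true(ppv$undefined[ppv$class == "B"])
  expect_equal(ppv$ppv[ppv$class == "C"], 1.0)
  expect_equal(ppv$n_rated_total[ppv$class == "A"], 4L)
})

test_that("diagnosis criteria i-iv are applied in order", {
  ppv <- data.frame(class = c("hi", "lo"), ppv = c(0.8, 0.2),
                    n_rated_pathogenic_or_likely = c(8, 2),
                    n_rated_total = c(10, 10), undefined = FALSE,
                    stringsAsFactors = FALSE)
  recs <- rbind(
    base_record(proband = "P1", clinician_rating = "likely_pathogenic",
                clinical_filter_class = "lo"),
    base_record(proband = "P2", inheritance = "de_novo", consequence = "PTV",
                pli = 0.99, clinical_filter_class = "lo",
                clinician_rating = "benign"),
    base_record(proband = "P3", clinician_rating = "benign",
                clinical_filter_class = "lo"),
    base_record(proband = "P4", clinician_rating = "unrated",
                clinical_filter_class = "hi"),
    base_record(proband = "P5", clinician_rating = "unrated",
                clinical_filter_class = "lo"))
  st <- flag_undiagnosed(recs, ppv, reanalysis_diagnosed = "P3")
  expect_equal(st$criterion[st$proband == "P1"], "ii")
  expect_equal(st$criterion[st$proband == "P2"], "iv")
  expect_equal(st$criterion[st$proband == "P3"], "i")
  expect_equal(st$criterion[st$proband == "P4"], "iii")
  expect_false(st$diagnosed[st$proband == "P5"])
  # benign-rated variant in a low-PPV class is not a diagnosis
  st2 <- flag_undiagnosed(base_record(clinician_rating = "benign",
                                      clinical_filter_class = "lo"), ppv)
  expect_false(st2$diagnosed)
  # with no criteria inputs everyone is undiagnosed
  st3 <- flag_undiagnosed(base_record(clinician_rating = "benign",
                                      clinical_filter_class = "lo"),
                          ppv, reanalysis_diagnosed = character(0))
  expect_false(any(st3$diagnosed))
  # unknown class on an unrated variant is an error
  expect_error(flag_undiagnosed(base_record(clinician_rating = "unrated",
                                            clinical_filter_class = "mystery"),
                                ppv), "mystery")
})

test_that("NDD phenotype filter is exact-term membership", {
  sets <- list(P1 = c("HP:0001250"), P2 = c("HP:9999999"), P3 = character(0),
               P4 = c("HP:0000001", "HP:0012759"))
  expect_equal(ndd_phenotype_filter(sets), c("P1", "P4"))
  expect_equal(length(ndd_hpo_terms()), 10L)
  expect_error(ndd_phenotype_filter(sets, character(0)))
})

test_that("unique-pair selection is uniform, per-category and seeded", {
  cl <- data.frame(
    proband = c("P1", "P1", "P1", "P2"),
    parent = c("P1.mo", "P1.fa", "P1.mo", "P2.fa"),
    gene = c("G1", "G2", "G3", "G1"),
    inheritance = c("maternal", "paternal", "maternal", "paternal"),
    category = "constrained", stringsAsFactors = FALSE)
  one <- select_unique_pairs(cl, seed = 4)
  expect_equal(nrow(one), 2L)
  expect_equal(anyDuplicated(one$proband), 0L)
  expect_identical(one, select_unique_pairs(cl, seed = 4))
  # single-candidate probands always get that candidate
  expect_equal(one$gene[one$proband == "P2"], "G1")
  # frequency over seeds: P1's three candidates each ~1/3
  picks <- vapply(1:2000, function(s)
    select_unique_pairs(cl, seed = s)$gene[1], character(1))
  freq <- table(factor(picks, c("G1", "G2", "G3"))) / 2000
  se <- sqrt((1 / 3) * (2 / 3) / 2000)
  expect_true(all(abs(freq - 1 / 3) <= 4 * se))
  # a record without a transmitting parent is an error
  bad <- cl
  bad$inheritance[1] <- "unknown"
  expect_error(select_unique_pairs(bad, seed = 1), "transmitting")
  # per-category sampling: same proband may appear in two categories
  cl2 <- rbind(cl, within(cl, category <- "dominant_lof"))
  two <- select_unique_pairs(cl2, seed = 4)
  expect_equal(sum(two$proband == "P1"), 2L)
})
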