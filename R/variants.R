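#' Thresholds for rare damaging-variant classification
#'
#' Defaults follow the strict filter used for penetrance analyses: gnomAD
#' MAF strictly below 1e-5, cohort MAF at or below 1e-4, MPC >= 2 for
#' missense variants in constrained genes, pLI > 0.9 for constraint.
#' `preset = "lenient"` applies the sensitivity setting MAF < 0.1% to both
#' frequency sources. `mpc_all_categories = TRUE` extends the MPC gate on
#' missense variants to the DDG2P categories as well (off by default: the
#' MPC gate belongs to the constrained-gene category).
#'
#' @param gnomad_af_max Strict upper bound on gnomAD allele frequency.
#' @param cohort_af_max Inclusive upper bound on cohort allele frequency.
#' @param mpc_min Minimum MPC for missense in constrained genes.
#' @param pli_min pLI above which a gene counts as constrained.
#' @param mpc_all_categories Extend MPC gating to DDG2P categories.
#' @param preset `"strict"` (default) or `"lenient"`.
#' @return A list of class `damaging_thresholds`.
#' @export
damaging_thresholds <- function(gnomad_af_max = 1e-5,
                                cohort_af_max = 1e-4,
                                mpc_min = 2,
                                pli_min = 0.9,
                                mpc_all_categories = FALSE,
                                preset = c("strict", "lenient")) {
  preset <- match.arg(preset)
  if (preset == "lenient") {
    gnomad_af_max <- 1e-3
    cohort_af_max <- 1e-3
  }
  structure(list(gnomad_af_max = gnomad_af_max, cohort_af_max = cohort_af_max,
                 mpc_min = mpc_min, pli_min = pli_min,
                 mpc_all_categories = mpc_all_categories),
            class = "damaging_thresholds")
}

#' Classify rare inherited variants into penetrance-relevant categories
#'
#' A variant is a candidate only if heterozygous, inherited (maternal or
#' paternal), gnomAD AF strictly below the gnomAD gate and cohort AF at or
#' below the cohort gate. Candidates are then assigned to:
#' \describe{
#'   \item{dominant_lof}{PTV or missense in a confirmed/probable dominant
#'     DDG2P gene with a LoF mechanism.}
#'   \item{recessive_lof}{as above with recessive inheritance.}
#'   \item{constrained}{PTV, or missense with MPC >= `mpc_min`, in a gene
#'     with pLI > `pli_min`. A missense candidate with missing MPC is
#'     excluded from this category with a logged warning.}
#' }
#' The PTV-only sub-analysis is derivable from the `consequence` column
#' (`ptv` logical in the output).
#'
#' @param variants Data frame of variant records: `proband`, `gene`,
#'   `consequence` (`"PTV"`, `"missense"`, `"other"`), `mpc`, `gnomad_af`,
#'   `cohort_af`, `heterozygous`, `inheritance` (`"maternal"`,
#'   `"paternal"`, `"de_novo"`, `"unknown"`), plus free columns.
#' @param genes Data frame of gene annotations: `gene`, `pli`,
#'   `ddg2p_inheritance`, `ddg2p_mechanism`, `ddg2p_confidence`.
#' @param thresholds A [damaging_thresholds()] list.
#' @return The input data frame with added logical columns `candidate`,
#'   `dominant_lof`, `recessive_lof`, `constrained` and `ptv`.
#' @export
classify_damaging <- function(variants, genes,
                              thresholds = damaging_thresholds()) {
  stopifnot(all(c("proband", "gene", "consequence", "gnomad_af", "cohort_af",
                  "heterozygous", "inheritance") %in% names(variants)))
  if (any(variants$gnomad_af < 0 | variants$gnomad_af > 1, na.rm = TRUE) ||
      any(variants$cohort_af < 0 | variants$cohort_af > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  gi <- match(variants$gene, genes$gene)
  pli <- genes$pli[gi]
  dd_inh <- genes$ddg2p_inheritance[gi]
  dd_mech <- genes$ddg2p_mechanism[gi]
  dd_conf <- genes$ddg2p_confidence[gi]
  mpc <- if (is.null(variants$mpc)) rep(NA_real_, nrow(variants)) else variants$mpc

  candidate <- variants$heterozygous &
    variants$inheritance %in% c("maternal", "paternal") &
    variants$gnomad_af < thresholds$gnomad_af_max &
    variants$cohort_af <= thresholds$cohort_af_max
  coding <- variants$consequence %in% c("PTV", "missense")
  mpc_ok <- !is.na(mpc) & mpc >= thresholds$mpc_min
  ddg2p_cons <- if (thresholds$mpc_all_categories) {
    variants$consequence == "PTV" | (variants$consequence == "missense" & mpc_ok)
  } else {
    coding
  }
  is_dd <- !is.na(dd_conf) & dd_conf %in% c("confirmed", "probable") &
    !is.na(dd_mech) & dd_mech == "LoF"
  dominant_lof <- candidate & ddg2p_cons & is_dd & dd_inh == "dominant"
  recessive_lof <- candidate & ddg2p_cons & is_dd & dd_inh == "recessive"
  cons_gene <- !is.na(pli) & pli > thresholds$pli_min
  missing_mpc_cand <- candidate & cons_gene &
    variants$consequence == "missense" & is.na(mpc)
  if (any(missing_mpc_cand)) {
    warning(sprintf(
      "%d missense candidate(s) in constrained genes lack MPC and are excluded from the constrained category",
      sum(missing_mpc_cand)))
  }
  constrained <- candidate & cons_gene &
    (variants$consequence == "PTV" |
       (variants$consequence == "missense" & mpc_ok))
  out <- variants
  out$candidate <- candidate & coding
  out$dominant_lof <- dominant_lof & !is.na(dominant_lof)
  out$recessive_lof <- recessive_lof & !is.na(recessive_lof)
  out$constrained <- constrained & !is.na(constrained)
  out$ptv <- variants$consequence == "PTV"
  out
}

#' Long-format view of classified variants
#'
#' One row per (variant record, category) membership; convenient input for
#' [select_unique_pairs()].
#'
#' @param classified Output of [classify_damaging()].
#' @return Data frame with a `category` column, one row per membership.
#' @export
categories_long <- function(classified) {
  cats <- c("dominant_lof", "recessive_lof", "constrained")
  rows <- lapply(cats, function(cat) {
    d <- classified[classified[[cat]], , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    d$category <- cat
    d
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(classified[0, , drop = FALSE],
                 data.frame(category = character(0)))
  }
  rownames(out) <- NULL
  out
}

#' Remove probands' multi-indel genes
#'
#' When a sample carries more than one indel in the same gene (a frequent
#' signature of a complex mutational event that would need haplotype-aware
#' annotation to resolve), all indels of that (proband, gene) pair are
#' removed. SNVs are untouched.
#'
#' @param records Data frame with `proband`, `gene`, `is_indel`.
#' @return The filtered data frame; removal count reported via message.
#' @export
indel_dedup_filter <- function(records) {
  if (nrow(records) == 0) return(records)
  key <- paste(records$proband, records$gene, sep = "\r")
  indel_counts <- table(key[records$is_indel])
  bad <- names(indel_counts)[indel_counts >= 2]
  drop <- records$is_indel & key %in% bad
  if (any(drop)) {
    message(sprintf("indel_dedup_filter: removed %d indel(s) in %d proband-gene pair(s)",
                    sum(drop), length(bad)))
  }
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate positive predictive values per clinical filter class
#'
#' PPV of a class is the share of its clinician-rated variants rated
#' pathogenic or likely pathogenic; unrated variants are excluded from both
#' numerator and denominator. Classes with no rated variant get `ppv = NA`
#' and are flagged.
#'
#' @param records Data frame with `clinical_filter_class` and
#'   `clinician_rating` (one of `definitely_pathogenic`,
#'   `likely_pathogenic`, `uncertain`, `likely_benign`, `benign`,
#'   `unrated`).
#' @return Data frame: `class`, `n_rated_pathogenic_or_likely`,
#'   `n_rated_total`, `ppv`, `undefined`.
#' @export
estimate_ppv <- function(records) {
  cls <- sort(unique(records$clinical_filter_class))
  rated <- records$clinician_rating != "unrated"
  path <- records$clinician_rating %in% c("definitely_pathogenic",
                                          "likely_pathogenic")
  n_tot <- vapply(cls, function(k)
    sum(rated & records$clinical_filter_class == k), integer(1))
  n_path <- vapply(cls, function(k)
    sum(rated & path & records$clinical_filter_class == k), integer(1))
  data.frame(class = cls,
             n_rated_pathogenic_or_likely = n_path,
             n_rated_total = n_tot,
             ppv = ifelse(n_tot > 0, n_path / n_tot, NA_real_),
             undefined = n_tot == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

# compound-het pairs by trans-inheritance: two variants in the same gene of
# the same proband with opposite parental inheritance
find_compound_hets <- function(records) {
  inh <- records$inheritance
  keep <- inh %in% c("maternal", "paternal")
  d <- records[keep, , drop = FALSE]
  key <- paste(d$proband, d$gene, sep = "\r")
  both <- tapply(d$inheritance, key, function(x)
    any(x == "maternal") && any(x == "paternal"))
  names(both)[!is.na(both) & both]
}

#' Flag diagnosed vs undiagnosed probands
#'
#' A proband is DIAGNOSED if it meets at least one of: (i) membership of a
#' reanalysis-diagnosed id set; (ii) at least one variant (or compound-het
#' pair) rated pathogenic or likely pathogenic; (iii) at least one unrated
#' variant in a clinical filter class with PPV above `ppv_threshold`;
#' (iv) a de novo PTV in a gene with pLI > 0.9. Otherwise UNDIAGNOSED.
#' Compound-het pairs are detected as two variants of the same gene with
#' opposite parental inheritance.
#'
#' @param records Data frame with `proband`, `gene`, `consequence`,
#'   `inheritance`, `clinician_rating`, `clinical_filter_class`, `pli`.
#' @param ppv_table Output of [estimate_ppv()]; must cover every class
#'   referenced by an unrated variant.
#' @param ppv_threshold Criterion (iii) PPV cut (strictly above).
#' @param reanalysis_diagnosed Character vector of proband ids (criterion i).
#' @return Data frame: `proband`, `diagnosed`, `criterion` (first met, or
#'   `NA`).
#' @export
flag_undiagnosed <- function(records, ppv_table, ppv_threshold = 0.5,
                             reanalysis_diagnosed = character(0)) {
  probands <- sort(unique(records$proband))
  unrated <- records$clinician_rating == "unrated"
  unknown <- setdiff(unique(records$clinical_filter_class[unrated]),
                     ppv_table$class)
  if (length(unknown) > 0) {
    stop("variant(s) reference clinical filter class(es) absent from the PPV table: ",
         paste(unknown, collapse = ", "))
  }
  path <- records$clinician_rating %in% c("definitely_pathogenic",
                                          "likely_pathogenic")
  ppv <- ppv_table$ppv[match(records$clinical_filter_class, ppv_table$class)]
  crit_iii_var <- unrated & !is.na(ppv) & ppv > ppv_threshold
  crit_iv_var <- records$inheritance == "de_novo" &
    records$consequence == "PTV" &
    !is.na(records$pli) & records$pli > 0.9
  res <- lapply(probands, function(p) {
    mine <- records$proband == p
    crit <- if (p %in% reanalysis_diagnosed) {
      "i"
    } else if (any(path & mine)) {
      "ii"
    } else if (any(crit_iii_var & mine)) {
      "iii"
    } else if (any(crit_iv_var & mine)) {
      "iv"
    } else {
      NA_character_
    }
    data.frame(proband = p, diagnosed = !is.na(crit), criterion = crit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' The NDD-defining HPO term set
#'
#' The ten phenotype terms whose presence defines a neurodevelopmental
#' disorder for cohort inclusion (exact term membership, no ontology
#' traversal). The encephalopathy term is stored with its standard 7-digit
#' accession HP:0001298.
#'
#' @return Character vector of 10 HPO ids.
#' @export
ndd_hpo_terms <- function() {
  c("HP:0012705",  # abnormal metabolic brain imaging by MRS
    "HP:0012657",  # abnormal brain positron emission tomography
    "HP:0012535",  # abnormal synaptic transmission
    "HP:0001311",  # abnormal nervous system electrophysiology
    "HP:0000708",  # behavioural abnormality
    "HP:0001250",  # seizures
    "HP:0001298",  # encephalopathy
    "HP:0011446",  # abnormality of higher mental function
    "HP:0012759",  # neurodevelopmental abnormality
    "HP:0012639")  # abnormality of nervous system morphology
}

#' Keep probands with an NDD-defining phenotype term
#'
#' @param term_sets Named list: proband id -> character vector of HPO terms.
#' @param ndd_terms Term list (default [ndd_hpo_terms()]).
#' @return Character vector of kept proband ids.
#' @export
ndd_phenotype_filter <- function(term_sets, ndd_terms = ndd_hpo_terms()) {
  stopifnot(length(ndd_terms) > 0)
  keep <- vapply(term_sets, function(x) length(intersect(x, ndd_terms)) > 0,
                 logical(1))
  names(term_sets)[keep]
}

#' Sample one proband-parent-gene combination per proband and category
#'
#' Within each category analysis, a proband contributing several candidate
#' (parent, gene) combinations has exactly one selected uniformly at
#' random; selection is deterministic given `seed`. A proband may appear in
#' several category analyses (per-analysis sampling).
#'
#' @param classified Long-format classified variants (see
#'   [categories_long()]); must have `proband`, `gene`, `inheritance`
#'   (`maternal`/`paternal`; anything else is an error) and `category`.
#'   A `parent` column is carried through when present.
#' @param seed Integer seed for the selection stream.
#' @return Data frame: `proband`, `parent`, `gene`, `category` (one row per
#'   proband per category).
#' @export
select_unique_pairs <- function(classified, seed = 1L) {
  if (nrow(classified) == 0) {
    return(data.frame(proband = character(0), parent = character(0),
                      gene = character(0), category = character(0)))
  }
  if (!all(classified$inheritance %in% c("maternal", "paternal"))) {
    stop("select_unique_pairs: every record needs a resolvable transmitting ",
         "parent (inheritance must be maternal or paternal)")
  }
  parent <- if (!is.null(classified$parent)) classified$parent else
    classified$inheritance
  d <- data.frame(proband = classified$proband, parent = parent,
                  gene = classified$gene, category = classified$category,
                  stringsAsFactors = FALSE)
  d <- d[order(d$category, d$proband, d$parent, d$gene), , drop = FALSE]
  set.seed(as.integer(seed))
  grp <- paste(d$category, d$proband, sep = "\r")
  picks <- unlist(lapply(split(seq_len(nrow(d)), factor(grp, unique(grp))),
                         function(ix) ix[sample.int(length(ix), 1L)]),
                  use.names = FALSE)
  out <- d[sort(picks), , drop = FALSE]
  rownames(out) <- NULL
  out
}
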