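#' Simulate an ascertained trio cohort with a penetrance-modifying haplotype
#' mechanism
#'
#' Generates phased parental haplotypes (independent Bernoulli(MAF) alleles,
#' no LD), Mendelian transmission of one uniformly chosen haplotype from
#' each parent, and one rare damaging variant placed on one haplotype of one
#' parent in a randomly chosen gene per candidate trio. Affection is
#' Bernoulli with logit
#' `alpha + beta * (mu_g - (E_wt + eps))`, where `E_wt` is the predicted
#' expression of the individual's non-carrier (wild-type) haplotype for the
#' variant gene, `mu_g` the population mean haplotype expression of that
#' gene, and `eps ~ N(0, noise_sd)`. Candidate trios are ascertained until
#' `n_trios_target` satisfy: child affected AND child inherited the variant
#' AND transmitting parent unaffected — mirroring a proband-ascertained
#' design of undiagnosed children with unaffected carrier parents.
#'
#' Because genes are generated independently (no LD), ascertainment depends
#' only on the variant gene's four parental haplotypes; those are sampled
#' first and the remaining genes are filled in for accepted trios, which is
#' exact and keeps large candidate streams cheap.
#'
#' @param config A [sim_config()]; `penetrance_effect` is beta,
#'   `baseline_logit` is alpha.
#' @param weights An `eqtl_weights` table from [simulate_eqtl_models()]
#'   (must carry the generator `maf` column).
#' @return A list with components `cohort` (class `trio_cohort`: phased
#'   haplotype matrix, 6-column pedigree, variant table, rare-variant
#'   placements) and `truth` (per-trio transmitting parent, carrier
#'   haplotype, wild-type expression values and liabilities).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 3, snps_per_gene = 4, n_trios_target = 10, seed = 7)
#' sim <- simulate_trio_cohort(cfg, simulate_eqtl_models(cfg))
#' nrow(sim$cohort$pedigree)  # 30 individuals
simulate_trio_cohort <- function(config, weights) {
  validate_sim_config(config)
  if (is.null(weights) || nrow(weights) == 0) {
    stop("weights must be a non-empty eqtl_weights table")
  }
  if (is.null(weights$maf)) {
    stop("weights table lacks the generator 'maf' column")
  }
  set.seed(sim_seed(config, "trios"))

  genes <- unique(weights$gene)
  ng <- length(genes)
  wsplit <- split(weights[, c("variant_id", "weight", "maf")], weights$gene)[genes]
  mu_hap <- vapply(wsplit, function(d) sum(d$weight * d$maf), numeric(1))
  alpha <- config$baseline_logit
  beta <- config$penetrance_effect
  target <- config$n_trios_target

  # stage 1: ascertain on the variant gene only
  acc_gene <- integer(0)
  acc_haps <- list()      # per accepted trio: 4 x m matrix (m1, m2, f1, f2)
  acc_meta <- list()
  n_acc <- 0L
  attempts <- 0L
  while (n_acc < target) {
    remaining_budget <- config$max_attempts - attempts
    if (remaining_budget <= 0L) {
      stop(sprintf(
        paste0("trio ascertainment failed: only %d of %d trios accepted ",
               "after %d candidate attempts (max_attempts = %d); ",
               "raise baseline_logit or max_attempts"),
        n_acc, target, attempts, config$max_attempts), call. = FALSE)
    }
    p_hat <- if (attempts > 0L) max(n_acc / attempts, 1e-3) else 0.05
    batch <- min(remaining_budget,
                 max(500L, ceiling((target - n_acc) / p_hat * 1.3)))
    attempts <- attempts + batch
    g_idx <- sample.int(ng, batch, replace = TRUE)
    for (gi in sort(unique(g_idx))) {
      rows <- which(g_idx == gi)
      k <- length(rows)
      d <- wsplit[[gi]]
      m <- nrow(d)
      H4 <- matrix(stats::rbinom(4L * k * m, 1L, rep(d$maf, each = 4L * k)),
                   nrow = 4L * k)
      E <- as.numeric(H4 %*% d$weight)
      Em1 <- E[seq_len(k)]; Em2 <- E[k + seq_len(k)]
      Ef1 <- E[2L * k + seq_len(k)]; Ef2 <- E[3L * k + seq_len(k)]
      tp <- sample(c("m", "f"), k, replace = TRUE)   # transmitting parent
      ch <- sample.int(2L, k, replace = TRUE)        # carrier haplotype
      tm <- sample.int(2L, k, replace = TRUE)        # hap transmitted by mother
      tf <- sample.int(2L, k, replace = TRUE)        # hap transmitted by father
      inherited <- ifelse(tp == "m", tm == ch, tf == ch)
      E_child_wt <- ifelse(tp == "m",
                           ifelse(tf == 1L, Ef1, Ef2),
                           ifelse(tm == 1L, Em1, Em2))
      E_parent_wt <- ifelse(tp == "m",
                            ifelse(ch == 1L, Em2, Em1),
                            ifelse(ch == 1L, Ef2, Ef1))
      eps_c <- stats::rnorm(k, 0, config$noise_sd)
      eps_p <- stats::rnorm(k, 0, config$noise_sd)
      p_child <- stats::plogis(alpha + beta * (mu_hap[gi] - (E_child_wt + eps_c)))
      p_parent <- stats::plogis(alpha + beta * (mu_hap[gi] - (E_parent_wt + eps_p)))
      child_aff <- stats::rbinom(k, 1L, p_child) == 1L
      parent_aff <- stats::rbinom(k, 1L, p_parent) == 1L
      keep <- which(child_aff & inherited & !parent_aff)
      for (i in keep) {
        n_acc <- n_acc + 1L
        acc_gene[n_acc] <- gi
        acc_haps[[n_acc]] <- H4[c(i, k + i, 2L * k + i, 3L * k + i), ,
                                drop = FALSE]
        acc_meta[[n_acc]] <- list(
          tp = tp[i], ch = ch[i], tm = tm[i], tf = tf[i],
          E_child_wt = E_child_wt[i], E_parent_wt = E_parent_wt[i],
          p_child = p_child[i], p_parent = p_parent[i])
      }
    }
  }
  acc_gene <- acc_gene[seq_len(target)]
  acc_haps <- acc_haps[seq_len(target)]
  acc_meta <- acc_meta[seq_len(target)]

  # stage 2: fill in every gene for the accepted trios
  n <- target
  fam <- sprintf("T%04d", seq_len(n))
  iid_child <- paste0(fam, ".p")
  iid_mother <- paste0(fam, ".mo")
  iid_father <- paste0(fam, ".fa")
  hap_ids <- as.vector(t(cbind(paste0(iid_child, "|1"), paste0(iid_child, "|2"),
                               paste0(iid_mother, "|1"), paste0(iid_mother, "|2"),
                               paste0(iid_father, "|1"), paste0(iid_father, "|2"))))
  V <- nrow(weights)
  H <- matrix(0L, nrow = 6L * n, ncol = V,
              dimnames = list(hap_ids, weights$variant_id))
  row0 <- (seq_len(n) - 1L) * 6L   # per-trio row offset

  tp_v <- vapply(acc_meta, `[[`, character(1), "tp")
  ch_v <- vapply(acc_meta, `[[`, integer(1), "ch")
  col_of <- match(weights$variant_id, colnames(H))  # identity, kept for clarity
  gene_cols <- split(col_of, weights$gene)[genes]
  tm_all <- matrix(NA_integer_, nrow = n, ncol = ng)
  tf_all <- matrix(NA_integer_, nrow = n, ncol = ng)

  for (gi in seq_len(ng)) {
    d <- wsplit[[gi]]
    m <- nrow(d)
    cols <- gene_cols[[gi]]
    Hm1 <- matrix(stats::rbinom(n * m, 1L, rep(d$maf, each = n)), nrow = n)
    Hm2 <- matrix(stats::rbinom(n * m, 1L, rep(d$maf, each = n)), nrow = n)
    Hf1 <- matrix(stats::rbinom(n * m, 1L, rep(d$maf, each = n)), nrow = n)
    Hf2 <- matrix(stats::rbinom(n * m, 1L, rep(d$maf, each = n)), nrow = n)
    tm_g <- sample.int(2L, n, replace = TRUE)
    tf_g <- sample.int(2L, n, replace = TRUE)
    at_variant_gene <- which(acc_gene == gi)
    for (t in at_variant_gene) {
      Hm1[t, ] <- acc_haps[[t]][1L, ]; Hm2[t, ] <- acc_haps[[t]][2L, ]
      Hf1[t, ] <- acc_haps[[t]][3L, ]; Hf2[t, ] <- acc_haps[[t]][4L, ]
      tm_g[t] <- acc_meta[[t]]$tm; tf_g[t] <- acc_meta[[t]]$tf
    }
    child1 <- ifelse(tm_g == 1L, 1L, 0L)
    Hc1 <- Hm1 * child1 + Hm2 * (1L - child1)
    child2 <- ifelse(tf_g == 1L, 1L, 0L)
    Hc2 <- Hf1 * child2 + Hf2 * (1L - child2)
    H[row0 + 1L, cols] <- Hc1
    H[row0 + 2L, cols] <- Hc2
    H[row0 + 3L, cols] <- Hm1
    H[row0 + 4L, cols] <- Hm2
    H[row0 + 5L, cols] <- Hf1
    H[row0 + 6L, cols] <- Hf2
    # kept for secondary variant placement (multi_variant_prob)
    tm_all[, gi] <- tm_g
    tf_all[, gi] <- tf_g
  }

  pedigree <- data.frame(
    fid = rep(fam, each = 3L),
    iid = as.vector(rbind(iid_child, iid_mother, iid_father)),
    father = as.vector(rbind(iid_father, "0", "0")),
    mother = as.vector(rbind(iid_mother, "0", "0")),
    sex = as.vector(rbind(sample(1:2, n, replace = TRUE), 2L, 1L)),
    phenotype = as.vector(rbind(2L, 1L, 1L)),
    stringsAsFactors = FALSE
  )

  parent_iid <- ifelse(tp_v == "m", iid_mother, iid_father)
  inheritance <- ifelse(tp_v == "m", "maternal", "paternal")
  child_carrier_slot <- ifelse(tp_v == "m", 1L, 2L)
  rare_variants <- data.frame(
    trio = fam,
    proband = iid_child,
    gene = genes[acc_gene],
    inheritance = inheritance,
    parent = parent_iid,
    parent_carrier_hap = paste0(parent_iid, "|", ch_v),
    child_carrier_hap = paste0(iid_child, "|", child_carrier_slot),
    child_wt_hap = paste0(iid_child, "|", 3L - child_carrier_slot),
    parent_wt_hap = paste0(parent_iid, "|", 3L - ch_v),
    primary = TRUE,
    stringsAsFactors = FALSE
  )

  if (config$multi_variant_prob > 0 && ng > 1L) {
    extra <- which(stats::runif(n) < config$multi_variant_prob)
    if (length(extra) > 0) {
      rows <- lapply(extra, function(t) {
        other <- setdiff(seq_len(ng), acc_gene[t])
        g2 <- other[sample.int(length(other), 1L)]
        p2 <- sample(c("m", "f"), 1L)
        # place on the haplotype the parent transmitted for that gene, so the
        # child carries it too (inherited secondary variant)
        ch2 <- if (p2 == "m") tm_all[t, g2] else tf_all[t, g2]
        piid <- if (p2 == "m") iid_mother[t] else iid_father[t]
        slot <- if (p2 == "m") 1L else 2L
        data.frame(trio = fam[t], proband = iid_child[t], gene = genes[g2],
                   inheritance = if (p2 == "m") "maternal" else "paternal",
                   parent = piid,
                   parent_carrier_hap = paste0(piid, "|", ch2),
                   child_carrier_hap = paste0(iid_child[t], "|", slot),
                   child_wt_hap = paste0(iid_child[t], "|", 3L - slot),
                   parent_wt_hap = paste0(piid, "|", 3L - ch2),
                   primary = FALSE, stringsAsFactors = FALSE)
      })
      rare_variants <- rbind(rare_variants, do.call(rbind, rows))
      rare_variants <- rare_variants[order(rare_variants$trio,
                                           !rare_variants$primary), ]
      rownames(rare_variants) <- NULL
    }
  }

  cohort <- structure(list(
    haplotypes = H,
    pedigree = pedigree,
    variants = data.frame(variant_id = weights$variant_id,
                          chrom = weights$chrom, pos = weights$pos,
                          ref = weights$ref, alt = weights$alt,
                          maf = weights$maf, stringsAsFactors = FALSE),
    rare_variants = rare_variants,
    tissue = weights$tissue[1]
  ), class = "trio_cohort")

  truth <- list(
    trios = data.frame(
      trio = fam,
      gene = genes[acc_gene],
      transmitting_parent = parent_iid,
      carrier_haplotype = rare_variants$parent_carrier_hap[
        match(fam, rare_variants$trio[rare_variants$primary])],
      child_E_wt = vapply(acc_meta, `[[`, numeric(1), "E_child_wt"),
      parent_E_wt = vapply(acc_meta, `[[`, numeric(1), "E_parent_wt"),
      child_liability = vapply(acc_meta, `[[`, numeric(1), "p_child"),
      parent_liability = vapply(acc_meta, `[[`, numeric(1), "p_parent"),
      stringsAsFactors = FALSE
    ),
    attempts = attempts,
    config = config
  )

  list(cohort = cohort, truth = truth)
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("trio_cohort: %d trios, %d variants, tissue %s\n",
              nrow(x$pedigree) / 3L, ncol(x$haplotypes), x$tissue))
  invisible(x)
}

#' Collapse a phased trio cohort to unphased genotype dosages
#'
#' @param cohort A `trio_cohort`.
#' @return Integer matrix, individuals x variants, values 0/1/2.
#' @export
trio_genotypes <- function(cohort) {
  H <- cohort$haplotypes
  iid <- sub("\\|[12]$", "", rownames(H))
  G <- H[seq(1, nrow(H), by = 2), , drop = FALSE] +
    H[seq(2, nrow(H), by = 2), , drop = FALSE]
  rownames(G) <- unique(iid)
  G
}
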