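#' Simulate an unrelated case/control cohort for the TWAS scan
#'
#' Draws unrelated genotypes under Hardy-Weinberg from the weight table's
#' MAFs, computes each individual's predicted expression under the true
#' weights, and assigns affection Bernoulli with logit
#' `baseline_logit + sum_g gamma * (E_g + eps_g - mu_g)` over the configured
#' effect genes (the first `n_effect_genes` genes of the weight set;
#' `gamma = twas_effect`, `eps_g ~ N(0, noise_sd)`). Individuals are drawn
#' until `n_cases` cases and `n_controls` controls are collected. A matrix
#' of `n_covariates` standard-normal nuisance columns is emitted alongside.
#'
#' @param config A [sim_config()].
#' @param weights An `eqtl_weights` table with the generator `maf` column.
#' @return A list: `dosages` (individuals x variants, 0/1/2, with a
#'   `variants` attribute carrying ref/alt/MAF metadata), `status` (0/1,
#'   cases first), `covariates`, and `truth` (effect genes, gamma, per-gene
#'   population means).
#' @export
simulate_case_control <- function(config, weights) {
  validate_sim_config(config)
  if (is.null(weights) || nrow(weights) == 0) {
    stop("weights must be a non-empty eqtl_weights table")
  }
  if (is.null(weights$maf)) stop("weights table lacks the generator 'maf' column")
  set.seed(sim_seed(config, "casecontrol"))

  genes <- unique(weights$gene)
  ng <- length(genes)
  V <- nrow(weights)
  W <- matrix(0, nrow = V, ncol = ng, dimnames = list(weights$variant_id, genes))
  W[cbind(seq_len(V), match(weights$gene, genes))] <- weights$weight
  mu_ind <- 2 * hap_expr_mean(weights)   # individual-level mean = 2 x haplotype mean
  n_eff <- min(config$n_effect_genes, ng)
  effect_genes <- genes[seq_len(n_eff)]
  gamma <- config$twas_effect

  need_cases <- config$n_cases
  need_controls <- config$n_controls
  case_rows <- list()
  control_rows <- list()
  drawn <- 0L
  while (need_cases > 0L || need_controls > 0L) {
    if (drawn >= config$max_attempts) {
      stop(sprintf(
        paste0("case/control sampling failed: still need %d cases and %d ",
               "controls after %d draws (max_attempts = %d)"),
        need_cases, need_controls, drawn, config$max_attempts), call. = FALSE)
    }
    batch <- min(config$max_attempts - drawn,
                 max(500L, 3L * (need_cases + need_controls)))
    drawn <- drawn + batch
    G <- matrix(stats::rbinom(batch * V, 2L, rep(weights$maf, each = batch)),
                nrow = batch)
    colnames(G) <- weights$variant_id
    eta <- rep(config$baseline_logit, batch)
    if (n_eff > 0L && gamma != 0) {
      E <- G %*% W[, effect_genes, drop = FALSE]
      for (j in seq_len(n_eff)) {
        eps <- stats::rnorm(batch, 0, config$noise_sd)
        eta <- eta + gamma * (E[, j] + eps - mu_ind[effect_genes[j]])
      }
    }
    y <- stats::rbinom(batch, 1L, stats::plogis(eta))
    ci <- which(y == 1L)[seq_len(min(sum(y == 1L), need_cases))]
    ui <- which(y == 0L)[seq_len(min(sum(y == 0L), need_controls))]
    if (length(ci) > 0L) {
      case_rows[[length(case_rows) + 1L]] <- G[ci, , drop = FALSE]
      need_cases <- need_cases - length(ci)
    }
    if (length(ui) > 0L) {
      control_rows[[length(control_rows) + 1L]] <- G[ui, , drop = FALSE]
      need_controls <- need_controls - length(ui)
    }
  }
  dosages <- rbind(do.call(rbind, case_rows), do.call(rbind, control_rows))
  n_total <- nrow(dosages)
  rownames(dosages) <- sprintf("S%05d", seq_len(n_total))
  attr(dosages, "variants") <- data.frame(
    variant_id = weights$variant_id, chrom = weights$chrom, pos = weights$pos,
    ref = weights$ref, alt = weights$alt, maf = weights$maf,
    stringsAsFactors = FALSE)
  status <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
  names(status) <- rownames(dosages)
  covariates <- if (config$n_covariates > 0L) {
    matrix(stats::rnorm(n_total * config$n_covariates),
           nrow = n_total,
           dimnames = list(rownames(dosages),
                           sprintf("PC%d", seq_len(config$n_covariates))))
  } else {
    matrix(numeric(0), nrow = n_total, ncol = 0,
           dimnames = list(rownames(dosages), NULL))
  }
  list(
    dosages = dosages,
    status = status,
    covariates = covariates,
    truth = list(effect_genes = effect_genes, gamma = gamma,
                 mu_individual = mu_ind, draws = drawn)
  )
}
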