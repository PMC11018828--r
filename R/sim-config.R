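#' Simulation configuration
#'
#' Bundles and validates the generative parameters used by
#' [simulate_eqtl_models()], [simulate_trio_cohort()] and
#' [simulate_case_control()]. The generative model is a liability model in
#' which lower predicted expression of the wild-type (non-variant-carrying)
#' haplotype increases the penetrance of a rare damaging variant: the
#' affection log-odds of an individual are
#' `baseline_logit + penetrance_effect * (mu - (E_wt + eps))`, where `E_wt`
#' is the predicted expression of that individual's wild-type haplotype for
#' the variant gene, `mu` is the population mean haplotype expression of the
#' gene, and `eps ~ N(0, noise_sd)` is environmental noise on the expression
#' scale.
#'
#' Reproducibility: `seed` is a single master seed; each generator derives
#' its own stream by a fixed offset (`+101` for weight models, `+202` for
#' trio cohorts, `+303` for case/control cohorts), so the three generators
#' can be called in any order without perturbing one another.
#'
#' @param n_genes Number of genes with cis-eQTL weight models.
#' @param snps_per_gene Number of cis-SNPs per gene model.
#' @param maf_range Length-2 vector, minor allele frequency range in
#'   (0, 0.5]; per-variant MAFs are drawn uniformly from it.
#' @param weight_sd SD of the zero-mean normal from which per-variant
#'   expression weights are drawn (expression units per alt allele).
#' @param noise_sd SD of environmental noise added to the wild-type
#'   haplotype expression inside the liability (expression units).
#' @param n_trios_target Number of ascertained trios to emit.
#' @param n_cases,n_controls Case/control cohort sizes.
#' @param baseline_logit Baseline affection log-odds (alpha). Interpreted on
#'   the risk scale of families segregating a damaging variant, not as a
#'   population prevalence.
#' @param penetrance_effect Liability effect (beta) per unit of wild-type
#'   haplotype expression deficit; `0` recovers the null exactly.
#' @param twas_effect Liability effect (gamma) per unit of total predicted
#'   expression for case/control effect genes.
#' @param n_effect_genes Number of genes carrying `twas_effect` in
#'   [simulate_case_control()] (the first genes of the weight set).
#' @param n_covariates Number of standard-normal nuisance covariate columns
#'   emitted with the case/control cohort.
#' @param multi_variant_prob Probability that an ascertained trio receives a
#'   second inherited rare variant in another gene (exercises
#'   [select_unique_pairs()]); the second variant does not feed back into
#'   ascertainment.
#' @param max_attempts Bound on candidate trios (or case/control draws)
#'   examined before ascertainment is declared failed.
#' @param seed Master integer seed.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 2, snps_per_gene = 3, seed = 1)
sim_config <- function(n_genes = 25,
                       snps_per_gene = 10,
                       maf_range = c(0.05, 0.5),
                       weight_sd = 0.2,
                       noise_sd = 0.1,
                       n_trios_target = 200,
                       n_cases = 500,
                       n_controls = 500,
                       baseline_logit = -2,
                       penetrance_effect = 1,
                       twas_effect = 1,
                       n_effect_genes = 1,
                       n_covariates = 10,
                       multi_variant_prob = 0,
                       max_attempts = 10000 * n_trios_target,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    snps_per_gene = as.integer(snps_per_gene),
    maf_range = as.numeric(maf_range),
    weight_sd = as.numeric(weight_sd),
    noise_sd = as.numeric(noise_sd),
    n_trios_target = as.integer(n_trios_target),
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    baseline_logit = as.numeric(baseline_logit),
    penetrance_effect = as.numeric(penetrance_effect),
    twas_effect = as.numeric(twas_effect),
    n_effect_genes = as.integer(n_effect_genes),
    n_covariates = as.integer(n_covariates),
    multi_variant_prob = as.numeric(multi_variant_prob),
    max_attempts = as.integer(max_attempts),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  if (is.na(cfg$n_genes) || cfg$n_genes < 1L) stop_cfg("n_genes must be >= 1")
  if (is.na(cfg$snps_per_gene) || cfg$snps_per_gene < 1L) {
    stop_cfg("snps_per_gene must be >= 1")
  }
  if (length(cfg$maf_range) != 2L || any(is.na(cfg$maf_range)) ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop_cfg("maf_range must be an increasing pair within (0, 0.5]")
  }
  if (cfg$weight_sd < 0) stop_cfg("weight_sd must be >= 0")
  if (cfg$noise_sd < 0) stop_cfg("noise_sd must be >= 0")
  if (cfg$n_trios_target < 1L) stop_cfg("n_trios_target must be >= 1")
  if (cfg$n_cases < 1L) stop_cfg("n_cases must be >= 1")
  if (cfg$n_controls < 1L) stop_cfg("n_controls must be >= 1")
  if (cfg$n_covariates < 0L) stop_cfg("n_covariates must be >= 0")
  if (cfg$n_effect_genes < 0L) stop_cfg("n_effect_genes must be >= 0")
  if (cfg$multi_variant_prob < 0 || cfg$multi_variant_prob > 1) {
    stop_cfg("multi_variant_prob must be in [0, 1]")
  }
  if (cfg$max_attempts < 1L) stop_cfg("max_attempts must be >= 1")
  if (is.na(cfg$seed)) stop_cfg("seed must be a finite integer")
  invisible(cfg)
}

# fixed per-component seed stream offsets (documented in ?sim_config)
.seed_offsets <- c(models = 101L, trios = 202L, casecontrol = 303L)

sim_seed <- function(cfg, component) {
  cfg$seed + .seed_offsets[[component]]
}
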