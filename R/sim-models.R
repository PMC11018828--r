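#' Simulate per-gene cis-eQTL weight models
#'
#' Fabricates a sparse linear expression model per gene: `snps_per_gene`
#' cis-variants with MAFs drawn uniformly from `maf_range` and weights drawn
#' from a zero-mean normal with sd `weight_sd`, plus a synthetic per-gene
#' cross-validation p value (Beta(0.5, 10), right-skewed so that most but
#' not all genes pass the conventional 0.05 filter). Variant ids are
#' `chrom:pos:ref:alt` and unique genome-wide; alleles are fixed to the
#' non-palindromic pair A/G so that simulated variants survive array QC.
#'
#' @param config A [sim_config()].
#' @param tissue Tissue label attached to every model.
#' @return An `eqtl_weights` data frame with columns `gene`, `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `weight`, `cv_p`, `tissue` and the
#'   generator-metadata column `maf`.
#' @export
#' @examples
#' w <- simulate_eqtl_models(sim_config(n_genes = 2, snps_per_gene = 3), "whole_blood")
simulate_eqtl_models <- function(config, tissue = "whole_blood") {
  validate_sim_config(config)
  set.seed(sim_seed(config, "models"))
  ng <- config$n_genes
  m <- config$snps_per_gene
  gene <- sprintf("G%04d", seq_len(ng))
  chrom <- as.character(((seq_len(ng) - 1L) %% 22L) + 1L)
  pos <- as.integer(rep(seq_len(ng), each = m) * 1e6L +
                      rep(seq_len(m), times = ng) * 1000L)
  df <- data.frame(
    gene = rep(gene, each = m),
    variant_id = NA_character_,
    chrom = rep(chrom, each = m),
    pos = pos,
    ref = "A",
    alt = "G",
    weight = stats::rnorm(ng * m, mean = 0, sd = config$weight_sd),
    cv_p = rep(stats::rbeta(ng, 0.5, 10), each = m),
    tissue = tissue,
    maf = stats::runif(ng * m, config$maf_range[1], config$maf_range[2]),
    stringsAsFactors = FALSE
  )
  df$variant_id <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  stopifnot(!anyDuplicated(df$variant_id))
  class(df) <- c("eqtl_weights", "data.frame")
  df
}

#' @export
print.eqtl_weights <- function(x, ...) {
  cat(sprintf("eqtl_weights: %d genes, %d variants, tissue(s): %s\n",
              length(unique(x$gene)), nrow(x),
              paste(unique(x$tissue), collapse = ", ")))
  NextMethod()
}

# mean expression of one haplotype per gene under the generative model:
# E[sum w * h] = sum w * maf (haplotype alleles ~ Bernoulli(maf))
hap_expr_mean <- function(weights) {
  vapply(split(weights$weight * weights$maf, weights$gene), sum, numeric(1))
}

#' Write and read eQTL weight tables
#'
#' Tab-separated tables with columns `gene`, `variant_id`, `chrom`, `pos`,
#' `ref`, `alt`, `weight`, `cv_p`, `tissue` (PredictDB-style flat export).
#' Extra columns (e.g. the generator's `maf`) round-trip unchanged.
#'
#' @param weights An `eqtl_weights` data frame.
#' @param path File path.
#' @return `read_weights()` returns an `eqtl_weights` data frame;
#'   `write_weights()` returns `path` invisibly.
#' @export
write_weights <- function(weights, path) {
  utils::write.table(as.data.frame(weights), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  required <- c("gene", "variant_id", "chrom", "pos", "ref", "alt",
                "weight", "cv_p", "tissue")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("weight table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df[, c("gene", "variant_id")])) {
    stop("duplicated (gene, variant_id) pairs in weight table")
  }
  if (any(!is.finite(df$weight))) stop("non-finite weights in weight table")
  if (any(df$cv_p < 0 | df$cv_p > 1)) stop("cv_p outside [0, 1]")
  class(df) <- c("eqtl_weights", "data.frame")
  df
}
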