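#' Filter weight models on cross-validation performance
#'
#' Retains genes whose cross-validation adjusted p value is strictly below
#' `cv_p_max` (and, optionally, whose cross-validation correlation exceeds
#' `cv_r_min` when a `cv_r` column is present — some weight providers report
#' an r > 0.1 and p < 0.05 rule instead of p alone).
#'
#' @param weights An `eqtl_weights` table.
#' @param cv_p_max Keep genes with `cv_p < cv_p_max`; in (0, 1].
#' @param cv_r_min Optional: additionally require `cv_r > cv_r_min`.
#' @return The filtered `eqtl_weights` table.
#' @export
#' @examples
#' w <- simulate_eqtl_models(sim_config(n_genes = 5, snps_per_gene = 2))
#' filter_models(w, 0.05)
filter_models <- function(weights, cv_p_max = 0.05, cv_r_min = NULL) {
  stopifnot(is.numeric(cv_p_max), length(cv_p_max) == 1L,
            cv_p_max > 0, cv_p_max <= 1)
  keep <- weights$cv_p < cv_p_max
  if (!is.null(cv_r_min)) {
    if (is.null(weights$cv_r)) stop("cv_r_min given but weights has no cv_r column")
    keep <- keep & weights$cv_r > cv_r_min
  }
  out <- weights[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_kept <- length(unique(out$gene))
  n_in <- length(unique(weights$gene))
  message(sprintf("filter_models: retained %d of %d genes (cv_p < %g)",
                  n_kept, n_in, cv_p_max))
  if (nrow(out) == 0) warning("no genes pass the cross-validation filter")
  class(out) <- c("eqtl_weights", "data.frame")
  out
}

# shared linear predictor: rows of `mat` (samples or haplotypes) x weight
# models; returns matrix + coverage, dropping genes with no matched variants
apply_weights <- function(mat, weights, allow_flip = FALSE) {
  if (is.null(colnames(mat))) stop("dosage matrix must have variant_id colnames")
  vmeta <- attr(mat, "variants")
  if (!is.null(vmeta)) {
    m <- match(colnames(mat), vmeta$variant_id)
    have <- !is.na(m)
    wm <- match(colnames(mat)[have], weights$variant_id)
    cmp <- !is.na(wm)
    idx_mat <- which(have)[cmp]
    idx_w <- wm[cmp]
    flipped <- vmeta$ref[m[have]][cmp] == weights$alt[idx_w] &
      vmeta$alt[m[have]][cmp] == weights$ref[idx_w]
    if (any(flipped)) {
      if (!allow_flip) {
        stop(sprintf(
          "ref/alt mismatch for %d variant(s) (e.g. %s); rerun with allow_flip = TRUE",
          sum(flipped), colnames(mat)[idx_mat[which(flipped)[1]]]))
      }
      top <- if (all(mat %in% c(0, 1))) 1 else 2  # haplotypes vs dosages
      mat[, idx_mat[flipped]] <- top - mat[, idx_mat[flipped], drop = FALSE]
      message(sprintf("apply_weights: flipped dosage coding for %d variant(s)",
                      sum(flipped)))
    }
  }
  genes <- unique(weights$gene)
  wsplit <- split(weights[, c("variant_id", "weight")], weights$gene)[genes]
  out <- matrix(NA_real_, nrow = nrow(mat), ncol = length(genes),
                dimnames = list(rownames(mat), genes))
  coverage <- stats::setNames(numeric(length(genes)), genes)
  for (g in seq_along(genes)) {
    d <- wsplit[[g]]
    idx <- match(d$variant_id, colnames(mat))
    found <- !is.na(idx)
    coverage[g] <- mean(found)
    if (!any(found)) next
    out[, g] <- mat[, idx[found], drop = FALSE] %*% d$weight[found]
  }
  dropped <- genes[coverage == 0]
  if (length(dropped) > 0) {
    message(sprintf("apply_weights: %d gene(s) with no matched variants omitted",
                    length(dropped)))
  }
  keep <- coverage > 0
  structure(out[, keep, drop = FALSE],
            coverage = coverage[keep], class = c("expression_matrix", "matrix"))
}

#' Predict genetically-determined gene expression from dosages
#'
#' For each gene, `E[i, g] = sum_v weight(g, v) * dosage(i, v)` over the
#' model variants present in the dosage data. Model variants absent from
#' the dosage data are dropped (not mean-imputed); the share of model
#' variants found is reported per gene as a `coverage` attribute, and genes
#' with no matched variant are omitted with a message. Predicted values are
#' interpretable as inverse quantile-normalised expression and are used raw
#' downstream (the penetrance tests are rank- or difference-based).
#'
#' @param dosages Numeric matrix, samples x variants, values in \[0, 2\],
#'   with variant ids as column names. An optional `variants` attribute
#'   (data frame with `variant_id`, `ref`, `alt`) enables allele checking:
#'   a ref/alt swap relative to the weight table is a hard error unless
#'   `allow_flip = TRUE`, in which case dosage is replaced by `2 - dosage`
#'   and the flip is logged.
#' @param weights An `eqtl_weights` table.
#' @param allow_flip Permit ref/alt flips (see above).
#' @return An `expression_matrix`: samples x genes with a per-gene
#'   `coverage` attribute.
#' @export
predict_expression <- function(dosages, weights, allow_flip = FALSE) {
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]")
  }
  apply_weights(dosages, weights, allow_flip = allow_flip)
}

#' Predict expression of individual phased haplotypes
#'
#' Applies the same linear model to phased haplotype alleles (values in
#' \{0, 1\}; rows are haplotypes, e.g. `"T0001.p|1"`). For any individual,
#' the two haplotype predictions sum to the unphased prediction.
#'
#' @param haplotypes Integer matrix of phased alleles in \{0, 1\},
#'   haplotypes x variants.
#' @inheritParams predict_expression
#' @return An `expression_matrix` keyed by haplotype id.
#' @export
predict_haplotype_expression <- function(haplotypes, weights, allow_flip = FALSE) {
  if (!all(haplotypes %in% c(0L, 1L))) {
    stop("haplotype input must be phased alleles in {0, 1}; got other values ",
         "(unphased dosages?)")
  }
  apply_weights(haplotypes, weights, allow_flip = allow_flip)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d genes (mean coverage %.2f)\n",
              nrow(x), ncol(x), mean(attr(x, "coverage"))))
  invisible(x)
}

#' Write / read an expression matrix as TSV
#'
#' Samples x genes, with sample ids in the first column. The per-gene
#' coverage fractions are written alongside as `<path>.coverage.tsv`.
#'
#' @param expr An `expression_matrix`.
#' @param path Output TSV path.
#' @return `read_expression()` returns the matrix (coverage attribute
#'   restored when the side-car file exists).
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(sample = rownames(expr), as.data.frame(unclass(expr)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cov <- attr(expr, "coverage")
  if (!is.null(cov)) {
    utils::write.table(data.frame(gene = names(cov), coverage = cov),
                       paste0(path, ".coverage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  covpath <- paste0(path, ".coverage.tsv")
  cov <- NULL
  if (file.exists(covpath)) {
    cd <- utils::read.delim(covpath, stringsAsFactors = FALSE)
    cov <- stats::setNames(cd$coverage, cd$gene)
  }
  structure(m, coverage = cov, class = c("expression_matrix", "matrix"))
}
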