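#' Within-family paired t-test of wild-type haplotype expression
#'
#' Tests whether unaffected transmitting parents have higher
#' genetically-predicted expression of the variant gene than their affected
#' children. On paired differences `d = parent_expr - child_expr`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom; the
#' one-sided p is for H1 `mean(d) > 0` (parent higher). The two-sided p and
#' a two-sided 95% t confidence interval on the mean difference are also
#' reported (reversed effects are conventionally quoted two-sided).
#'
#' @param pairs Data frame with numeric columns `parent_expr` and
#'   `child_expr`, one row per unique proband-parent-gene pair (enforce
#'   uniqueness upstream with [select_unique_pairs()]).
#' @param alternative `"parent_greater"` (default) or `"child_greater"`.
#' @return A list of class `paired_t_result`: `t`, `df`, `p_one_sided`,
#'   `p_two_sided`, `mean_diff`, `ci` (95%), `n`.
#' @export
#' @examples
#' family_paired_test(data.frame(parent_expr = c(1, .7, .9, 1.2),
#'                               child_expr = c(.6, .5, .8, .7)))
family_paired_test <- function(pairs,
                               alternative = c("parent_greater",
                                               "child_greater")) {
  alternative <- match.arg(alternative)
  d <- pairs$parent_expr - pairs$child_expr
  if (any(!is.finite(d))) stop("non-finite expression values in pairs")
  n <- length(d)
  if (n < 2) stop("paired test needs at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0) stop("degenerate input: all paired differences are identical")
  se <- s / sqrt(n)
  t <- mean(d) / se
  df <- n - 1
  p_one <- if (alternative == "parent_greater") {
    stats::pt(t, df, lower.tail = FALSE)
  } else {
    stats::pt(t, df, lower.tail = TRUE)
  }
  ci <- mean(d) + c(-1, 1) * stats::qt(0.975, df) * se
  structure(list(t = t, df = df,
                 p_one_sided = p_one,
                 p_two_sided = 2 * stats::pt(-abs(t), df),
                 mean_diff = mean(d), ci = ci, n = n,
                 alternative = alternative),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf(
    "paired t: n = %d, mean diff = %.4g [%.4g, %.4g], t = %.3f, one-sided p = %.3g (two-sided %.3g)\n",
    x$n, x$mean_diff, x$ci[1], x$ci[2], x$t, x$p_one_sided, x$p_two_sided))
  invisible(x)
}

#' Wild-type haplotype expression for trio proband-parent pairs
#'
#' For each rare-variant placement in a simulated (or equivalently
#' structured) trio cohort, predicts the expression of the child's and the
#' transmitting parent's wild-type (non-carrier) haplotype for the variant
#' gene, yielding the paired comparison consumed by
#' [family_paired_test()].
#'
#' @param cohort A `trio_cohort`.
#' @param weights An `eqtl_weights` table.
#' @param primary_only Use only the primary variant placement per trio
#'   (default TRUE).
#' @return Data frame: `proband`, `parent`, `gene`, `child_expr`,
#'   `parent_expr`, `diff`.
#' @export
trio_pair_expression <- function(cohort, weights, primary_only = TRUE) {
  rv <- cohort$rare_variants
  if (primary_only) rv <- rv[rv$primary, , drop = FALSE]
  hap_ids <- unique(c(rv$child_wt_hap, rv$parent_wt_hap))
  H <- cohort$haplotypes[hap_ids, , drop = FALSE]
  E <- suppressMessages(predict_haplotype_expression(H, weights))
  gi <- match(rv$gene, colnames(E))
  if (anyNA(gi)) stop("rare-variant gene(s) absent from the weight models")
  child_expr <- E[cbind(match(rv$child_wt_hap, rownames(E)), gi)]
  parent_expr <- E[cbind(match(rv$parent_wt_hap, rownames(E)), gi)]
  data.frame(proband = rv$proband, parent = rv$parent, gene = rv$gene,
             child_expr = child_expr, parent_expr = parent_expr,
             diff = parent_expr - child_expr, stringsAsFactors = FALSE)
}

#' Percentile ranks on a 0-100 scale
#'
#' Mean ranks for ties; `percentile = 100 * (rank - 0.5) / N`. With this
#' convention a complete untied control set has mean percentile exactly 50.
#' The transform is invariant to any strictly monotone transform of the
#' input.
#'
#' @param x Numeric vector (pooled carriers + controls for one gene).
#' @return Numeric vector of percentiles, names preserved.
#' @export
#' @examples
#' percentile_ranks(c(a = 1, b = 2, c = 2, d = 10))
percentile_ranks <- function(x) {
  if (length(x) < 2) stop("percentile ranks need at least 2 values")
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Pool per-gene percentile ranks of carriers and controls
#'
#' For each gene with at least one carrier, ranks the pooled vector of
#' carrier and control predicted expression and keeps every individual's
#' percentile, with gene provenance. Each control contributes one rank per
#' gene, so the pooled size is
#' `n_carriers + n_genes * n_controls`.
#'
#' @param expr An `expression_matrix` covering carriers and controls.
#' @param carriers Data frame with `proband` and `gene` (one row per
#'   carrier-gene; typically [select_unique_pairs()] output).
#' @param control_ids Control row ids in `expr`.
#' @return Data frame: `id`, `gene`, `group` (`"case"`/`"control"`),
#'   `percentile`.
#' @export
build_rank_input <- function(expr, carriers, control_ids) {
  stopifnot(length(control_ids) > 0)
  genes <- unique(carriers$gene)
  rows <- lapply(genes, function(g) {
    probands <- carriers$proband[carriers$gene == g]
    ids <- c(probands, control_ids)
    ix <- match(ids, rownames(expr))
    if (anyNA(ix)) stop("ids missing from expression matrix for gene ", g)
    pct <- percentile_ranks(expr[ix, g])
    data.frame(id = ids, gene = g,
               group = c(rep("case", length(probands)),
                         rep("control", length(control_ids))),
               percentile = as.numeric(pct), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sided Wilcoxon rank test on pooled percentile ranks
#'
#' Mann-Whitney test of whether the case percentile distribution is
#' stochastically lower than the control one (default). Exact enumeration
#' when the pooled size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie and continuity correction. The method used
#' is recorded in the output.
#'
#' @param case_ranks,control_ranks Numeric vectors of pooled percentiles.
#' @param alternative `"cases_lower"` (default) or `"cases_higher"`.
#' @param exact_max Pooled size at or below which the exact path is used.
#' @return List: `U`, `p`, `method`, `n_cases`, `n_controls`.
#' @export
#' @examples
#' rank_wilcoxon(c(1, 2), c(3, 4, 5))  # exact p = 0.1
rank_wilcoxon <- function(case_ranks, control_ranks,
                          alternative = c("cases_lower", "cases_higher"),
                          exact_max = 20L) {
  alternative <- match.arg(alternative)
  stopifnot(length(case_ranks) > 0, length(control_ranks) > 0)
  n_tot <- length(case_ranks) + length(control_ranks)
  ties <- anyDuplicated(c(case_ranks, control_ranks)) > 0
  exact <- n_tot <= exact_max && !ties
  alt <- if (alternative == "cases_lower") "less" else "greater"
  wt <- suppressWarnings(
    stats::wilcox.test(case_ranks, control_ranks, alternative = alt,
                       exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approx",
       n_cases = length(case_ranks), n_controls = length(control_ranks))
}

#' Power of the one-sided paired t-test
#'
#' `power = P(T' > t_{1-alpha, n-1})` where `T'` is noncentral t with
#' `n - 1` degrees of freedom and noncentrality `d * sqrt(n)` (Cohen's d on
#' paired differences). The two-sided variant sums both rejection tails.
#'
#' @param d Effect size (Cohen's d of the paired differences).
#' @param n Number of pairs (>= 2).
#' @param alpha Significance level.
#' @param sided `"one"` (default) or `"two"`.
#' @return Power in \[0, 1\].
#' @export
#' @examples
#' paired_t_power(0.5, 30)             # one-sided
#' paired_t_power(0, 30)               # equals alpha
paired_t_power <- function(d, n, alpha = 0.05, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (sided == "one") {
    stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(-crit, df, ncp = ncp) +
      stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  }
}

#' Smallest number of pairs reaching a target power
#'
#' Bracketed integer search for the minimal `n` with
#' `paired_t_power(d, n, alpha, sided) >= target_power`.
#'
#' @inheritParams paired_t_power
#' @param target_power Target power in (alpha, 1).
#' @return Integer sample size.
#' @export
#' @examples
#' paired_t_sample_size(0.5, target_power = 0.8)
paired_t_sample_size <- function(d, alpha = 0.05, target_power = 0.8,
                                 sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (d == 0) stop("d = 0: no finite sample size reaches the target power")
  stopifnot(target_power > alpha, target_power < 1)
  lo <- 2L
  hi <- 2L
  while (paired_t_power(d, hi, alpha, sided) < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 1e8) stop("sample size search exceeded 1e8 pairs")
  }
  while (hi > lo + 1L) {
    mid <- (lo + hi) %/% 2L
    if (paired_t_power(d, mid, alpha, sided) >= target_power) hi <- mid else lo <- mid
  }
  if (paired_t_power(d, lo, alpha, sided) >= target_power) lo else hi
}
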