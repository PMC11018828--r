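#' Per-gene TWAS logistic scan
#'
#' For each gene, fits a maximum-likelihood logistic regression of
#' case/control status on predicted expression plus the supplied covariates
#' (typically the first 10 genotype principal components) and reports the
#' Wald test on the expression coefficient. Genes with constant expression,
#' non-converging fits or (quasi-)separation are flagged
#' (`converged = FALSE`) and carry no p value. A likelihood-ratio test is
#' available behind `test = "lrt"`.
#'
#' @param expr An `expression_matrix` (samples x genes).
#' @param status Binary vector (1 = case), aligned with `expr` rows.
#' @param covariates Numeric covariate matrix aligned with `expr` rows, or
#'   `NULL`.
#' @param test `"wald"` (default) or `"lrt"`.
#' @return Data frame: `gene`, `beta`, `se`, `z`, `p`, `n_cases`,
#'   `n_controls`, `converged`.
#' @export
twas_scan <- function(expr, status, covariates = NULL,
                      test = c("wald", "lrt")) {
  test <- match.arg(test)
  status <- as.numeric(status)
  if (nrow(expr) != length(status)) stop("expr rows and status must align")
  if (!all(status %in% c(0, 1))) stop("status must be binary 0/1")
  if (length(unique(status)) < 2) stop("status must contain both classes")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(status)) {
      stop("covariate rows and status must align")
    }
  }
  n_cases <- sum(status == 1)
  n_controls <- sum(status == 0)
  genes <- colnames(expr)
  res <- lapply(seq_along(genes), function(j) {
    x <- expr[, j]
    row <- data.frame(gene = genes[j], beta = NA_real_, se = NA_real_,
                      z = NA_real_, p = NA_real_, n_cases = n_cases,
                      n_controls = n_controls, converged = FALSE,
                      stringsAsFactors = FALSE)
    if (stats::sd(x) == 0 || anyNA(x)) return(row)
    X <- if (is.null(covariates)) cbind(expr = x) else cbind(expr = x, covariates)
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X), status, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
    cf <- fit$coefficients
    if (!fit$converged || anyNA(cf)) return(row)
    # Wald pieces from the information matrix at the converged estimate
    Xd <- cbind(1, X)
    mu <- stats::plogis(as.vector(Xd %*% cf))
    XtWX <- crossprod(Xd * sqrt(mu * (1 - mu)))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov)) return(row)
    se <- unname(sqrt(diag(cov))[2])
    beta <- unname(cf[2])
    if (!is.finite(se) || se > 1e3) return(row)  # separation guard
    row$beta <- beta
    row$se <- se
    row$z <- beta / se
    row$converged <- TRUE
    if (test == "wald") {
      row$p <- 2 * stats::pnorm(-abs(row$z))
    } else {
      fit0 <- suppressWarnings(
        stats::glm.fit(if (is.null(covariates)) matrix(1, length(status)) else
          cbind(1, covariates), status, family = stats::binomial(),
          control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
      row$p <- stats::pchisq(fit0$deviance - fit$deviance, df = 1,
                             lower.tail = FALSE)
    }
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 11338 + 11103)  # 2.23e-6
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1) {
    stop("n_tests must be a positive count")
  }
  alpha / n_tests
}

#' Outlier-expression enrichment test
#'
#' Per gene, computes the control-only mean and SD of predicted expression;
#' an individual is an outlier when its expression is more than
#' `k_sd` control SDs from the control mean (strict inequality). The
#' case/control x outlier/non-outlier 2x2 table is tested with a two-sided
#' Fisher's exact test. Genes with zero control SD are skipped with a
#' warning. The Bonferroni threshold over the tested genes is attached as
#' an attribute.
#'
#' @param expr An `expression_matrix` containing both groups.
#' @param case_ids,control_ids Row ids of cases and controls.
#' @param k_sd Outlier bound in control SDs (default 3).
#' @param genes Optional gene subset to test (e.g. a DD-gene list); default
#'   all columns.
#' @param alpha FWER for the attached Bonferroni threshold.
#' @return Data frame: `gene`, `control_mean`, `control_sd`,
#'   `n_case_outliers`, `n_case_total`, `n_control_outliers`,
#'   `n_control_total`, `fisher_p`; attribute `bonferroni`.
#' @export
outlier_enrichment <- function(expr, case_ids, control_ids, k_sd = 3,
                               genes = NULL, alpha = 0.05) {
  stopifnot(length(control_ids) > 0, length(case_ids) > 0)
  if (is.null(genes)) genes <- colnames(expr)
  genes <- intersect(genes, colnames(expr))
  ci <- match(case_ids, rownames(expr))
  ui <- match(control_ids, rownames(expr))
  if (anyNA(ci) || anyNA(ui)) stop("case/control ids missing from expr")
  rows <- lapply(genes, function(g) {
    xc <- expr[ci, g]
    xu <- expr[ui, g]
    mu <- mean(xu)
    s <- stats::sd(xu)
    if (is.na(s) || s == 0) {
      warning(sprintf("gene %s skipped: zero control SD", g))
      return(NULL)
    }
    out_c <- abs(xc - mu) > k_sd * s
    out_u <- abs(xu - mu) > k_sd * s
    tab <- matrix(c(sum(out_c), sum(!out_c), sum(out_u), sum(!out_u)), nrow = 2)
    p <- stats::fisher.test(tab)$p.value
    data.frame(gene = g, control_mean = mu, control_sd = s,
               n_case_outliers = sum(out_c), n_case_total = length(xc),
               n_control_outliers = sum(out_u), n_control_total = length(xu),
               fisher_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), control_mean = numeric(0),
                      control_sd = numeric(0), n_case_outliers = integer(0),
                      n_case_total = integer(0), n_control_outliers = integer(0),
                      n_control_total = integer(0), fisher_p = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "bonferroni") <- if (nrow(out) > 0)
    bonferroni_threshold(alpha, nrow(out)) else NA_real_
  out
}
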