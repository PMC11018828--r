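# Independent oracles used across the suite. Each re-derives the quantity by
# a different route than the implementation (explicit loops, closed forms,
# enumeration, quadrature), so agreement is evidence, not tautology.

# expression prediction by explicit per-term accumulation
oracle_predict_loop <- function(dosages, weights) {
  genes <- unique(weights$gene)
  out <- matrix(0, nrow(dosages), length(genes),
                dimnames = list(rownames(dosages), genes))
  for (i in seq_len(nrow(dosages))) {
    for (g in genes) {
      wg <- weights[weights$gene == g, ]
      acc <- 0
      n_found <- 0
      for (k in seq_len(nrow(wg))) {
        j <- which(colnames(dosages) == wg$variant_id[k])
        if (length(j) == 1) {
          acc <- acc + wg$weight[k] * dosages[i, j]
          n_found <- n_found + 1
        }
      }
      out[i, g] <- if (n_found > 0) acc else NA_real_
    }
  }
  out[, colSums(is.na(out)) < nrow(out), drop = FALSE]
}

# HWE exact p by direct closed-form enumeration over admissible het counts
oracle_hwe_enum <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  n_rare <- min(n_a, n_b)
  if (n_rare == 0) return(1)
  hets <- seq.int(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

# two-sided Fisher 2x2 p by hypergeometric summation
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Mendelian impossibility by enumerating actual parental allele multisets
oracle_mendel_impossible <- function(child, mother, father) {
  alleles <- function(g) switch(as.character(g), "0" = c(0, 0),
                                "1" = c(0, 1), "2" = c(1, 1))
  kids <- as.vector(outer(alleles(mother), alleles(father), `+`))
  !(child %in% kids)
}

# from-scratch Newton-Raphson (IRLS) logistic fit; X includes intercept
oracle_irls_logistic <- function(X, y, tol = 1e-13, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- crossprod(X, y - p)
    info <- crossprod(X * W, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  se <- sqrt(diag(solve(crossprod(X * (p * (1 - p)), X))))
  list(beta = beta, se = se)
}

# one-sided paired-t p by quadrature of the explicit t density
oracle_paired_t <- function(d) {
  n <- length(d)
  t_obs <- mean(d) / (sd(d) / sqrt(n))
  df <- n - 1
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  p_one <- integrate(dens, t_obs, Inf, rel.tol = 1e-12)$value
  list(t = t_obs, p_one = p_one,
       p_two = 2 * integrate(dens, abs(t_obs), Inf, rel.tol = 1e-12)$value)
}

# exact one-sided ("cases lower") Mann-Whitney p by enumeration of all
# assignments of the pooled ranks to the case group (untied input only)
oracle_wilcoxon_enum <- function(cases, controls) {
  pooled <- c(cases, controls)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  a <- length(cases)
  w_obs <- sum(r[seq_len(a)])
  combos <- combn(length(pooled), a)
  sums <- apply(combos, 2, function(ix) sum(r[ix]))
  mean(sums <= w_obs)
}

# percentile by explicit sort-and-count (mean rank for ties)
oracle_percentile <- function(x) {
  n <- length(x)
  vapply(x, function(v) {
    r <- sum(x < v) + (1 + sum(x == v)) / 2
    100 * (r - 0.5) / n
  }, numeric(1))
}

# small weight table builder for handcrafted cases
make_weights <- function(gene, variant_id, weight, cv_p = 0.01,
                         chrom = "1", pos = seq_along(variant_id),
                         ref = "A", alt = "G", tissue = "whole_blood",
                         maf = 0.2) {
  df <- data.frame(gene = gene, variant_id = variant_id, chrom = chrom,
                   pos = pos, ref = ref, alt = alt, weight = weight,
                   cv_p = cv_p, tissue = tissue, maf = maf,
                   stringsAsFactors = FALSE)
  class(df) <- c("eqtl_weights", "data.frame")
  df
}
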