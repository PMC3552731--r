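#' Principal components of the standardized genotype matrix
#'
#' Top-k principal-component scores of `Z` (already column-centered by
#' standardization), computed by singular value decomposition, orthogonal
#' and ordered by decreasing eigenvalue. Used as fixed covariates to correct
#' for population structure.
#'
#' @param std A `std_geno` from [impute_and_standardize()].
#' @param k Number of components (`k = 0` gives an n x 0 matrix; `k >= n`
#'   is an error).
#' @return n x k score matrix with line ids as row names.
#' @export
compute_pcs <- function(std, k = 10) {
  Z <- std$Z
  n <- nrow(Z)
  if (k >= n) abort("`k` must be smaller than the number of lines.")
  if (k == 0) {
    out <- matrix(0, n, 0)
    rownames(out) <- rownames(Z)
    return(out)
  }
  sv <- svd(Z, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(Z)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Partition genetic variance across chromosomes
#'
#' Fits the linear mixed model
#' `y = 1 mu + Q beta + sum_c g_c + e` with `g_c ~ N(0, G_c s2_gc)` and
#' `e ~ N(0, I s2_e)`, where `Q` holds the first principal components of the
#' SNP data (population-structure correction) and `G_c = Z_c Z_c'/p_c` is
#' the relationship matrix from chromosome c only. All 10 chromosome
#' components and the residual are estimated simultaneously by REML; the
#' share of genetic variance attributed to chromosome c is
#' `s2_gc / (sum_c s2_gc + s2_e)`. Chromosome kernels whose smallest
#' eigenvalue falls below `1e-8` are repaired to the nearest positive
#' definite matrix first.
#'
#' @param kernels List of per-chromosome [kernel_matrix()] objects (kind
#'   `chromosome_Gc`), one per chromosome, same line order as `trait`.
#' @param trait Trait tibble (`line_id`, `value`, ...) or numeric vector in
#'   kernel line order.
#' @param Q Optional n x k matrix of principal-component scores.
#' @param reml_tol,max_iter REML convergence settings.
#' @return Object of class `partition_result`: per-chromosome variance
#'   components and shares, residual variance, PC coefficients, restricted
#'   log-likelihood, convergence flag and the number of PD repairs.
#' @export
fit_partition <- function(kernels, trait, Q = NULL, reml_tol = 1e-6,
                          max_iter = 200) {
  stopifnot(length(kernels) >= 1)
  line_ids <- rownames(kernels[[1]]$values)
  y <- align_trait(trait, line_ids)
  n <- length(y)
  n_repairs <- 0
  kernels <- lapply(kernels, function(k) {
    ev_min <- min(eigen(k$values, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < 1e-8) {
      k <- repair_kernel(k, eig_floor = 1e-8)
      n_repairs <<- n_repairs + 1
    }
    k
  })
  X <- if (is.null(Q) || ncol(Q) == 0) matrix(1, n, 1) else cbind(1, Q)
  fit <- reml_multi(y, kernels, X = X, tol = reml_tol, max_iter = max_iter)
  total <- sum(fit$sigma2) + fit$sigma2_e
  chroms <- vapply(kernels, function(k) k$chromosome, integer(1))
  structure(
    list(
      chromosomes = chroms,
      sigma2_gc = fit$sigma2,
      sigma2_e = fit$sigma2_e,
      shares = fit$sigma2 / total,
      residual_share = fit$sigma2_e / total,
      beta = fit$beta,
      loglik = fit$loglik,
      converged = fit$converged,
      iterations = fit$iterations,
      n_pd_repairs = n_repairs,
      n_lines = n
    ),
    class = "partition_result"
  )
}

#' One-call genome partition from a panel and a trait
#'
#' Builds standardized genotypes, the 10 per-chromosome relationship
#' matrices and the principal-component correction, then calls
#' [fit_partition()].
#'
#' @param panel A QC'd [genotype_panel()].
#' @param trait Trait tibble or numeric vector.
#' @param n_pcs Number of principal components for structure correction
#'   (default 10).
#' @param ... Passed to [fit_partition()].
#' @return A `partition_result` with per-chromosome SNP counts attached.
#' @export
partition_genome <- function(panel, trait, n_pcs = 10, ...) {
  std <- impute_and_standardize(panel, drop_monomorphic = TRUE)
  chroms <- sort(unique(std$snp_map$chrom))
  kernels <- lapply(chroms, function(ch) build_grm(std, chromosome = ch))
  Q <- compute_pcs(std, k = n_pcs)
  res <- fit_partition(kernels, trait, Q = Q, ...)
  res$n_snps <- vapply(chroms, function(ch) sum(std$snp_map$chrom == ch), integer(1))
  res
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(
    "<partition_result> %d chromosomes, n = %d, %sconverged in %d iterations\n",
    length(x$chromosomes), x$n_lines, if (x$converged) "" else "NOT ", x$iterations
  ))
  cat(sprintf("  total genetic share = %.3f, residual share = %.3f, PD repairs = %d\n",
              sum(x$shares), x$residual_share, x$n_pd_repairs))
  print(tidy(x), n = 12)
  invisible(x)
}

#' @describeIn fit_partition Per-chromosome tibble: `chrom`, `sigma2_gc`,
#'   `share`, cumulative share, and SNP count when available.
#' @param x A `partition_result`.
#' @param ... Unused.
#' @export
tidy.partition_result <- function(x, ...) {
  out <- tibble(
    chrom = x$chromosomes,
    sigma2_gc = x$sigma2_gc,
    share = x$shares
  )
  out <- dplyr::arrange(out, .data$chrom)
  out$cumulative_share <- cumsum(out$share)
  if (!is.null(x$n_snps)) out$n_snps <- x$n_snps
  out
}

#' @describeIn fit_partition One-row summary: total genetic share, residual
#'   variance, log-likelihood, convergence.
#' @export
glance.partition_result <- function(x, ...) {
  tibble(
    n_lines = x$n_lines,
    n_chromosomes = length(x$chromosomes),
    total_genetic_share = sum(x$shares),
    sigma2_e = x$sigma2_e,
    loglik = x$loglik,
    converged = x$converged,
    iterations = x$iterations,
    n_pd_repairs = x$n_pd_repairs
  )
}

#' @export
autoplot.partition_result <- function(object, chrom_lengths = NULL, ...) {
  td <- tidy(object)
  if (!is.null(chrom_lengths)) {
    td$length_mb <- chrom_lengths[td$chrom] / 1e6
    return(
      ggplot2::ggplot(td, ggplot2::aes(x = .data$length_mb, y = .data$share)) +
        ggplot2::geom_point() +
        ggplot2::geom_text(ggplot2::aes(label = .data$chrom), vjust = -0.6, size = 3) +
        ggplot2::labs(x = "chromosome length (Mb)", y = "genetic variance share") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$chrom), y = .data$share)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "chromosome", y = "genetic variance share") +
    ggplot2::theme_minimal()
}

#' Regress chromosome variance shares on chromosome length
#'
#' Pearson correlation (with two-sided p-value) between chromosome length
#' and estimated genetic-variance share, excluding chromosomes that carry a
#' known QTL or association signal. A polygenic trait on a panel with SNP
#' counts proportional to length is expected to show a positive correlation:
#' longer chromosomes capture more genetic variance.
#'
#' @param result A `partition_result`.
#' @param chrom_lengths Numeric vector of chromosome lengths (bp), indexed
#'   by chromosome number.
#' @param exclude Chromosomes to drop before the regression.
#' @return One-row tibble with `r`, `p_value`, `n_chromosomes`.
#' @export
chromosome_length_regression <- function(result, chrom_lengths,
                                         exclude = integer(0)) {
  keep <- !(result$chromosomes %in% exclude)
  if (sum(keep) < 3) abort("need at least 3 chromosomes after exclusion.")
  shares <- result$shares[keep]
  lens <- chrom_lengths[result$chromosomes[keep]]
  if (sd(shares) == 0 || sd(lens) == 0) {
    abort("degenerate regression: shares or lengths are constant.")
  }
  ct <- stats::cor.test(lens, shares, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n_chromosomes = sum(keep))
}
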