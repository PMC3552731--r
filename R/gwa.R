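# align a trait table (line_id, value, h2) or plain vector to a line order
align_trait <- function(trait, line_ids) {
  if (is.numeric(trait)) {
    if (!is.null(names(trait)) && !is.null(line_ids)) {
      stopifnot(all(line_ids %in% names(trait)))
      return(unname(trait[line_ids]))
    }
    stopifnot(length(trait) == length(line_ids) || is.null(line_ids))
    return(as.numeric(trait))
  }
  stopifnot(is.data.frame(trait), all(c("line_id", "value") %in% names(trait)))
  idx <- match(line_ids, trait$line_id)
  if (anyNA(idx)) abort("trait table is missing some panel lines.")
  trait$value[idx]
}

trait_h2 <- function(trait, h2 = NULL) {
  if (!is.null(h2)) return(h2)
  if (is.data.frame(trait) && "h2" %in% names(trait)) {
    u <- unique(trait$h2)
    stopifnot(length(u) == 1)
    return(u)
  }
  abort("heritability `h2` is required (column in the trait table or argument).")
}

#' Single-marker mixed-model association scan (Q + K model)
#'
#' Two-step approximation: the variance components of the null model
#' `y = [1 Q] b + g + e`, `var(g) = K s2_g`, are estimated once by REML and
#' then held fixed while every SNP is tested by generalized least squares on
#' the whitened data (the population-parameters-previously-determined
#' shortcut used by EMMAX-style software). Wald p-values per SNP; the
#' Bonferroni threshold is `alpha / p`. Each SNP's "explained genetic
#' variance" is its squared dosage-phenotype correlation divided by the
#' trait heritability.
#'
#' @param std A `std_geno` from [impute_and_standardize()].
#' @param trait Trait tibble (`line_id`, `value`, `h2`) or numeric vector.
#' @param K Whole-genome [kernel_matrix()] from [build_grm()].
#' @param Q Optional PC score matrix from [compute_pcs()].
#' @param alpha Genome-wide significance level before Bonferroni correction
#'   (default 0.01).
#' @param h2 Heritability override (must be > 0 to compute explained genetic
#'   variance).
#' @return A tibble of class `gwa_result` with columns `snp_id`, `chrom`,
#'   `pos`, `beta`, `se`, `p`, `explained_gv` and attributes
#'   `bonferroni_threshold`, `h2`, `sigma2_g`, `sigma2_e`.
#' @export
gwa_scan <- function(std, trait, K, Q = NULL, alpha = 0.01, h2 = NULL) {
  Z <- std$Z
  n <- nrow(Z)
  y <- align_trait(trait, rownames(Z))
  h2 <- trait_h2(trait, h2)
  if (h2 <= 0) abort("h2 must be positive to compute explained genetic variance.")
  X <- if (is.null(Q) || ncol(Q) == 0) matrix(1, n, 1) else cbind(1, Q)

  null_fit <- reml_kernel(y, K, X = X)
  d <- pmax(null_fit$eig$values, 0)
  U <- null_fit$eig$vectors
  wt <- 1 / sqrt(null_fit$sigma2_g * d + null_fit$sigma2_e)

  yt <- wt * crossprod(U, y)
  Xt <- wt * crossprod(U, X)
  Zt <- wt * crossprod(U, Z)

  qr_x <- qr(Xt)
  ry <- qr.resid(qr_x, yt)
  Rz <- qr.resid(qr_x, Zt)

  znorm2 <- colSums(Rz^2)
  zy <- colSums(Rz * c(ry))
  df <- n - ncol(X) - 1
  ok <- znorm2 > 1e-12
  beta <- ifelse(ok, zy / znorm2, 0)
  rss <- sum(ry^2) - beta^2 * znorm2
  s2 <- pmax(rss, 0) / df
  se <- ifelse(ok, sqrt(s2 / znorm2), NA_real_)
  tstat <- ifelse(ok, beta / se, 0)
  p <- ifelse(ok, 2 * pt(-abs(tstat), df = df), 1)

  expl <- suppressWarnings(cor(Z, y)^2) / h2
  out <- tibble(
    snp_id = std$snp_map$snp_id,
    chrom = std$snp_map$chrom,
    pos = std$snp_map$pos,
    beta = beta,
    se = se,
    p = p,
    explained_gv = drop(expl)
  )
  structure(
    out,
    class = c("gwa_result", class(out)),
    bonferroni_threshold = alpha / ncol(Z),
    h2 = h2,
    sigma2_g = null_fit$sigma2_g,
    sigma2_e = null_fit$sigma2_e
  )
}

#' @export
autoplot.gwa_result <- function(object, ...) {
  df <- as_tibble(object)
  df$cum_pos <- df$pos
  offset <- 0
  for (ch in sort(unique(df$chrom))) {
    sel <- df$chrom == ch
    df$cum_pos[sel] <- df$pos[sel] + offset
    offset <- offset + max(df$pos[sel])
  }
  thr <- attr(object, "bonferroni_threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cum_pos / 1e6, y = -log10(.data$p),
                                   colour = factor(.data$chrom %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2, colour = "red") +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
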