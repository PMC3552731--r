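#' Kernel / relationship matrices
#'
#' Container for n x n symmetric kernel matrices with provenance: the
#' whole-genome relationship matrix `G = ZZ'/p`, a per-chromosome
#' `G_c = Z_c Z_c'/p_c`, or a Gaussian kernel on modified Rogers' distances.
#'
#' @param values Symmetric numeric matrix with line ids as dimnames.
#' @param kind One of `"inner_product_G"`, `"chromosome_Gc"`, `"gaussian_K"`.
#' @param chromosome Chromosome number for `chromosome_Gc` kernels.
#' @param theta Bandwidth for `gaussian_K` kernels.
#' @param psd_repaired Whether a positive-definiteness repair was applied.
#' @return An object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(values, kind, chromosome = NA_integer_,
                          theta = NA_real_, psd_repaired = FALSE) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-10) abort("kernel must be symmetric.")
  structure(
    list(values = values, kind = kind, chromosome = chromosome,
         theta = theta, psd_repaired = psd_repaired),
    class = "kernel_matrix"
  )
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> %s, %d x %d", x$kind, nrow(x$values), ncol(x$values)))
  if (!is.na(x$chromosome)) cat(sprintf(", chromosome %d", x$chromosome))
  if (!is.na(x$theta)) cat(sprintf(", theta = %.3g", x$theta))
  if (x$psd_repaired) cat(", PSD-repaired")
  cat("\n")
  invisible(x)
}

#' Genomic relationship matrix from standardized dosages
#'
#' `G = ZZ'/p` over all SNPs, or `G_c = Z_c Z_c'/p_c` restricted to one
#' chromosome. Because columns are standardized with the population sd, the
#' mean diagonal of the whole-genome G is exactly 1.
#'
#' @param std A `std_geno` from [impute_and_standardize()].
#' @param chromosome Optional chromosome (1-10) to restrict to.
#' @return A [kernel_matrix()].
#' @export
build_grm <- function(std, chromosome = NULL) {
  stopifnot(inherits(std, "std_geno"))
  Z <- std$Z
  if (!is.null(chromosome)) {
    cols <- which(std$snp_map$chrom == chromosome)
    if (!length(cols)) abort(sprintf("no SNPs on chromosome %s.", chromosome))
    Z <- Z[, cols, drop = FALSE]
  }
  G <- tcrossprod(Z) / ncol(Z)
  kernel_matrix(
    G,
    kind = if (is.null(chromosome)) "inner_product_G" else "chromosome_Gc",
    chromosome = if (is.null(chromosome)) NA_integer_ else as.integer(chromosome)
  )
}

#' Modified Rogers' distance between lines
#'
#' Euclidean distance between biallelic marker profiles scaled to `[0, 1]`:
#' `GD_ij = sqrt( sum_k (x_ik - x_jk)^2 / (4 p) )` with dosages `x` in
#' \{0, 1, 2\}. The normalizer 1/(4p) maps the maximal biallelic contrast
#' (homozygous for opposite alleles at every SNP) to exactly 1, and a
#' heterozygote contributes half the contrast of an opposite homozygote.
#'
#' @param panel A [genotype_panel()] or a complete dosage matrix. Missing
#'   values are mean-imputed first.
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
modified_rogers_distance <- function(panel) {
  x <- if (inherits(panel, "genotype_panel")) panel$dosages else panel
  if (anyNA(x)) {
    cm <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- cm[idx[, 2]]
  }
  p <- ncol(x)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  D <- sqrt(d2 / (4 * p))
  diag(D) <- 0
  D
}

#' Gaussian kernel on modified Rogers' distances
#'
#' `K_ij = exp(-GD_ij / theta^2)`; `theta` controls how fast relatedness
#' decays with genetic distance.
#'
#' @param D Distance matrix from [modified_rogers_distance()].
#' @param theta Positive bandwidth.
#' @return A [kernel_matrix()] of kind `gaussian_K`.
#' @export
gaussian_kernel <- function(D, theta) {
  stopifnot(theta > 0)
  kernel_matrix(exp(-D / theta^2), kind = "gaussian_K", theta = theta)
}

#' Nearest positive (semi)definite matrix
#'
#' Higham's alternating-projections algorithm (via [Matrix::nearPD()]) with
#' an explicit eigenvalue floor so the result is numerically positive
#' definite. An input whose smallest eigenvalue already exceeds the floor is
#' returned unchanged.
#'
#' @param M Symmetric matrix.
#' @param eig_floor Smallest admissible eigenvalue of the result.
#' @return Symmetric positive-definite matrix; attribute `repaired` records
#'   whether anything was changed.
#' @export
nearest_pd <- function(M, eig_floor = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-8) {
    abort("`M` must be a symmetric matrix.")
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= eig_floor) {
    attr(M, "repaired") <- FALSE
    return(M)
  }
  res <- Matrix::nearPD(M, corr = FALSE, keepDiag = FALSE,
                        eig.tol = 1e-10, conv.tol = 1e-9, posd.tol = 0)
  out <- as.matrix(res$mat)
  e <- eigen(out, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(M)
  attr(out, "repaired") <- TRUE
  out
}

#' Repair a kernel_matrix to positive definiteness if needed
#'
#' @param kernel A [kernel_matrix()].
#' @param eig_floor Eigenvalue floor passed to [nearest_pd()].
#' @return The (possibly repaired) `kernel_matrix` with `psd_repaired` set.
#' @export
repair_kernel <- function(kernel, eig_floor = 1e-8) {
  v <- nearest_pd(kernel$values, eig_floor)
  rep <- attr(v, "repaired")
  attr(v, "repaired") <- NULL
  kernel$values <- v
  kernel$psd_repaired <- kernel$psd_repaired || rep
  kernel
}

#' Linkage-disequilibrium decay profile
#'
#' Squared Pearson correlation of dosages for all intra-chromosomal SNP
#' pairs up to `max_dist_bp` apart, averaged within distance bins. Also
#' reports the mean adjacent-SNP r-squared.
#'
#' @param panel A [genotype_panel()].
#' @param max_dist_bp Maximum pair distance considered.
#' @param n_bins Number of equal-width distance bins.
#' @return An object of class `ld_profile`: list with `profile` (tibble:
#'   `dist_lo`, `dist_hi`, `dist_mid`, `mean_r2`, `n_pairs`) and
#'   `mean_adjacent_r2`.
#' @export
ld_r2_profile <- function(panel, max_dist_bp = 2e6, n_bins = 40) {
  map <- panel$snp_map
  d <- panel$dosages
  breaks <- seq(0, max_dist_bp, length.out = n_bins + 1)
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  adj_r2 <- c()
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    if (length(cols) < 2) next
    x <- d[, cols, drop = FALSE]
    pos <- map$pos[cols]
    cc <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
    r2 <- cc^2
    dist <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dist)
    dd <- dist[ut]
    rr <- r2[ut]
    ok <- dd <= max_dist_bp & !is.na(rr)
    bin <- findInterval(dd[ok], breaks, rightmost.closed = TRUE, left.open = TRUE)
    bin[bin == 0] <- 1
    for (b in unique(bin)) {
      sums[b] <- sums[b] + sum(rr[ok][bin == b])
      counts[b] <- counts[b] + sum(bin == b)
    }
    adj <- r2[cbind(seq_len(length(cols) - 1), 2:length(cols))]
    adj_r2 <- c(adj_r2, adj[!is.na(adj)])
  }
  profile <- tibble(
    dist_lo = breaks[-(n_bins + 1)],
    dist_hi = breaks[-1],
    dist_mid = (breaks[-(n_bins + 1)] + breaks[-1]) / 2,
    mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
    n_pairs = counts
  )
  structure(
    list(profile = profile, mean_adjacent_r2 = mean(adj_r2)),
    class = "ld_profile"
  )
}

#' @export
print.ld_profile <- function(x, ...) {
  cat(sprintf("<ld_profile> mean adjacent-SNP r2 = %.3f\n", x$mean_adjacent_r2))
  print(x$profile, n = 10)
  invisible(x)
}

#' @export
tidy.ld_profile <- function(x, ...) x$profile

#' Distance at which the LD profile crosses a given r-squared level
#'
#' Linear interpolation between the first pair of adjacent bins that
#' brackets the level.
#'
#' @param ld An `ld_profile` from [ld_r2_profile()].
#' @param level Target r-squared (default 0.1).
#' @return Distance in bp (`NA` if the profile never crosses the level).
#' @export
ld_decay_distance <- function(ld, level = 0.1) {
  pr <- ld$profile[!is.na(ld$profile$mean_r2) & ld$profile$n_pairs > 0, ]
  r2 <- pr$mean_r2
  dm <- pr$dist_mid
  below <- which(r2 < level)
  if (!length(below) || below[1] == 1) return(NA_real_)
  i <- below[1]
  j <- i - 1
  dm[j] + (r2[j] - level) / (r2[j] - r2[i]) * (dm[i] - dm[j])
}

#' @export
autoplot.ld_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$dist_mid / 1e3, y = .data$mean_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.1, linetype = 2, colour = "red") +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2),
                  title = "LD decay") +
    ggplot2::theme_minimal()
}
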