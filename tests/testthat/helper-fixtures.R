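# Fixtures and independent oracles used across the suite.
# Everything is generated in code; no stored data.

# tiny hand-rolled panel: n lines x p SNPs, homozygous unless stated
toy_panel <- function(n = 20, p = 8, seed = 42, chroms = NULL, pos = NULL) {
  set.seed(seed)
  d <- matrix(sample(c(0, 2), n * p, replace = TRUE, prob = c(0.6, 0.4)), n, p)
  # guarantee polymorphism
  for (j in seq_len(p)) {
    if (length(unique(d[, j])) == 1) d[1, j] <- 2 - d[1, j]
  }
  rownames(d) <- sprintf("L%02d", seq_len(n))
  colnames(d) <- sprintf("S%02d", seq_len(p))
  if (is.null(chroms)) chroms <- rep(1, p)
  if (is.null(pos)) {
    pos <- unlist(lapply(split(seq_len(p), chroms), seq_along)) * 1000
    pos <- pos[order(order(chroms))]  # increasing within chromosome
  }
  genotype_panel(d, data.frame(snp_id = colnames(d), chrom = chroms, pos = pos))
}

std_from_matrix <- function(Z, chroms = NULL) {
  p <- ncol(Z)
  if (is.null(colnames(Z))) colnames(Z) <- sprintf("S%02d", seq_len(p))
  if (is.null(rownames(Z))) rownames(Z) <- sprintf("L%02d", seq_len(nrow(Z)))
  if (is.null(chroms)) chroms <- rep(1, p)
  structure(
    list(
      Z = Z,
      col_means = rep(1, p),
      col_sds = rep(1, p),
      snp_map = tibble::tibble(snp_id = colnames(Z), chrom = chroms,
                               pos = seq_len(p) * 1000)
    ),
    class = "std_geno"
  )
}

# invert the stored standardization so predict() recovers Z exactly
std_to_panel <- function(std) {
  sweep(sweep(std$Z, 2, std$col_sds, "*"), 2, std$col_means, "+")
}

# standardized random design (population sd), used for model oracles
random_std <- function(n, p, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- sweep(Z, 2, sqrt(colMeans(Z^2)), "/")
  std_from_matrix(Z)
}

# --- elastic-net oracle: sign-pattern enumeration (exact for p <= 6) -------
# objective: RSS/(2n) + lambda * (alpha ||u||_1 + (1-alpha)/2 ||u||_2^2),
# intercept unpenalized.
enet_oracle <- function(Z, y, lambda, alpha) {
  n <- nrow(Z); p <- ncol(Z)
  stopifnot(p <= 6)
  mu <- mean(y)           # Z columns are centered, so the intercept is ybar
  r <- y - mu
  best <- NULL
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (k in seq_len(nrow(signs))) {
    s <- signs[k, ]
    act <- s != 0
    u <- numeric(p)
    if (any(act)) {
      A <- crossprod(Z[, act, drop = FALSE]) / n +
        diag(lambda * (1 - alpha), sum(act))
      b <- crossprod(Z[, act, drop = FALSE], r) / n - lambda * alpha * s[act]
      u_act <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(u_act)) next
      if (any(sign(u_act) != s[act])) next
      u[act] <- u_act
    }
    grad <- drop(crossprod(Z, r - Z %*% u)) / n - lambda * (1 - alpha) * u
    if (any(abs(grad[!act]) > lambda * alpha + 1e-10)) next
    obj <- sum((r - Z %*% u)^2) / (2 * n) +
      lambda * (alpha * sum(abs(u)) + (1 - alpha) / 2 * sum(u^2))
    if (is.null(best) || obj < best$obj) best <- list(u = u, mu = mu, obj = obj)
  }
  best
}

# --- dense REML oracle: direct maximization of the restricted likelihood ---
# independent of the package's AI-REML path: plain matrix algebra + optim()
reml_oracle_loglik <- function(log_theta, y, X, Ks) {
  th <- exp(log_theta)
  n <- length(y)
  V <- diag(th[length(th)], n)
  for (i in seq_along(Ks)) V <- V + th[i] * Ks[[i]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(
    -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
              t(r) %*% Vi %*% r)
  )
}

reml_oracle <- function(y, Ks, X = NULL, start = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  m <- length(Ks)
  if (is.null(start)) start <- rep(log(var(y) / (m + 1)), m + 1)
  opt <- optim(start, reml_oracle_loglik, y = y, X = X, Ks = Ks,
               method = "Nelder-Mead",
               control = list(fnscale = -1, maxit = 5000, reltol = 1e-14))
  # restart from the optimum to polish the simplex solution
  opt <- optim(opt$par, reml_oracle_loglik, y = y, X = X, Ks = Ks,
               method = "Nelder-Mead",
               control = list(fnscale = -1, maxit = 5000, reltol = 1e-15))
  list(sigma2 = exp(opt$par[seq_len(m)]), sigma2_e = exp(opt$par[m + 1]),
       loglik = opt$value, convergence = opt$convergence)
}

# simulate from the single-kernel mixed model y = mu + g + e
simulate_kernel_trait <- function(K, s2g, s2e, mu = 0, seed = 1) {
  set.seed(seed)
  n <- nrow(K)
  ev <- eigen(K, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  drop(mu + L %*% rnorm(n) * sqrt(s2g) + rnorm(n, sd = sqrt(s2e)))
}

quick_sim <- function(seed = 1, n_lines = 120, snps_per_chrom = 60, ...) {
  cfg <- sim_config(
    n_lines = n_lines,
    n_snps_per_chrom = rep(as.integer(snps_per_chrom), 10),
    seed = seed, ...
  )
  panel <- simulate_genotypes(cfg)
  list(cfg = cfg, panel = panel)
}
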