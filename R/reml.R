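# REML engines.
#
# Two fitters:
#  * reml_kernel(): single-kernel model y = X b + g + e, var(g) = K s2_g,
#    solved by a 1-D profile-likelihood search on the variance ratio in the
#    eigenbasis of K (exact, fast, used by RR-BLUP, RKHS and the GWA null).
#  * reml_multi(): multi-kernel model (one component per chromosome plus
#    residual), average-information REML with step-halving and an active set
#    pinning components at zero when their updates go negative.

# restricted log-likelihood for given variance components (dense, O(n^3))
reml_loglik_dense <- function(y, X, Klist, sigma2, sigma2_e) {
  n <- length(y)
  V <- diag(sigma2_e, n)
  for (i in seq_along(Klist)) V <- V + sigma2[i] * Klist[[i]]
  cV <- chol(V)
  Vinv_y <- backsolve(cV, forwardsolve(t(cV), y))
  Vinv_X <- backsolve(cV, forwardsolve(t(cV), X))
  XtVX <- crossprod(X, Vinv_X)
  beta <- solve(XtVX, crossprod(Vinv_X, y))
  Py <- Vinv_y - Vinv_X %*% beta
  ldetV <- 2 * sum(log(diag(cV)))
  ldetX <- determinant(XtVX, logarithm = TRUE)$modulus
  -0.5 * (ldetV + as.numeric(ldetX) + sum(y * Py))
}

#' Single-kernel REML fit
#'
#' Fits `y = X b + g + e` with `var(g) = K s2_g`, `var(e) = I s2_e` by
#' restricted maximum likelihood. The variance ratio `s2_g / s2_e` is
#' profiled on the spectral decomposition of `K`, so each candidate ratio is
#' evaluated in closed form; `s2_e` is then available analytically.
#'
#' @param y Numeric response of length n.
#' @param K A [kernel_matrix()] or plain symmetric n x n matrix.
#' @param X Fixed-effect design matrix (default: intercept only).
#' @return List with `sigma2_g`, `sigma2_e`, `beta`, `loglik` (restricted,
#'   original scale), `ghat` (BLUP of g), `alpha` (weights such that
#'   `ghat = K alpha` and a new line's BLUP is `k_new' alpha`), `eig`
#'   (spectral decomposition reused by callers).
#' @export
reml_kernel <- function(y, K, X = NULL) {
  Km <- if (inherits(K, "kernel_matrix")) K$values else K
  n <- length(y)
  stopifnot(nrow(Km) == n)
  if (var(y) == 0) abort("response has zero variance.")
  if (is.null(X)) X <- matrix(1, n, 1)
  q <- ncol(X)

  e <- eigen(Km, symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)

  # profile restricted loglik as a function of gamma = s2_g / s2_e
  prof <- function(log_gamma) {
    g <- exp(log_gamma)
    w <- 1 / (g * d + 1)
    XtWX <- crossprod(Xt, w * Xt)
    XtWy <- crossprod(Xt, w * yt)
    beta <- solve(XtWX, XtWy)
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    s2e <- rss / (n - q)
    ll <- -0.5 * ((n - q) * log(s2e) + sum(log(g * d + 1)) +
                    determinant(XtWX, logarithm = TRUE)$modulus + (n - q))
    as.numeric(ll)
  }
  opt <- optimize(prof, interval = c(-25, 25), maximum = TRUE, tol = 1e-10)
  g_ratio <- exp(opt$maximum)

  w <- 1 / (g_ratio * d + 1)
  XtWX <- crossprod(Xt, w * Xt)
  beta <- solve(XtWX, crossprod(Xt, w * yt))
  rt <- yt - Xt %*% beta
  s2e <- sum(w * rt^2) / (n - q)
  s2g <- g_ratio * s2e
  # alpha such that ghat = K alpha; for a new line gpred = k_new' alpha
  alpha <- U %*% (g_ratio * w * rt)
  ghat <- U %*% (g_ratio * d * w * rt)
  list(
    sigma2_g = s2g,
    sigma2_e = s2e,
    beta = drop(beta),
    loglik = opt$objective,
    gamma = g_ratio,
    ghat = drop(ghat),
    alpha = drop(alpha),
    eig = e,
    X = X
  )
}

#' Multi-kernel REML by average information with active-set constraints
#'
#' Simultaneously estimates one variance component per kernel plus a
#' residual component for `y = X b + sum_c g_c + e`, `var(g_c) = K_c s2_c`.
#' Average-information updates with step-halving when a step would decrease
#' the restricted likelihood or leave the parameter space; components whose
#' updates are pinned at zero are treated as an active set and may re-enter
#' if their score turns positive. The response is scaled to unit variance
#' internally and components are scaled back, so tolerances behave uniformly
#' across traits.
#'
#' @param y Response vector.
#' @param Klist List of [kernel_matrix()] or plain matrices.
#' @param X Fixed-effect design (default intercept).
#' @param tol Convergence tolerance on the change in restricted log-likelihood.
#' @param max_iter Maximum iterations.
#' @param verbose Print iteration trace.
#' @return List with `sigma2` (per-kernel components), `sigma2_e`, `beta`,
#'   `loglik` (original scale), `converged`, `iterations`.
#' @export
reml_multi <- function(y, Klist, X = NULL, tol = 1e-6, max_iter = 200,
                       verbose = FALSE) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  Ks <- lapply(Klist, function(k) if (inherits(k, "kernel_matrix")) k$values else k)
  m <- length(Ks)
  sy <- sd(y)
  if (sy == 0) abort("response has zero variance.")
  ys <- y / sy

  theta <- c(rep(0.5 / m, m), 0.5)  # kernels then residual, on var(ys) = 1 scale
  floor_v <- 1e-10

  eval_state <- function(theta) {
    V <- diag(theta[m + 1], n)
    for (i in seq_len(m)) if (theta[i] > 0) V <- V + theta[i] * Ks[[i]]
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Vinv <- chol2inv(cV)
    VX <- Vinv %*% X
    XtVX <- crossprod(X, VX)
    XtVXi <- solve(XtVX)
    P <- Vinv - VX %*% XtVXi %*% t(VX)
    Py <- P %*% ys
    ll <- -0.5 * (2 * sum(log(diag(cV))) +
                    determinant(XtVX, logarithm = TRUE)$modulus +
                    sum(ys * Py))
    list(P = P, Py = Py, ll = as.numeric(ll), XtVXi = XtVXi, VX = VX)
  }

  st <- eval_state(theta)
  if (is.null(st)) abort("initial variance matrix not positive definite.")
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    P <- st$P; Py <- st$Py
    # score and AI matrix over all m+1 components (O(n^2) per entry)
    Tm <- matrix(0, n, m + 1)
    tr_PK <- numeric(m + 1)
    for (i in seq_len(m)) {
      Tm[, i] <- Ks[[i]] %*% Py
      tr_PK[i] <- sum(P * Ks[[i]])
    }
    Tm[, m + 1] <- Py
    tr_PK[m + 1] <- sum(diag(P))
    score <- -0.5 * (tr_PK - colSums(Tm * c(Py)))
    S <- P %*% Tm
    AI <- 0.5 * crossprod(Tm, S)

    active <- theta > floor_v | score > 0  # pinned components may re-enter
    active[m + 1] <- TRUE
    delta <- numeric(m + 1)
    ai_sub <- AI[active, active, drop = FALSE]
    sol <- tryCatch(solve(ai_sub + diag(1e-10, sum(active)), score[active]),
                    error = function(e) NULL)
    if (is.null(sol)) sol <- score[active]  # gradient fallback
    delta[active] <- sol

    step <- 1
    improved <- FALSE
    for (h in 1:30) {
      cand <- theta + step * delta
      cand[cand < 0] <- 0
      cand[!active] <- 0
      if (cand[m + 1] < floor_v) cand[m + 1] <- floor_v
      st_new <- eval_state(cand)
      if (!is.null(st_new) && st_new$ll >= st$ll - 1e-12) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    dll <- st_new$ll - st$ll
    theta <- cand
    st <- st_new
    if (verbose) {
      cat(sprintf("iter %3d  ll = %.8f  dll = %.2e\n", iter, st$ll, dll))
    }
    if (abs(dll) < tol) {
      converged <- TRUE
      break
    }
  }

  scale2 <- sy^2
  sigma2 <- theta[seq_len(m)] * scale2
  sigma2_e <- theta[m + 1] * scale2
  beta <- drop(st$XtVXi %*% crossprod(st$VX, ys)) * sy
  ll_orig <- reml_loglik_dense(y, X, Ks, sigma2, sigma2_e)
  list(
    sigma2 = sigma2,
    sigma2_e = sigma2_e,
    beta = beta,
    loglik = ll_orig,
    converged = converged,
    iterations = iter
  )
}
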