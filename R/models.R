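# Common fit container for the five whole-genome prediction models.
new_wgp_fit <- function(model, mu, snp_effects = NULL, genotype_effects = NULL,
                        hyperparams = list(), std = NULL, diagnostics = list(),
                        extra = list()) {
  structure(
    c(list(
      model = model,
      mu = mu,
      snp_effects = snp_effects,
      genotype_effects = genotype_effects,
      hyperparams = hyperparams,
      col_means = std$col_means,
      col_sds = std$col_sds,
      snp_map = std$snp_map,
      training_line_ids = if (!is.null(std)) rownames(std$Z) else NULL,
      diagnostics = diagnostics
    ), extra),
    class = c(paste0("wgp_", model), "wgp_fit")
  )
}

#' @export
print.wgp_fit <- function(x, ...) {
  cat(sprintf("<wgp_fit: %s> n = %d training lines", x$model,
              length(x$training_line_ids)))
  if (!is.null(x$snp_effects)) {
    cat(sprintf(", %d SNP effects (%d nonzero)", length(x$snp_effects),
                sum(x$snp_effects != 0)))
  }
  cat("\n  hyperparameters:",
      paste(names(x$hyperparams),
            vapply(x$hyperparams, function(v) format(v[1], digits = 4), ""),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.wgp_fit <- function(x, ...) {
  if (is.null(x$snp_effects)) {
    return(tibble(line_id = x$training_line_ids,
                  genotype_effect = unname(x$genotype_effects)))
  }
  map <- x$snp_map
  idx <- match(names(x$snp_effects), map$snp_id)
  tibble(
    snp_id = names(x$snp_effects),
    chrom = map$chrom[idx],
    pos = map$pos[idx],
    effect = unname(x$snp_effects)
  )
}

#' @export
glance.wgp_fit <- function(x, ...) {
  hp <- x$hyperparams[vapply(x$hyperparams, function(v) is.numeric(v) && length(v) == 1, TRUE)]
  dplyr::bind_cols(
    tibble(model = x$model, mu = x$mu, n_train = length(x$training_line_ids)),
    as_tibble(hp)
  )
}

#' @export
autoplot.wgp_fit <- function(object, ...) {
  td <- tidy(object)
  if (!"effect" %in% names(td)) abort("no SNP effects to plot for this model.")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$pos / 1e6, y = .data$effect)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos / 1e6, yend = 0), linewidth = 0.3) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "SNP effect", title = object$model) +
    ggplot2::theme_minimal()
}

# ---- RR-BLUP ---------------------------------------------------------------

#' Ridge-regression BLUP via the kernel dual
#'
#' All SNP effects are treated as draws from `N(0, s2_u)`, equivalent to a
#' genotype-level mixed model with inner-product kernel `G = ZZ'/p`,
#' `var(g) = G s2_g`, `s2_g = p s2_u`. Variance components are estimated by
#' REML on the kernel form; genotype effects are the BLUP, and SNP effects
#' are recovered by the dual back-transformation `u = Z' G^- g / p`, which
#' reproduces the primal ridge solution `(Z'Z + lambda I)^-1 Z'(y - mu)`
#' with `lambda = s2_e / s2_u`.
#'
#' @param std A `std_geno` from [impute_and_standardize()].
#' @param trait Trait tibble or numeric response.
#' @param lambda Optional fixed ridge penalty `lambda_RR = s2_e / s2_u`;
#'   when `NULL` (default) it is estimated by REML.
#' @return A `wgp_fit` with SNP effects, genotype effects and hyperparameters
#'   `lambda_RR`, `sigma2_u`, `sigma2_e`.
#' @export
fit_rrblup <- function(std, trait, lambda = NULL) {
  Z <- std$Z
  n <- nrow(Z)
  p <- ncol(Z)
  if (n < 2) abort("need at least two training lines.")
  y <- align_trait(trait, rownames(Z))
  if (var(y) == 0) abort("response has zero variance.")

  G <- tcrossprod(Z) / p
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors

  if (is.null(lambda)) {
    fit <- reml_kernel(y, G, X = matrix(1, n, 1))
    sigma2_g <- fit$sigma2_g
    sigma2_e <- fit$sigma2_e
    sigma2_u <- sigma2_g / p
    lambda <- if (sigma2_u > 0) sigma2_e / sigma2_u else Inf
  } else {
    sigma2_u <- NA_real_
    sigma2_e <- NA_real_
  }

  # W = ZZ' + lambda I = p G + lambda I, diagonal in the eigenbasis of G
  wvals <- p * d + lambda
  yt <- crossprod(U, y)
  ones_t <- crossprod(U, rep(1, n))
  mu <- sum(ones_t * yt / wvals) / sum(ones_t^2 / wvals)
  rt <- yt - ones_t * mu
  winv_r <- rt / wvals               # U' W^-1 (y - mu)
  ghat <- U %*% (p * d * winv_r)     # p G W^-1 r
  # u = Z' G^- ghat / p  (pseudoinverse on the span of G) = Z' W^-1 r
  pos <- d > max(d) * 1e-12
  ginv_ghat <- U[, pos, drop = FALSE] %*% (crossprod(U[, pos, drop = FALSE], ghat) / d[pos])
  u <- drop(crossprod(Z, ginv_ghat)) / p

  new_wgp_fit(
    "rrblup",
    mu = mu,
    snp_effects = setNames(u, colnames(Z)),
    genotype_effects = setNames(drop(ghat), rownames(Z)),
    hyperparams = list(lambda_RR = lambda, sigma2_u = sigma2_u,
                       sigma2_e = sigma2_e),
    std = std
  )
}

# ---- LASSO / elastic net ---------------------------------------------------

# deterministic fold ids for the inner hyperparameter CV (uses the caller's
# RNG state so a set.seed() upstream fixes the selection)
inner_foldid <- function(n, nfolds) sample(rep(seq_len(nfolds), length.out = n))

glmnet_path <- function(Z, y, alpha, lambda = NULL, nlambda = 100,
                        thresh = 1e-14) {
  glmnet::glmnet(Z, y, family = "gaussian", alpha = alpha,
                 lambda = lambda, nlambda = nlambda,
                 standardize = FALSE, intercept = TRUE, thresh = thresh,
                 maxit = 1e6)
}

# glmnet standardizes the gaussian response internally, which leaves the L1
# part of its penalty on the raw-y scale but divides the L2 part by the
# population sd of y. These maps convert between the advertised objective
#   RSS/(2n) + lambda (alpha ||u||_1 + (1-alpha)/2 ||u||_2^2)
# and the (alpha, lambda) glmnet must be given to solve it exactly.
to_glmnet_penalty <- function(alpha, lambda, s) {
  lg <- lambda * (alpha + (1 - alpha) * s)
  ag <- if (lg > 0) alpha * lambda / lg else alpha
  list(alpha = ag, lambda = lg)
}

from_glmnet_penalty <- function(alpha_g, lambda_g, s) {
  l1 <- alpha_g * lambda_g
  l2 <- (1 - alpha_g) * lambda_g / s
  lambda <- l1 + l2
  list(alpha = if (lambda > 0) l1 / lambda else alpha_g, lambda = lambda)
}

pop_sd <- function(y) sqrt(mean((y - mean(y))^2))

# fit at one fixed (alpha, lambda) of the advertised objective by running a
# warm-started glmnet path down to the converted penalty
glmnet_at <- function(Z, y, alpha, lambda, thresh = 1e-14) {
  n <- nrow(Z)
  conv <- to_glmnet_penalty(alpha, lambda, pop_sd(y))
  r <- y - mean(y)
  lam_max <- max(abs(crossprod(Z, r)) / n) / max(conv$alpha, 1e-3)
  if (conv$lambda >= lam_max) lam_max <- conv$lambda * 1.001
  path <- exp(seq(log(lam_max), log(conv$lambda), length.out = 30))
  fit <- glmnet_path(Z, y, conv$alpha, lambda = path, thresh = thresh)
  list(fit = fit, s = conv$lambda)
}

#' LASSO whole-genome regression
#'
#' L1-penalized SNP effects (coordinate-descent path via glmnet):
#' some effects are set exactly to zero, so a trait driven by a major QTL is
#' captured by a sparse set of markers. The penalty uses the objective
#' `RSS/(2n) + lambda ||u||_1`. When `lambda` is not supplied it is chosen
#' by 5-fold cross-validated mean squared error inside the training data
#' (the raw training MSE would always pick `lambda -> 0`).
#'
#' @param std A `std_geno`.
#' @param trait Trait tibble or numeric response.
#' @param lambda Fixed penalty, or `NULL` for inner-CV selection.
#' @param nlambda Length of the automatic lambda path.
#' @param nfolds Inner CV folds.
#' @param thresh Coordinate-descent convergence threshold (tight default for
#'   near-exact stationarity; relax to ~1e-8 in large repeated-CV sweeps
#'   where selection noise dominates).
#' @return A `wgp_fit` with sparse SNP effects and hyperparameter `lambda_L`.
#' @export
fit_lasso <- function(std, trait, lambda = NULL, nlambda = 100, nfolds = 5,
                      thresh = 1e-14) {
  res <- fit_elastic_net(std, trait, alpha_grid = 1, lambda = lambda,
                         nlambda = nlambda, nfolds = nfolds, thresh = thresh)
  res$model <- "lasso"
  class(res)[1] <- "wgp_lasso"
  res$hyperparams <- list(lambda_L = res$hyperparams$lambda_EN,
                          cv_mse = res$hyperparams$cv_mse)
  res
}

#' Elastic-net whole-genome regression
#'
#' Mixed L1/L2 penalty `lambda (alpha ||u||_1 + (1 - alpha)/2 ||u||_2^2)`:
#' `alpha = 1` is the LASSO, `alpha = 0` ridge. The `(alpha, lambda)` pair
#' is selected by a grid search minimizing 5-fold cross-validated MSE within
#' the training set, with ties broken toward larger `lambda` and then larger
#' `alpha` (sparser models).
#'
#' @param std A `std_geno`.
#' @param trait Trait tibble or numeric response.
#' @param alpha_grid Mixing values in `[0, 1]` (default 0, 0.1, ..., 1).
#' @param lambda Fixed penalty (then `alpha_grid` must have length 1), or
#'   `NULL` for inner-CV selection.
#' @param nlambda Length of each automatic lambda path.
#' @param nfolds Inner CV folds.
#' @param thresh Coordinate-descent convergence threshold.
#' @return A `wgp_fit` with hyperparameters `alpha`, `lambda_EN`, `cv_mse`.
#' @export
fit_elastic_net <- function(std, trait, alpha_grid = seq(0, 1, by = 0.1),
                            lambda = NULL, nlambda = 100, nfolds = 5,
                            thresh = 1e-14) {
  Z <- std$Z
  n <- nrow(Z)
  if (n < 10 && is.null(lambda)) abort("need at least 10 lines for inner CV.")
  y <- align_trait(trait, rownames(Z))
  if (var(y) == 0) abort("response has zero variance.")
  stopifnot(all(alpha_grid >= 0 & alpha_grid <= 1))

  if (!is.null(lambda)) {
    stopifnot(length(alpha_grid) == 1)
    # the requested lambda is the last point of the warm-started path, so
    # coef() returns that exact solution without refitting
    ga <- glmnet_at(Z, y, alpha_grid, lambda, thresh = thresh)
    cf <- coef(ga$fit, s = ga$s)
    best <- list(alpha = alpha_grid, lambda = lambda, cvm = NA_real_)
  } else {
    foldid <- inner_foldid(n, nfolds)
    s_y <- pop_sd(y)
    best <- NULL
    for (a in sort(alpha_grid)) {
      scale_a <- a + (1 - a) * s_y  # per-alpha penalty rescaling (see above)
      cvf <- glmnet::cv.glmnet(Z, y, alpha = a / scale_a, foldid = foldid,
                               nlambda = nlambda, standardize = FALSE,
                               intercept = TRUE, thresh = thresh, maxit = 1e6)
      i <- which.min(cvf$cvm)
      cand <- list(alpha = a, lambda = cvf$lambda[i] / scale_a,
                   lambda_g = cvf$lambda[i], cvm = cvf$cvm[i],
                   fit = cvf$glmnet.fit)
      if (is.null(best) ||
          cand$cvm < best$cvm - 1e-12 ||
          (abs(cand$cvm - best$cvm) <= 1e-12 &&
             (cand$lambda > best$lambda ||
                (cand$lambda == best$lambda && cand$alpha > best$alpha)))) {
        best <- cand
      }
    }
    cf <- coef(best$fit, s = best$lambda_g)  # lambda.min lies on the path
  }
  cf <- as.numeric(cf)
  mu <- cf[1]
  u <- cf[-1]
  conv <- check_kkt(Z, y, mu, u, best$lambda, best$alpha)
  new_wgp_fit(
    "elastic_net",
    mu = mu,
    snp_effects = setNames(u, colnames(Z)),
    hyperparams = list(alpha = best$alpha, lambda_EN = best$lambda,
                       cv_mse = best$cvm),
    std = std,
    diagnostics = list(n_nonzero = sum(u != 0), kkt_max_violation = conv)
  )
}

# maximum KKT violation of the elastic-net stationarity conditions
check_kkt <- function(Z, y, mu, u, lambda, alpha) {
  n <- nrow(Z)
  r <- y - mu - drop(Z %*% u)
  grad <- drop(crossprod(Z, r)) / n - lambda * (1 - alpha) * u
  active <- u != 0
  v_active <- if (any(active)) {
    max(abs(grad[active] - lambda * alpha * sign(u[active])))
  } else 0
  v_inactive <- if (any(!active)) {
    max(0, max(abs(grad[!active])) - lambda * alpha)
  } else 0
  max(v_active, v_inactive)
}

# ---- RKHS ------------------------------------------------------------------

#' Reproducing kernel Hilbert space regression on genetic distances
#'
#' Gaussian kernel `K_ij = exp(-GD_ij / theta^2)` on modified Rogers'
#' distances. For each candidate bandwidth the genotype-level mixed model
#' `y = 1 mu + g + e`, `var(g) = K s2_g` is fitted by REML and `theta` is
#' chosen at the maximum restricted likelihood. Prediction for a new line
#' uses its cross-kernel row against the training lines.
#'
#' @param panel A QC'd [genotype_panel()] (distances use mean-imputed raw
#'   dosages).
#' @param trait Trait tibble or numeric response.
#' @param theta_grid Candidate bandwidths; default 30 log-spaced points in
#'   `[0.1, 100]`.
#' @return A `wgp_fit` with genotype effects (no SNP effects), hyperparameters
#'   `theta`, `sigma2_g`, `sigma2_e`, and the theta likelihood profile in
#'   `diagnostics$theta_profile`.
#' @export
fit_rkhs <- function(panel, trait, theta_grid = NULL) {
  if (is.null(theta_grid)) {
    theta_grid <- exp(seq(log(0.1), log(100), length.out = 30))
  }
  stopifnot(all(theta_grid >= 0.1 - 1e-9 & theta_grid <= 100 + 1e-9))
  x <- panel$dosages
  if (anyNA(x)) {
    cm <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- cm[idx[, 2]]
  }
  D <- modified_rogers_distance(x)
  y <- align_trait(trait, rownames(x))

  best <- NULL
  prof <- tibble(theta = theta_grid, loglik = NA_real_)
  for (i in seq_along(theta_grid)) {
    th <- theta_grid[i]
    K <- exp(-D / th^2)
    fit <- tryCatch(reml_kernel(y, K, X = matrix(1, nrow(K), 1)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    prof$loglik[i] <- fit$loglik
    if (is.null(best) || fit$loglik > best$fit$loglik) {
      best <- list(theta = th, fit = fit)
    }
  }
  if (is.null(best)) abort("REML failed for every theta in the grid.")

  f <- best$fit
  std_stub <- list(col_means = NULL, col_sds = NULL,
                   snp_map = panel$snp_map, Z = x)
  new_wgp_fit(
    "rkhs",
    mu = f$beta[1],
    genotype_effects = setNames(f$ghat, rownames(x)),
    hyperparams = list(theta = best$theta, sigma2_g = f$sigma2_g,
                       sigma2_e = f$sigma2_e, loglik = f$loglik),
    std = std_stub,
    diagnostics = list(theta_profile = prof),
    extra = list(train_dosages = x, alpha = f$alpha)
  )
}

# ---- BayesB ----------------------------------------------------------------

#' BayesB with uncertain hyperparameters (Metropolis-within-Gibbs)
#'
#' SNP effects are t-distributed with a point mass at zero: each effect
#' `u_i ~ N(0, s2_ui)` where `s2_ui` is exactly zero with probability `Pi_u`
#' and otherwise follows a scaled-inverse-chi-squared `(nu_u, S2_u)`
#' distribution. The hyperparameters are themselves uncertain, with priors
#' `Pi_u ~ Beta(7, 3)`, `nu_u ~ Gamma(shape 5, scale 2)`,
#' `S2_u ~ Gamma(shape 0.1, scale 10)`; the residual variance has a
#' scaled-inverse-chi-squared prior with `nu_e = 4.001` and scale matched to
#' the REML residual-variance estimate. Per SNP the inclusion state is
#' updated by a Metropolis step with the effect integrated out, then the
#' effect is drawn from its conditional; `nu_u` and `S2_u` move by adaptive
#' random-walk Metropolis on the log scale, `Pi_u` and the residual variance
#' by their conjugate full conditionals.
#'
#' @param std A `std_geno`.
#' @param trait Trait tibble or numeric response.
#' @param n_iter,burn_in,thin MCMC protocol (defaults 50000 / 5000 / 10).
#' @param reduce_to Optional marker count: the panel is thinned to this many
#'   SNPs, evenly spaced by map position, before sampling (the classical
#'   5000-SNP reduction). `NULL` keeps all SNPs.
#' @param seed Seed for the sampler (R RNG; fixing it fixes the posterior
#'   summaries exactly).
#' @param include_all Disable the point mass (every SNP always in the model).
#' @param fixed_effect_var Fix all `s2_ui` at this common value (with
#'   `include_all = TRUE` this is conjugate Bayesian ridge, used for
#'   validation against the analytic posterior).
#' @param fixed_resid_var Fix the residual variance.
#' @param fix_mu Fix the intercept (e.g. 0 for a centered response).
#' @return A `wgp_fit` with posterior-mean SNP effects; hyperparameter
#'   posterior means (`Pi_u`, `nu_u`, `S2_u`, `sigma2_e`), Metropolis
#'   acceptance rates and per-SNP inclusion probabilities in `diagnostics`.
#' @export
fit_bayesb <- function(std, trait, n_iter = 50000, burn_in = 5000, thin = 10,
                       reduce_to = NULL, seed = NULL,
                       include_all = FALSE, fixed_effect_var = NA_real_,
                       fixed_resid_var = NA_real_, fix_mu = NA_real_) {
  Z <- std$Z
  n <- nrow(Z)
  y <- align_trait(trait, rownames(Z))
  stopifnot(n_iter > burn_in, thin >= 1)
  if (!is.null(seed)) set.seed(seed)

  sel <- seq_len(ncol(Z))
  if (!is.null(reduce_to) && reduce_to < ncol(Z)) {
    sel <- unique(round(seq(1, ncol(Z), length.out = reduce_to)))
  }
  Zs <- Z[, sel, drop = FALSE]

  if (is.na(fixed_resid_var)) {
    G <- tcrossprod(Zs) / ncol(Zs)
    s2e_hat <- reml_kernel(y, G)$sigma2_e
  } else {
    s2e_hat <- fixed_resid_var
  }
  nu_e <- 4.001
  S2_e <- s2e_hat * (nu_e - 2) / nu_e

  res <- bayesb_gibbs(
    Zs, y,
    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    thin = as.integer(thin),
    pi_a = 7, pi_b = 3, nu_u_shape = 5, nu_u_scale = 2,
    s2u_shape = 0.1, s2u_scale = 10, nu_e = nu_e, S2_e = S2_e,
    include_all = include_all, fixed_effect_var = fixed_effect_var,
    fixed_resid_var = fixed_resid_var, fix_mu = fix_mu
  )

  acc <- c(nu_u = res$acc_nu, S2_u = res$acc_s2)
  if (!include_all && any(acc < 0.05 | acc > 0.95)) {
    warn(sprintf("Metropolis acceptance rate outside [0.05, 0.95]: %s",
                 paste(sprintf("%s=%.2f", names(acc), acc), collapse = ", ")))
  }

  u_full <- numeric(ncol(Z))
  u_full[sel] <- res$u_mean
  new_wgp_fit(
    "bayesb",
    mu = res$mu_mean,
    snp_effects = setNames(u_full, colnames(Z)),
    hyperparams = list(
      Pi_u = res$pi_mean, nu_u = res$nu_u_mean, S2_u = res$s2u_mean,
      sigma2_e = res$s2e_mean, S2_e_prior = S2_e
    ),
    std = std,
    diagnostics = list(
      acceptance = acc,
      inclusion_prob = setNames(res$incl_prob, colnames(Zs)),
      n_samples = res$n_samples,
      u_mean_reduced = setNames(res$u_mean, colnames(Zs)),
      u_sd_reduced = setNames(res$u_sd, colnames(Zs)),
      selected_snps = colnames(Zs),
      hyper_trace = tibble(
        sample = seq_along(res$trace_s2e),
        sigma2_e = res$trace_s2e, Pi_u = res$trace_pi,
        nu_u = res$trace_nu, S2_u = res$trace_s2u
      )
    )
  )
}

# ---- prediction ------------------------------------------------------------

new_dosage_matrix <- function(newdata) {
  if (inherits(newdata, "genotype_panel")) return(newdata$dosages)
  if (inherits(newdata, "std_geno")) abort("pass raw dosages or a genotype_panel; standardization must reuse the training statistics.")
  as.matrix(newdata)
}

#' Predict genotypic values for new lines
#'
#' Effect-based models score `mu + Z_new u` where `Z_new` standardizes the
#' new dosages with the *training* column means and sds (never re-estimated
#' on test data; missing entries fall back to the training mean, i.e. a
#' centered value of zero). RKHS scores `mu + k(new, train) alpha` with the
#' Gaussian cross-kernel on modified Rogers' distances.
#'
#' @param object A `wgp_fit`.
#' @param newdata A [genotype_panel()] or raw dosage matrix whose columns
#'   include all training SNPs.
#' @param ... Unused.
#' @return Named numeric vector of predictions.
#' @export
predict.wgp_fit <- function(object, newdata, ...) {
  x <- new_dosage_matrix(newdata)
  if (object$model == "rkhs") {
    need <- colnames(object$train_dosages)
    missing_snps <- setdiff(need, colnames(x))
    if (length(missing_snps)) {
      abort(sprintf("newdata lacks %d training SNPs (e.g. %s)",
                    length(missing_snps), paste(head(missing_snps, 3), collapse = ", ")))
    }
    x <- x[, need, drop = FALSE]
    if (anyNA(x)) {
      cm <- colMeans(object$train_dosages)
      idx <- which(is.na(x), arr.ind = TRUE)
      x[idx] <- cm[idx[, 2]]
    }
    tr <- object$train_dosages
    p <- ncol(tr)
    d2 <- outer(rowSums(x^2), rowSums(tr^2), "+") - 2 * x %*% t(tr)
    d2[d2 < 0] <- 0
    GD <- sqrt(d2 / (4 * p))
    Kx <- exp(-GD / object$hyperparams$theta^2)
    return(setNames(drop(object$mu + Kx %*% object$alpha), rownames(x)))
  }
  u <- object$snp_effects
  need <- names(u)
  missing_snps <- setdiff(need, colnames(x))
  if (length(missing_snps)) {
    abort(sprintf("newdata lacks %d training SNPs (e.g. %s)",
                  length(missing_snps), paste(head(missing_snps, 3), collapse = ", ")))
  }
  x <- x[, need, drop = FALSE]
  Zn <- sweep(x, 2, object$col_means)
  Zn[is.na(Zn)] <- 0  # training-mean imputation
  Zn <- sweep(Zn, 2, object$col_sds, "/")
  setNames(drop(object$mu + Zn %*% u), rownames(x))
}
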