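test_that("kernel-dual RR-BLUP reproduces the primal ridge closed form", {
  for (p in c(5, 50)) {
    std <- random_std(30, p, seed = p)
    set.seed(p + 1)
    y <- rnorm(30)
    lam <- 2.5
    fit <- fit_rrblup(std, y, lambda = lam)
    Z <- std$Z
    n <- nrow(Z)
    W <- tcrossprod(Z) + lam * diag(n)
    mu <- drop(crossprod(rep(1, n), solve(W, y)) / crossprod(rep(1, n), solve(W, rep(1, n))))
    u_primal <- solve(crossprod(Z) + lam * diag(p), crossprod(Z, y - mu))
    expect_lt(max(abs(fit$snp_effects - u_primal)), 1e-8)
    # effect-based and kernel-based predictions agree
    expect_lt(max(abs(Z %*% fit$snp_effects - fit$genotype_effects)), 1e-6)
  }
})

test_that("infinite shrinkage collapses RR-BLUP to the mean", {
  std <- random_std(25, 10, seed = 3)
  set.seed(4)
  y <- rnorm(25)
  fit <- fit_rrblup(std, y, lambda = 1e12)
  expect_lt(max(abs(fit$snp_effects)), 1e-8)
  pred <- predict(fit, std_to_panel(std))
  expect_equal(unname(pred), rep(fit$mu, 25), tolerance = 1e-6)
})

test_that("duplicated SNP columns receive identical RR and EN effects", {
  std <- random_std(40, 6, seed = 5)
  Z <- std$Z
  Z[, 6] <- Z[, 5]
  colnames(Z)[6] <- "S06"
  std2 <- std_from_matrix(Z)
  set.seed(6)
  y <- drop(Z %*% c(1, 0, 0, 0, 0.5, 0.5)) + rnorm(40, sd = 0.3)
  frr <- fit_rrblup(std2, y, lambda = 1.0)
  expect_lt(abs(frr$snp_effects[5] - frr$snp_effects[6]), 1e-8)
  fen <- fit_elastic_net(std2, y, alpha_grid = 0.5, lambda = 0.05,
                         thresh = 1e-16)
  expect_lt(abs(fen$snp_effects[5] - fen$snp_effects[6]), 1e-6)
})

test_that("lasso matches the sign-enumeration oracle on small instances", {
  for (seed in 1:5) {
    std <- random_std(30, 4, seed = 100 + seed)
    set.seed(200 + seed)
    y <- drop(std$Z %*% c(1.5, -0.8, 0, 0)) + rnorm(30, sd = 0.5)
    lam <- 0.15
    fit <- fit_lasso(std, y, lambda = lam)
    orc <- enet_oracle(std$Z, y, lam, alpha = 1)
    expect_lt(max(abs(fit$snp_effects - orc$u)), 1e-6)
    expect_lt(fit$diagnostics$kkt_max_violation, 1e-6)
  }
})

test_that("elastic net matches the oracle away from the endpoints", {
  std <- random_std(35, 5, seed = 11)
  set.seed(12)
  y <- drop(std$Z %*% c(1, 1, -0.5, 0, 0)) + rnorm(35, sd = 0.4)
  for (alpha in c(0.3, 0.7)) {
    fit <- fit_elastic_net(std, y, alpha_grid = alpha, lambda = 0.1)
    orc <- enet_oracle(std$Z, y, 0.1, alpha)
    expect_lt(max(abs(fit$snp_effects - orc$u)), 1e-6)
  }
})

test_that("penalty endpoints coincide with ridge and lasso", {
  std <- random_std(30, 8, seed = 13)
  set.seed(14)
  y <- rnorm(30)
  lam <- 0.2
  # alpha = 0: ridge closed form at matched penalty (glmnet objective
  # RSS/(2n) + lambda/2 ||u||^2 => (Z'Z/n + lambda I) u = Z'(y - ybar)/n)
  f0 <- fit_elastic_net(std, y, alpha_grid = 0, lambda = lam)
  Z <- std$Z
  n <- nrow(Z)
  u_ridge <- solve(crossprod(Z) / n + lam * diag(8), crossprod(Z, y - mean(y)) / n)
  expect_lt(max(abs(f0$snp_effects - u_ridge)), 1e-6)
  # alpha = 1 equals fit_lasso at the same lambda
  f1 <- fit_elastic_net(std, y, alpha_grid = 1, lambda = lam)
  fl <- fit_lasso(std, y, lambda = lam)
  expect_lt(max(abs(f1$snp_effects - fl$snp_effects)), 1e-8)
})

test_that("lambda at or above lambda_max zeroes every lasso effect", {
  std <- random_std(30, 6, seed = 15)
  set.seed(16)
  y <- rnorm(30)
  lam_max <- max(abs(crossprod(std$Z, y - mean(y)))) / 30
  fit <- fit_lasso(std, y, lambda = lam_max * 1.0001)
  expect_true(all(fit$snp_effects == 0))
})

test_that("inner-CV lasso finds a planted QTL through LD proxies", {
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_lines = 200, n_snps_per_chrom = rep(50L, 10),
                      architecture = "major_qtl", qtl_variance_fraction = 0.3,
                      qtl_chromosome = 7, heritability = 0.95, seed = 700 + s)
    panel <- simulate_genotypes(cfg)
    st <- simulate_trait(panel, cfg)
    std <- impute_and_standardize(panel, drop_monomorphic = TRUE)
    set.seed(s)
    fit <- fit_lasso(std, st$trait, nlambda = 60)
    active <- names(fit$snp_effects)[fit$snp_effects != 0]
    causal <- st$truth$qtl_snp_id
    ok <- causal %in% active ||
      any(vapply(active, function(a) cor(std$Z[, a], std$Z[, causal])^2 > 0.8,
                 logical(1)))
    if (ok) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("RKHS degenerates gracefully and selects theta by likelihood", {
  sim <- quick_sim(seed = 17, n_lines = 60, snps_per_chrom = 15)
  st <- simulate_trait(sim$panel, sim$cfg)
  fit <- fit_rkhs(sim$panel, st$trait,
                  theta_grid = exp(seq(log(0.1), log(100), length.out = 8)))
  expect_s3_class(fit, "wgp_rkhs")
  expect_true(fit$hyperparams$theta >= 0.1 - 1e-9 &&
                fit$hyperparams$theta <= 100 + 1e-9)
  prof <- fit$diagnostics$theta_profile
  expect_equal(max(prof$loglik, na.rm = TRUE), fit$hyperparams$loglik)
  # training predictions equal mu + ghat
  pred <- predict(fit, sim$panel)
  expect_lt(max(abs(pred - (fit$mu + fit$genotype_effects))), 1e-8)
})

test_that("all five fits absorb a constant shift of the response", {
  sim <- quick_sim(seed = 18, n_lines = 50, snps_per_chrom = 8)
  st <- simulate_trait(sim$panel, sim$cfg)
  std <- impute_and_standardize(sim$panel, drop_monomorphic = TRUE)
  y <- st$trait$value
  shift <- 100
  test_panel <- sim$panel

  f1 <- fit_rrblup(std, y); f1s <- fit_rrblup(std, y + shift)
  expect_equal(predict(f1, test_panel) + shift, predict(f1s, test_panel),
               tolerance = 1e-6)
  set.seed(20); f2 <- fit_lasso(std, y, lambda = 0.1)
  set.seed(20); f2s <- fit_lasso(std, y + shift, lambda = 0.1)
  expect_equal(predict(f2, test_panel) + shift, predict(f2s, test_panel),
               tolerance = 1e-6)
  f3 <- fit_rkhs(sim$panel, y, theta_grid = c(0.5, 2))
  f3s <- fit_rkhs(sim$panel, y + shift, theta_grid = c(0.5, 2))
  expect_equal(predict(f3, test_panel) + shift, predict(f3s, test_panel),
               tolerance = 1e-5)
  f4 <- fit_bayesb(std, y, n_iter = 600, burn_in = 100, thin = 2, seed = 21)
  f4s <- fit_bayesb(std, y + shift, n_iter = 600, burn_in = 100, thin = 2, seed = 21)
  expect_equal(predict(f4, test_panel) + shift, predict(f4s, test_panel),
               tolerance = 0.05 * sd(y))
})

test_that("prediction validates SNP sets and imputes missing new data to the mean", {
  sim <- quick_sim(seed = 22, n_lines = 40, snps_per_chrom = 6)
  st <- simulate_trait(sim$panel, sim$cfg)
  std <- impute_and_standardize(sim$panel, drop_monomorphic = TRUE)
  fit <- fit_rrblup(std, st$trait)
  # missing SNPs in newdata -> error naming them
  small <- subset_panel(sim$panel, snps = 1:10)
  expect_error(predict(fit, small), "lacks")
  # an all-missing line predicts exactly mu
  x <- sim$panel$dosages[1:2, , drop = FALSE]
  x[1, ] <- NA
  expect_equal(unname(predict(fit, x)[1]), fit$mu, tolerance = 1e-10)
})

test_that("tidy and glance methods return well-formed tibbles", {
  sim <- quick_sim(seed = 23, n_lines = 30, snps_per_chrom = 5)
  st <- simulate_trait(sim$panel, sim$cfg)
  std <- impute_and_standardize(sim$panel, drop_monomorphic = TRUE)
  fit <- fit_rrblup(std, st$trait)
  td <- tidy(fit)
  expect_named(td, c("snp_id", "chrom", "pos", "effect"))
  expect_equal(nrow(td), ncol(std$Z))
  gl <- glance(fit)
  expect_equal(gl$model, "rrblup")
  expect_true(is.finite(gl$lambda_RR))
})
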