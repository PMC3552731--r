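test_that("GRM matches direct arithmetic and diagonal averages to one", {
  # single SNP column (-1, 1): G = [[1,-1],[-1,1]]
  std <- std_from_matrix(matrix(c(-1, 1), 2, 1))
  G <- build_grm(std)
  expect_equal(unname(G$values), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)

  sim <- quick_sim(seed = 8, n_lines = 40, snps_per_chrom = 15)
  std2 <- impute_and_standardize(sim$panel, drop_monomorphic = TRUE)
  G2 <- build_grm(std2)
  # population-sd standardization makes mean(diag(G)) exactly 1
  expect_equal(mean(diag(G2$values)), 1, tolerance = 1e-12)
  expect_lt(max(abs(G2$values - t(G2$values))), 1e-10)
})

test_that("chromosome kernels recombine into the whole-genome GRM", {
  sim <- quick_sim(seed = 13, n_lines = 30, snps_per_chrom = 12)
  std <- impute_and_standardize(sim$panel, drop_monomorphic = TRUE)
  G <- build_grm(std)$values
  p <- ncol(std$Z)
  acc <- matrix(0, nrow(G), ncol(G))
  for (ch in 1:10) {
    Gc <- build_grm(std, chromosome = ch)
    pc <- sum(std$snp_map$chrom == ch)
    acc <- acc + Gc$values * pc / p
  }
  expect_lt(max(abs(acc - G)), 1e-10)
  expect_error(build_grm(std, chromosome = 11), "no SNPs")
})

test_that("modified Rogers' distance is a scaled metric on dosages", {
  # identical lines -> 0; full opposite homozygotes -> exactly 1
  d <- rbind(L1 = c(0, 0, 0, 0), L2 = c(2, 2, 2, 2), L3 = c(0, 0, 0, 0),
             L4 = c(0, 2, 0, 2))
  colnames(d) <- paste0("S", 1:4)
  D <- modified_rogers_distance(d)
  expect_equal(D["L1", "L3"], 0)
  expect_equal(D["L1", "L2"], 1)
  expect_equal(D["L1", "L4"], sqrt(8 / 16))
  # heterozygote contributes half the contrast of an opposite homozygote
  dh <- rbind(A = c(0, 0), B = c(1, 1), C = c(2, 2))
  Dh <- modified_rogers_distance(dh)
  expect_equal(Dh["A", "B"], 0.5)
  expect_equal(Dh["A", "C"], 1)

  # triangle inequality on random panels
  sim <- quick_sim(seed = 21, n_lines = 12, snps_per_chrom = 10)
  Dr <- modified_rogers_distance(sim$panel)
  n <- nrow(Dr)
  for (i in 1:n) for (j in 1:n) for (k in 1:5) {
    expect_lte(Dr[i, j], Dr[i, k] + Dr[k, j] + 1e-12)
  }
  expect_true(all(Dr >= 0 & Dr <= 1))
})

test_that("nearest_pd is a fixed point on PD matrices and clips a diagonal", {
  A <- crossprod(matrix(rnorm(25), 5))
  diag(A) <- diag(A) + 0.5
  out <- nearest_pd(A)
  expect_lt(max(abs(out - A)), 1e-10)
  expect_false(attr(out, "repaired"))

  Dm <- diag(c(1, -0.5))
  out2 <- nearest_pd(Dm, eig_floor = 1e-8)
  expect_equal(diag(out2), c(1, 1e-8), tolerance = 1e-7)
  expect_lt(abs(out2[1, 2]), 1e-9)

  expect_error(nearest_pd(matrix(1:6, 2, 3)), "symmetric")
})

test_that("nearest_pd is at least as close as naive eigenvalue clipping", {
  set.seed(99)
  for (i in 1:5) {
    M <- matrix(rnorm(25), 5); M <- (M + t(M)) / 2
    out <- nearest_pd(M, eig_floor = 0)
    ev <- eigen(M, symmetric = TRUE)
    clip <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    expect_lte(norm(out - M, "F"), norm(clip - M, "F") + 1e-6)
    expect_gte(min(eigen(out, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("LD profile reports perfect r2 for duplicated columns and noise floor otherwise", {
  n <- 60
  set.seed(31)
  x <- sample(c(0, 2), n, replace = TRUE)
  d <- cbind(S1 = x, S2 = x, S3 = sample(c(0, 2), n, TRUE))
  rownames(d) <- sprintf("L%02d", 1:n)
  panel <- genotype_panel(d, data.frame(snp_id = colnames(d), chrom = 1,
                                        pos = c(100, 200, 100000)))
  ld <- ld_r2_profile(panel, max_dist_bp = 2e5, n_bins = 4)
  expect_equal(ld$profile$mean_r2[1], 1)  # duplicated SNPs, first bin

  # independent SNPs: mean r2 ~ 1/(n-1) small-sample bias
  set.seed(32)
  p <- 80
  ind <- matrix(sample(c(0, 2), n * p, replace = TRUE), n, p)
  rownames(ind) <- sprintf("L%02d", 1:n)
  colnames(ind) <- sprintf("S%02d", 1:p)
  panel2 <- genotype_panel(ind, data.frame(snp_id = colnames(ind), chrom = 1,
                                           pos = (1:p) * 1000))
  ld2 <- ld_r2_profile(panel2, max_dist_bp = 1e5, n_bins = 2)
  overall <- sum(ld2$profile$mean_r2 * ld2$profile$n_pairs) / sum(ld2$profile$n_pairs)
  expect_equal(overall, 1 / (n - 1), tolerance = 0.35)
})

test_that("simulated panels cross r2 = 0.1 near the configured decay distance", {
  cross <- vapply(1:3, function(s) {
    p <- simulate_genotypes(sim_config(n_lines = 300,
                                       n_snps_per_chrom = rep(500L, 10),
                                       ld_decay_bp = 5e5, seed = 500 + s))
    ld_decay_distance(ld_r2_profile(p, max_dist_bp = 2e6, n_bins = 40))
  }, numeric(1))
  expect_gt(mean(cross), 3.5e5)
  expect_lt(mean(cross), 6.5e5)
})

test_that("gaussian kernel decays with distance and repair flags propagate", {
  sim <- quick_sim(seed = 41, n_lines = 15, snps_per_chrom = 8)
  D <- modified_rogers_distance(sim$panel)
  K <- gaussian_kernel(D, theta = 0.5)
  expect_equal(unname(diag(K$values)), rep(1, 15))
  expect_true(all(K$values <= 1 + 1e-12))
  expect_equal(K$kind, "gaussian_K")
  Kr <- repair_kernel(K)
  ev <- eigen(Kr$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})
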