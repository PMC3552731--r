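test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_lines = 0), "invalid config")
  expect_error(sim_config(heritability = 0), "invalid config")
  expect_error(sim_config(heritability = 1.2), "invalid config")
  expect_error(sim_config(architecture = "major_qtl", qtl_variance_fraction = 0,
                          qtl_chromosome = 2), "invalid config")
  expect_error(sim_config(architecture = "major_qtl", qtl_variance_fraction = 0.3),
               "invalid config")
  expect_error(sim_config(chrom_lengths_bp = c(-1, rep(1e6, 9))), "invalid config")
})

test_that("clean configs give pure homozygotes and fixed seeds reproduce exactly", {
  sim <- quick_sim(seed = 7, n_lines = 40, snps_per_chrom = 30)
  expect_true(all(sim$panel$dosages %in% c(0, 2)))
  sim2 <- quick_sim(seed = 7, n_lines = 40, snps_per_chrom = 30)
  expect_identical(sim$panel$dosages, sim2$panel$dosages)
  expect_identical(sim$panel$snp_map, sim2$panel$snp_map)

  st1 <- simulate_trait(sim$panel, sim$cfg)
  st2 <- simulate_trait(sim2$panel, sim2$cfg)
  expect_identical(st1$trait$value, st2$trait$value)
  expect_identical(st1$truth$causal_effects$effect, st2$truth$causal_effects$effect)
})

test_that("heterozygote and missing corruption hits the requested rates", {
  sim <- quick_sim(seed = 3, n_lines = 50, snps_per_chrom = 40,
                   het_rate = 0.02, missing_rate = 0.05)
  d <- sim$panel$dosages
  expect_gt(mean(is.na(d)), 0.03)
  expect_lt(mean(is.na(d)), 0.07)
  expect_gt(mean(d == 1, na.rm = TRUE), 0.005)
  # clean matrix kept for trait simulation
  expect_false(anyNA(sim$panel$clean_dosages))
  st <- simulate_trait(sim$panel, sim$cfg)
  expect_length(st$truth$genetic_values, 50)
})

test_that("SNP positions are sorted and MAFs respect the configured range", {
  sim <- quick_sim(seed = 5, n_lines = 200, snps_per_chrom = 80,
                   maf_range = c(0.1, 0.4))
  map <- sim$panel$snp_map
  for (ch in 1:10) {
    expect_true(all(diff(map$pos[map$chrom == ch]) > 0))
  }
  freq <- colMeans(sim$panel$dosages) / 2
  maf <- pmin(freq, 1 - freq)
  # panel MAF fluctuates around the founder MAF; the bulk must sit in-range
  expect_gt(mean(maf >= 0.05 & maf <= 0.5), 0.9)
})

test_that("heritability = 1 gives phenotype equal to genetic value", {
  sim <- quick_sim(seed = 2, n_lines = 30, snps_per_chrom = 10, heritability = 1)
  st <- simulate_trait(sim$panel, sim$cfg)
  expect_equal(unname(st$trait$value),
               unname(st$truth$genetic_values[st$trait$line_id]),
               tolerance = 1e-12)
  expect_equal(st$truth$realized_h2, 1, tolerance = 1e-12)
})

test_that("realized heritability and QTL fraction match their targets", {
  for (s in 1:3) {
    cfg <- sim_config(n_lines = 150, n_snps_per_chrom = rep(50L, 10),
                      architecture = "major_qtl", qtl_variance_fraction = 0.289,
                      qtl_chromosome = 3, heritability = 0.9, seed = 30 + s)
    panel <- simulate_genotypes(cfg)
    st <- simulate_trait(panel, cfg)
    expect_equal(st$truth$realized_h2, 0.9, tolerance = 0.02)
    expect_equal(st$truth$realized_qtl_variance_fraction, 0.289, tolerance = 0.02)
    expect_match(st$truth$qtl_snp_id, "^chr3_")
  }
})

test_that("QTL regression on dosage recovers the target share of phenotypic variance", {
  # brute-force check: R^2 of y on the causal dosage ~= fraction * h2
  r2 <- replicate(15, {
    s <- sample.int(1e4, 1)
    cfg <- sim_config(n_lines = 200, n_snps_per_chrom = rep(40L, 10),
                      architecture = "major_qtl", qtl_variance_fraction = 0.289,
                      qtl_chromosome = 2, heritability = 0.97, seed = s)
    panel <- simulate_genotypes(cfg)
    st <- simulate_trait(panel, cfg)
    x <- panel$dosages[, st$truth$qtl_snp_id]
    summary(lm(st$trait$value ~ x))$r.squared
  })
  expect_equal(mean(r2), 0.289 * 0.97, tolerance = 0.03)
})

test_that("per-chromosome genetic variances sum exactly to the total", {
  sim <- quick_sim(seed = 9, n_lines = 60, snps_per_chrom = 25)
  st <- simulate_trait(sim$panel, sim$cfg)
  expect_equal(sum(st$truth$per_chromosome_genetic_variance), 1, tolerance = 1e-8)
  # squared correlation of g with y reflects realized h2
  expect_equal(
    cor(st$truth$genetic_values, st$trait$value)^2,
    st$truth$realized_h2, tolerance = 0.02
  )
})

test_that("polygenic traits have no dominant single SNP", {
  worst <- replicate(20, {
    s <- sample.int(1e4, 1)
    cfg <- sim_config(n_lines = 100, n_snps_per_chrom = rep(200L, 10), seed = s)
    panel <- simulate_genotypes(cfg)
    st <- simulate_trait(panel, cfg)
    g <- st$truth$genetic_values
    eff <- st$truth$causal_effects
    top <- eff$snp_id[which.max(abs(eff$effect))]
    cor(panel$dosages[, top], g)^2
  })
  expect_lt(mean(worst), 0.10)
})

test_that("adjacent-SNP r2 lands in the maize-like band", {
  adj <- vapply(1:10, function(s) {
    p <- simulate_genotypes(sim_config(n_lines = 300,
                                       n_snps_per_chrom = rep(500L, 10),
                                       ld_decay_bp = 5e5, seed = 1000 + s))
    ld_r2_profile(p, max_dist_bp = 1e6, n_bins = 10)$mean_adjacent_r2
  }, numeric(1))
  expect_gt(mean(adj), 0.25)
  expect_lt(mean(adj), 0.45)
})

test_that("simulation files round-trip through the writers", {
  sim <- quick_sim(seed = 4, n_lines = 15, snps_per_chrom = 6)
  st <- simulate_trait(sim$panel, sim$cfg)
  td <- withr::local_tempdir()
  g <- file.path(td, "g.tsv"); m <- file.path(td, "m.tsv")
  ph <- file.path(td, "p.tsv"); tr <- file.path(td, "t.json")
  write_genotypes(sim$panel, g, m)
  write_phenotypes(st$trait, ph)
  write_sim_truth(st$truth, tr)
  back <- read_genotypes(g, m)
  expect_equal(back$dosages, sim$panel$dosages)
  expect_equal(as.data.frame(back$snp_map), as.data.frame(sim$panel$snp_map))
  pb <- read_phenotypes(ph)
  expect_equal(pb$value, st$trait$value)
  js <- jsonlite::read_json(tr)
  expect_equal(js$realized_h2, st$truth$realized_h2, tolerance = 1e-9)
})
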