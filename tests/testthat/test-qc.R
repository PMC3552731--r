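make_qc_panel <- function() {
  # 20 lines x 6 SNPs engineered around each QC boundary
  n <- 20
  d <- matrix(2, n, 6)
  base <- rep(c(0, 2), length.out = n)
  for (j in 1:6) d[, j] <- base
  # S1: exactly 10% missing (2/20) -> kept
  d[1:2, 1] <- NA
  # S2: 15% missing (3/20) -> removed
  d[1:3, 2] <- NA
  # S3: MAF exactly 0.025 -> removed (strict "greater than")
  d[, 3] <- 0; d[1, 3] <- 1       # 1/40 alleles = 0.025
  # S4: MAF 0.075 -> kept
  d[, 4] <- 0; d[1:3, 4] <- 2     # 6/40 = 0.15... keep simple, clearly above
  # S5: 3 hets -> kept
  d[, 5] <- base; d[1:3, 5] <- 1
  # S6: 4 hets -> removed
  d[, 6] <- base; d[1:4, 6] <- 1
  rownames(d) <- sprintf("L%02d", 1:n)
  colnames(d) <- paste0("S", 1:6)
  genotype_panel(d, data.frame(snp_id = paste0("S", 1:6), chrom = 1,
                               pos = (1:6) * 100))
}

test_that("each QC boundary behaves as specified", {
  res <- apply_snp_qc(make_qc_panel())
  kept <- res$panel$snp_map$snp_id
  expect_true("S1" %in% kept)    # 10% missing allowed
  expect_false("S2" %in% kept)   # >10% missing removed
  expect_false("S3" %in% kept)   # MAF == 0.025 removed
  expect_true("S4" %in% kept)
  expect_true("S5" %in% kept)    # 3 hets allowed
  expect_false("S6" %in% kept)   # 4 hets removed
  rep_tbl <- res$report
  expect_equal(rep_tbl$n_snps[rep_tbl$criterion == "missing"], 1)
  expect_equal(rep_tbl$n_snps[rep_tbl$criterion == "het"], 1)
  expect_equal(rep_tbl$n_snps[rep_tbl$criterion == "total_removed"], 3)
  expect_equal(rep_tbl$n_snps[rep_tbl$criterion == "retained"], 3)
})

test_that("conflicting replicate checks remove the SNP", {
  panel <- toy_panel(n = 10, p = 4, seed = 1)
  d <- panel$dosages
  # lines L01, L02 are replicated checks; make them disagree at S01 only
  d[c(1, 2), 1] <- c(0, 2)
  d[c(1, 2), 2] <- c(2, 2)
  d[1, 3] <- NA  # missing does not count as conflict
  d[2, 3] <- 0
  panel2 <- genotype_panel(d, panel$snp_map,
                           check_replicate_groups = c(L01 = "B73", L02 = "B73"))
  res <- apply_snp_qc(panel2, min_maf = 0)
  expect_false("S01" %in% res$panel$snp_map$snp_id)
  expect_true(all(c("S02", "S03") %in% res$panel$snp_map$snp_id))
  expect_equal(res$report$n_snps[res$report$criterion == "replicate_conflict"], 1)
})

test_that("QC filters are order-independent per-SNP predicates", {
  panel <- make_qc_panel()
  full <- apply_snp_qc(panel)$panel$snp_map$snp_id
  # apply filters one at a time in two different orders
  seq1 <- apply_snp_qc(panel, max_missing = 0.10, min_maf = 0, max_het = Inf)$panel
  seq1 <- apply_snp_qc(seq1, max_missing = 1, min_maf = 0.025, max_het = Inf)$panel
  seq1 <- apply_snp_qc(seq1, max_missing = 1, min_maf = 0, max_het = 3)$panel
  seq2 <- apply_snp_qc(panel, max_missing = 1, min_maf = 0, max_het = 3)$panel
  seq2 <- apply_snp_qc(seq2, max_missing = 1, min_maf = 0.025, max_het = Inf)$panel
  seq2 <- apply_snp_qc(seq2, max_missing = 0.10, min_maf = 0, max_het = Inf)$panel
  expect_setequal(seq1$snp_map$snp_id, full)
  expect_setequal(seq2$snp_map$snp_id, full)
})

test_that("all SNPs removed is an error, dosages re-orient to the minor allele", {
  panel <- toy_panel(n = 6, p = 3, seed = 2)
  expect_error(apply_snp_qc(panel, min_maf = 0.5), "all SNPs removed")
  res <- apply_snp_qc(panel)
  freq <- colMeans(res$panel$dosages) / 2
  expect_true(all(freq <= 0.5 + 1e-12))
})

test_that("imputation and standardization meet their contracts", {
  # worked example: column (0,2,2,0) -> (-1,1,1,-1)
  d <- cbind(S1 = c(0, 2, 2, 0), S2 = c(0, 0, 2, 2))
  rownames(d) <- paste0("L", 1:4)
  panel <- genotype_panel(d, data.frame(snp_id = c("S1", "S2"), chrom = 1,
                                        pos = c(100, 200)))
  std <- impute_and_standardize(panel)
  expect_equal(unname(std$Z[, "S1"]), c(-1, 1, 1, -1))

  # random panel: column means ~ 0, population sds ~ 1, no missing
  sim <- quick_sim(seed = 12, n_lines = 50, snps_per_chrom = 20,
                   missing_rate = 0.03)
  std2 <- impute_and_standardize(sim$panel, drop_monomorphic = TRUE)
  expect_false(anyNA(std2$Z))
  expect_lt(max(abs(colMeans(std2$Z))), 1e-10)
  expect_lt(max(abs(colMeans(std2$Z^2) - 1)), 1e-10)

  # idempotence: standardizing an already standardized matrix changes nothing
  zpan <- std_from_matrix(std2$Z)
  restd <- sweep(sweep(zpan$Z, 2, colMeans(zpan$Z)), 2,
                 sqrt(colMeans(sweep(zpan$Z, 2, colMeans(zpan$Z))^2)), "/")
  expect_lt(max(abs(restd - std2$Z)), 1e-12)
})

test_that("monomorphic SNPs error with the SNP named, or drop on request", {
  d <- cbind(S1 = c(0, 2, 0, 2), S2 = c(2, 2, 2, 2))
  rownames(d) <- paste0("L", 1:4)
  panel <- genotype_panel(d, data.frame(snp_id = c("S1", "S2"), chrom = 1,
                                        pos = c(1, 2)))
  expect_error(impute_and_standardize(panel), "S2")
  std <- impute_and_standardize(panel, drop_monomorphic = TRUE)
  expect_equal(colnames(std$Z), "S1")
})
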