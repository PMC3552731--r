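#' SNP quality control for an inbred-line panel
#'
#' Applies the standard chip-QC filters for inbred diversity panels. A SNP is
#' removed when any of the following holds:
#' \describe{
#'   \item{missing}{more than `max_missing` of its calls are missing;}
#'   \item{maf}{its minor allele frequency is not greater than `min_maf`
#'     (strict inequality, so a SNP at exactly the threshold is removed);}
#'   \item{het}{more than `max_het` lines carry a heterozygous call;}
#'   \item{replicate_conflict}{lines declared as replicated checks of the
#'     same genotype carry conflicting non-missing calls.}
#' }
#' Surviving SNPs are re-oriented so that the dosage counts the minor allele
#' in the retained panel (ties at frequency 0.5 keep the input orientation).
#' The filters are per-SNP predicates, so their order of application does not
#' affect the retained set.
#'
#' @param panel A [genotype_panel()].
#' @param max_missing Maximum tolerated fraction of missing calls (default 0.10).
#' @param min_maf Minor-allele-frequency threshold; SNPs with MAF strictly
#'   greater than this are kept (default 0.025).
#' @param max_het Maximum tolerated number of heterozygous calls (default 3).
#' @return A list with `panel` (the filtered, minor-allele-oriented
#'   `genotype_panel`) and `report` (tibble: one row per criterion with the
#'   number of SNPs violating it, plus totals).
#' @export
apply_snp_qc <- function(panel, max_missing = 0.10, min_maf = 0.025,
                         max_het = 3) {
  d <- panel$dosages
  n <- nrow(d)
  if (n == 0 || ncol(d) == 0) abort("empty panel.")

  miss_frac <- colMeans(is.na(d))
  freq <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0
  n_het <- colSums(d == 1, na.rm = TRUE)

  fail_missing <- miss_frac > max_missing
  fail_maf <- !(maf > min_maf)
  fail_het <- n_het > max_het

  fail_rep <- rep(FALSE, ncol(d))
  grp <- panel$check_replicate_groups
  if (!is.null(grp)) {
    for (g in unique(grp)) {
      ids <- names(grp)[grp == g]
      ids <- intersect(ids, rownames(d))
      if (length(ids) < 2) next
      sub <- d[ids, , drop = FALSE]
      n_distinct <- apply(sub, 2, function(x) length(unique(x[!is.na(x)])))
      fail_rep <- fail_rep | n_distinct > 1
    }
  }

  fail_any <- fail_missing | fail_maf | fail_het | fail_rep
  report <- tibble(
    criterion = c("missing", "maf", "het", "replicate_conflict", "total_removed", "retained"),
    n_snps = c(sum(fail_missing), sum(fail_maf), sum(fail_het), sum(fail_rep),
               sum(fail_any), sum(!fail_any))
  )
  if (all(fail_any)) abort("all SNPs removed by QC.")

  keep <- which(!fail_any)
  d2 <- d[, keep, drop = FALSE]
  # minor-allele orientation in the retained panel
  flip <- colMeans(d2, na.rm = TRUE) / 2 > 0.5
  d2[, flip] <- 2 - d2[, flip]
  out <- genotype_panel(
    d2,
    panel$snp_map[keep, , drop = FALSE],
    panel$check_replicate_groups
  )
  list(panel = out, report = report)
}

#' Impute missing dosages and standardize SNP columns
#'
#' Missing entries are replaced by the SNP's mean dosage, then every column
#' is centered and scaled to unit standard deviation. The population standard
#' deviation (denominator n) is used so that the mean diagonal of the
#' relationship matrix `ZZ'/p` built from the result is exactly 1.
#'
#' @param panel A [genotype_panel()] that passed QC.
#' @param drop_monomorphic If `FALSE` (default) a monomorphic SNP raises an
#'   error naming the SNP; if `TRUE` such SNPs are silently dropped (used
#'   inside cross-validation where a fold's training split can lose an
#'   allele).
#' @return An object of class `std_geno`: list with `Z` (n x p standardized
#'   matrix), `col_means`, `col_sds`, `snp_map`.
#' @export
impute_and_standardize <- function(panel, drop_monomorphic = FALSE) {
  d <- panel$dosages
  cm <- colMeans(d, na.rm = TRUE)
  if (anyNA(d)) {
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- cm[idx[, 2]]
  }
  n <- nrow(d)
  ctr <- sweep(d, 2, cm)
  sds <- sqrt(colMeans(ctr^2))  # population sd
  mono <- sds == 0
  if (any(mono)) {
    if (!drop_monomorphic) {
      abort(sprintf(
        "monomorphic SNP(s) cannot be standardized: %s",
        paste(head(colnames(d)[mono], 5), collapse = ", ")
      ))
    }
    ctr <- ctr[, !mono, drop = FALSE]
    sds <- sds[!mono]
    cm <- cm[!mono]
  }
  Z <- sweep(ctr, 2, sds, "/")
  structure(
    list(
      Z = Z,
      col_means = cm,
      col_sds = sds,
      snp_map = panel$snp_map[match(colnames(Z), panel$snp_map$snp_id), , drop = FALSE]
    ),
    class = "std_geno"
  )
}

#' @export
print.std_geno <- function(x, ...) {
  cat(sprintf("<std_geno> %d lines x %d standardized SNPs\n",
              nrow(x$Z), ncol(x$Z)))
  invisible(x)
}
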