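#' Genotype panel of inbred lines
#'
#' A `genotype_panel` bundles an n-lines-by-p-SNPs dosage matrix (counts of
#' one allele, values 0/1/2 or `NA`) with its SNP map. Inbred panels are
#' expected to be almost entirely homozygous, so dosages concentrate on
#' \{0, 2\}; heterozygous calls (1) and missing values are tolerated until
#' quality control.
#'
#' @param dosages Numeric matrix, lines in rows, SNPs in columns. Row names
#'   (line ids) and column names (SNP ids) are required; values must be in
#'   \{0, 1, 2, NA\}.
#' @param snp_map Data frame with columns `snp_id`, `chrom` (integer 1-10),
#'   `pos` (1-based bp), one row per column of `dosages`, positions strictly
#'   increasing within chromosome.
#' @param check_replicate_groups Optional named character/integer vector
#'   mapping line ids to replicate-group labels: lines sharing a label are
#'   replicated checks of the same genotype and must agree at every SNP.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages`, `snp_map` (tibble) and `check_replicate_groups`.
#' @export
genotype_panel <- function(dosages, snp_map, check_replicate_groups = NULL) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)) || is.null(colnames(dosages))) {
    abort("`dosages` must carry line ids as row names and SNP ids as column names.")
  }
  if (anyDuplicated(rownames(dosages))) abort("line ids must be unique.")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) abort("dosage values must be 0, 1, 2 or NA.")
  snp_map <- as_tibble(snp_map)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snp_map)))
  if (nrow(snp_map) != ncol(dosages)) {
    abort("`snp_map` must have one row per SNP column.")
  }
  if (!identical(as.character(snp_map$snp_id), colnames(dosages))) {
    abort("`snp_map$snp_id` must match the dosage column names in order.")
  }
  for (ch in unique(snp_map$chrom)) {
    p <- snp_map$pos[snp_map$chrom == ch]
    if (any(diff(p) <= 0)) {
      abort(sprintf("positions must be strictly increasing within chromosome %s.", ch))
    }
  }
  structure(
    list(
      dosages = dosages,
      snp_map = snp_map,
      check_replicate_groups = check_replicate_groups
    ),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  d <- x$dosages
  n_miss <- sum(is.na(d))
  n_het <- sum(d == 1, na.rm = TRUE)
  cat(sprintf(
    "<genotype_panel> %d lines x %d SNPs on %d chromosome(s)\n",
    nrow(d), ncol(d), length(unique(x$snp_map$chrom))
  ))
  cat(sprintf(
    "  missing: %.2f%%  heterozygous: %.2f%%\n",
    100 * n_miss / length(d), 100 * n_het / length(d)
  ))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

n_lines <- function(panel) nrow(panel$dosages)
n_snps <- function(panel) ncol(panel$dosages)

#' Subset a genotype panel
#'
#' @param panel A [genotype_panel()].
#' @param lines,snps Line ids / row indices and SNP ids / column indices to
#'   keep (default: all).
#' @return A `genotype_panel` restricted to the requested lines and SNPs.
#' @export
subset_panel <- function(panel, lines = NULL, snps = NULL) {
  d <- panel$dosages
  if (!is.null(lines)) d <- d[lines, , drop = FALSE]
  map <- panel$snp_map
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    map <- map[match(colnames(d), map$snp_id), , drop = FALSE]
  }
  grp <- panel$check_replicate_groups
  if (!is.null(grp)) grp <- grp[names(grp) %in% rownames(d)]
  genotype_panel(d, map, if (length(grp)) grp else NULL)
}

# ---- file formats ----------------------------------------------------------

#' Write / read a genotype panel as TSV
#'
#' Two files: a dosage matrix (first column `line_id`, then one column per
#' SNP, values 0/1/2/NA) and a SNP map (`snp_id`, `chrom`, `pos`, 1-based).
#'
#' @param panel A [genotype_panel()].
#' @param geno_file,map_file Paths for the dosage matrix and the SNP map.
#' @return `write_genotypes()` returns the paths invisibly; `read_genotypes()`
#'   returns a `genotype_panel`.
#' @export
write_genotypes <- function(panel, geno_file, map_file) {
  df <- data.frame(line_id = rownames(panel$dosages), panel$dosages,
                   check.names = FALSE)
  write.table(df, geno_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(panel$snp_map), map_file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(geno_file, map_file))
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(geno_file, map_file) {
  df <- read.table(geno_file, header = TRUE, sep = "\t", check.names = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- as.character(df[[1]])
  map <- read.table(map_file, header = TRUE, sep = "\t", check.names = FALSE)
  genotype_panel(d, map)
}

#' Read a genotype panel from a VCF file
#'
#' Biallelic SNPs only; the GT field is converted to an alternate-allele
#' dosage (0/1/2, missing for `./.`). Requires the vcfR package.
#'
#' @param vcf_file Path to an (uncompressed or gzipped) VCF.
#' @return A [genotype_panel()].
#' @export
read_vcf_panel <- function(vcf_file) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf_panel() requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  v <- v[biallelic, ]
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, 2, function(g) {
    g <- sub(":.*$", "", g)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0", "0|0")] <- 0
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    out[g %in% c("1/1", "1|1")] <- 2
    out
  })
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  d <- t(dose)
  colnames(d) <- ids
  map <- tibble(
    snp_id = ids,
    chrom = as.integer(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"])
  )
  ord <- order(map$chrom, map$pos)
  genotype_panel(d[, ord, drop = FALSE], map[ord, ])
}

#' Write / read a phenotype table as TSV
#'
#' Columns: `line_id`, `trait`, `value`, `h2` (line-mean heritability or
#' repeatability of the trait).
#'
#' @param pheno Data frame with the four columns above.
#' @param file Path.
#' @return `read_phenotypes()` returns a tibble.
#' @export
write_phenotypes <- function(pheno, file) {
  stopifnot(all(c("line_id", "trait", "value", "h2") %in% names(pheno)))
  write.table(as.data.frame(pheno), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(file) {
  as_tibble(read.table(file, header = TRUE, sep = "\t", check.names = FALSE))
}

#' Write a kernel matrix as TSV with line ids in header row and first column
#'
#' @param kernel A [kernel_matrix()] or plain symmetric matrix with dimnames.
#' @param file Path.
#' @export
write_kernel <- function(kernel, file) {
  m <- if (inherits(kernel, "kernel_matrix")) kernel$values else kernel
  df <- data.frame(line_id = rownames(m), m, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
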