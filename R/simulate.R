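#' Configuration for the synthetic inbred-panel generator
#'
#' Describes a maize-like diversity panel of fully homozygous inbred lines:
#' 10 chromosomes, tens of kb between adjacent SNPs, strong local linkage
#' disequilibrium (adjacent-SNP r-squared around 0.34 decaying with physical
#' distance), and traits that are either highly polygenic or carry a single
#' major QTL on a known chromosome contributing a set fraction of the
#' genetic variance on top of a polygenic background.
#'
#' Default chromosome lengths are scaled so that the default marker density
#' (~55 kb between adjacent SNPs at 500 SNPs/chromosome) matches the density
#' of a 50k-SNP chip on a real maize genome; the relative lengths follow the
#' maize karyotype.
#'
#' @param n_lines Number of inbred lines.
#' @param n_snps_per_chrom Integer vector of length 10, SNPs per chromosome.
#' @param chrom_lengths_bp Numeric vector of length 10, chromosome lengths.
#' @param ld_decay_bp Distance at which pairwise r-squared has decayed to
#'   about 0.1 (bp).
#' @param maf_range Interval in (0, 0.5] from which per-SNP founder minor
#'   allele frequencies are drawn uniformly.
#' @param architecture `"polygenic"` (no major QTL), `"major_qtl"` (one major
#'   QTL plus polygenic background) or `"mixed"` (synonym of `"major_qtl"`,
#'   intended for intermediate `qtl_variance_fraction`).
#' @param qtl_variance_fraction Fraction of genetic variance explained by the
#'   major QTL (0-1); must be > 0 under a major-QTL architecture.
#' @param qtl_chromosome Chromosome (1-10) carrying the major QTL.
#' @param heritability Line-mean heritability of the simulated trait, in (0, 1].
#' @param polygenic_density Fraction of polymorphic SNPs carrying a nonzero
#'   polygenic effect (default 0.10, i.e. a dense subset of several hundred
#'   causal loci at default dimensions — "highly polygenic" in the sense of
#'   real agronomic traits, while keeping the trait distinguishable from the
#'   strict infinitesimal model).
#' @param missing_rate,het_rate Fractions of dosage entries set to missing /
#'   heterozygous after trait simulation (the trait truth is unaffected).
#' @param n_founders Size of the founder haplotype pool for the mosaic
#'   copying process.
#' @param seed Integer seed; fixing it fixes every downstream artifact.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 300,
                       n_snps_per_chrom = rep(500L, 10),
                       chrom_lengths_bp = NULL,
                       ld_decay_bp = 5e5,
                       maf_range = c(0.05, 0.5),
                       architecture = c("polygenic", "major_qtl", "mixed"),
                       qtl_variance_fraction = 0,
                       qtl_chromosome = NA_integer_,
                       heritability = 0.95,
                       polygenic_density = 0.10,
                       missing_rate = 0,
                       het_rate = 0,
                       n_founders = 20,
                       seed = 1L) {
  architecture <- match.arg(architecture)
  if (is.null(chrom_lengths_bp)) {
    # maize relative chromosome lengths, rescaled to ~55 kb marker spacing
    rel <- c(301, 244, 236, 247, 223, 169, 176, 181, 159, 151)
    chrom_lengths_bp <- rel / sum(rel) * sum(n_snps_per_chrom) * 5.5e4
  }
  if (n_lines < 1 || any(n_snps_per_chrom < 1)) {
    abort("invalid config: need at least one line and one SNP per chromosome.")
  }
  if (length(n_snps_per_chrom) != 10 || length(chrom_lengths_bp) != 10) {
    abort("invalid config: `n_snps_per_chrom` and `chrom_lengths_bp` must have length 10.")
  }
  if (any(chrom_lengths_bp <= 0)) abort("invalid config: chromosome lengths must be positive.")
  if (any(n_snps_per_chrom > chrom_lengths_bp)) {
    abort("invalid config: more SNPs than bp positions on a chromosome.")
  }
  if (heritability <= 0 || heritability > 1) abort("invalid config: heritability must be in (0, 1].")
  stopifnot(
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2]
  )
  for (fr in c(qtl_variance_fraction, missing_rate, het_rate)) {
    if (fr < 0 || fr > 1) abort("invalid config: fractions must be in [0, 1].")
  }
  if (polygenic_density <= 0 || polygenic_density > 1) {
    abort("invalid config: polygenic_density must be in (0, 1].")
  }
  if (architecture %in% c("major_qtl", "mixed")) {
    if (qtl_variance_fraction <= 0) {
      abort("invalid config: a major-QTL architecture requires qtl_variance_fraction > 0.")
    }
    if (is.na(qtl_chromosome) || qtl_chromosome < 1 || qtl_chromosome > 10) {
      abort("invalid config: a major-QTL architecture requires qtl_chromosome in 1-10.")
    }
  }
  structure(
    list(
      n_lines = as.integer(n_lines),
      n_snps_per_chrom = as.integer(n_snps_per_chrom),
      chrom_lengths_bp = chrom_lengths_bp,
      ld_decay_bp = ld_decay_bp,
      maf_range = maf_range,
      architecture = architecture,
      qtl_variance_fraction = qtl_variance_fraction,
      qtl_chromosome = as.integer(qtl_chromosome),
      heritability = heritability,
      polygenic_density = polygenic_density,
      missing_rate = missing_rate,
      het_rate = het_rate,
      n_founders = as.integer(n_founders),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# LD calibration: the latent founder-haplotype correlation decays as
# exp(-d / L). Empirically the panel-level r^2 between distinct SNPs has an
# intercept of about 0.47 at d -> 0 (attenuation from binary thresholding
# and MAF mismatch), so r^2(d) ~ 0.47 * exp(-2 d / L_eff) and r^2 = 0.1 at
# ld_decay_bp requires L_eff = 2 * ld_decay / log(0.47 / 0.1). Founder-chain
# persistence and mosaic copying share that budget 4:1.
ld_length_scales <- function(ld_decay_bp) {
  l_eff <- 2 * ld_decay_bp / log(0.47 / 0.1)
  list(founder = 4 / 3 * l_eff, copy = 4 * l_eff)
}

#' Simulate genotypes for an inbred-line diversity panel
#'
#' Lines are mosaics of a small founder-haplotype pool (Markov copying along
#' each chromosome); the founder haplotypes themselves carry Markov linkage
#' disequilibrium so that pairwise r-squared between panel SNPs decays with
#' physical distance and reaches about 0.1 at `ld_decay_bp`. Lines are fully
#' homozygous (dosage 0/2); a `het_rate` fraction of entries is then set to 1
#' and a `missing_rate` fraction to `NA`. When either rate is positive the
#' uncorrupted matrix is kept in the `clean_dosages` element so trait
#' simulation sees the true genotypes.
#'
#' @param config A [sim_config()].
#' @return A [genotype_panel()]; SNP ids are `chr<chrom>_s<index>`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_lines
  nf <- config$n_founders
  scales <- ld_length_scales(config$ld_decay_bp)

  chrom_blocks <- vector("list", 10)
  maps <- vector("list", 10)
  for (ch in 1:10) {
    p <- config$n_snps_per_chrom[ch]
    len <- config$chrom_lengths_bp[ch]
    pos <- sort(sample.int(len, p))
    d <- diff(pos)

    # founder haplotypes: latent Gaussian AR(1) thresholded at per-SNP MAF
    q <- runif(p, config$maf_range[1], config$maf_range[2])
    phi <- c(0, exp(-d / scales$founder))
    z <- matrix(0, nf, p)
    z[, 1] <- rnorm(nf)
    for (j in seq_len(p)[-1]) {
      z[, j] <- phi[j] * z[, j - 1] + sqrt(1 - phi[j]^2) * rnorm(nf)
    }
    founders <- (z < matrix(stats::qnorm(q), nf, p, byrow = TRUE)) * 1L
    # keep every SNP polymorphic in the founder pool
    mono <- which(colSums(founders) %in% c(0L, nf))
    for (j in mono) {
      i <- sample.int(nf, 1)
      founders[i, j] <- 1L - founders[i, j]
    }

    # mosaic copying: per line a Markov chain over founder indices
    sw <- c(1, 1 - exp(-d / scales$copy))
    f <- sample.int(nf, n, replace = TRUE)
    alleles <- matrix(0L, n, p)
    alleles[, 1] <- founders[f, 1]
    for (j in seq_len(p)[-1]) {
      switch_now <- runif(n) < sw[j]
      if (any(switch_now)) f[switch_now] <- sample.int(nf, sum(switch_now), replace = TRUE)
      alleles[, j] <- founders[f, j]
    }
    chrom_blocks[[ch]] <- 2L * alleles
    maps[[ch]] <- tibble(
      snp_id = sprintf("chr%d_s%04d", ch, seq_len(p)),
      chrom = ch,
      pos = pos
    )
  }

  dosages <- do.call(cbind, chrom_blocks)
  map <- dplyr::bind_rows(maps)
  rownames(dosages) <- sprintf("L%03d", seq_len(n))
  colnames(dosages) <- map$snp_id

  clean <- NULL
  if (config$het_rate > 0 || config$missing_rate > 0) {
    clean <- dosages
    n_entries <- length(dosages)
    if (config$het_rate > 0) {
      idx <- sample.int(n_entries, round(config$het_rate * n_entries))
      dosages[idx] <- 1
    }
    if (config$missing_rate > 0) {
      idx <- sample.int(n_entries, round(config$missing_rate * n_entries))
      dosages[idx] <- NA
    }
  }
  panel <- genotype_panel(dosages, map)
  panel$clean_dosages <- clean
  panel
}

#' Simulate a trait with controlled genetic architecture
#'
#' Polygenic architecture draws i.i.d. normal additive effects at every
#' polymorphic SNP. A major-QTL architecture additionally places one QTL on
#' `qtl_chromosome` whose effect is solved analytically so that the squared
#' correlation between the QTL dosage and the total genetic value equals
#' `qtl_variance_fraction` exactly. Residual variance is set analytically to
#' `var(g) (1 - h2) / h2` so the realized line-mean heritability matches the
#' configured one up to sampling noise in the residual draw.
#'
#' @param panel A [genotype_panel()] from [simulate_genotypes()] (its
#'   `clean_dosages` are used when heterozygote/missing corruption was
#'   applied).
#' @param config The [sim_config()] used to build the panel.
#' @param trait_name Name for the trait column.
#' @param seed Seed for the effect and residual draws; defaults to
#'   `config$seed + 1` so genotype and trait randomness are decoupled but
#'   jointly reproducible.
#' @return A list with `trait` (tibble: `line_id`, `trait`, `value`, `h2`)
#'   and `truth` (class `sim_truth`): per-SNP causal effects, the QTL SNP id,
#'   realized QTL variance fraction, true genetic values, realized
#'   heritability, and per-chromosome fractions of genetic variance (defined
#'   as `cov(g_c, g)/var(g)` so they sum to one exactly).
#' @export
simulate_trait <- function(panel, config, trait_name = "sim_trait",
                           seed = config$seed + 1L) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  set.seed(seed)
  X <- if (!is.null(panel$clean_dosages)) panel$clean_dosages else panel$dosages
  if (anyNA(X)) abort("trait simulation needs complete dosages; supply the clean matrix.")
  sds <- apply(X, 2, sd)
  poly <- sds > 0
  if (sum(poly) < 2) abort("need at least two polymorphic SNPs.")

  W <- scale(X, center = TRUE, scale = FALSE)
  p <- ncol(X)
  beta <- numeric(p)
  # dense causal subset of the polymorphic SNPs
  idx_poly <- which(poly)
  n_causal <- max(2L, round(config$polygenic_density * length(idx_poly)))
  causal <- sort(sample(idx_poly, n_causal))
  beta[causal] <- rnorm(n_causal)
  g_bg <- drop(W %*% beta)

  qtl_snp <- NA_character_
  realized_qtl <- 0
  if (config$architecture %in% c("major_qtl", "mixed")) {
    on_chr <- panel$snp_map$chrom == config$qtl_chromosome & poly
    if (!any(on_chr)) {
      abort(sprintf("no polymorphic SNP on QTL chromosome %d.", config$qtl_chromosome))
    }
    maf <- pmin(colMeans(X) / 2, 1 - colMeans(X) / 2)
    eligible <- which(on_chr & maf >= min(0.15, max(maf[on_chr])))
    j <- eligible[sample.int(length(eligible), 1)]
    x <- W[, j]
    f <- config$qtl_variance_fraction
    v <- mean(x^2); cxg <- mean(x * g_bg); w <- mean(g_bg^2)
    disc <- f * (1 - f) * (v * w - cxg^2)
    b_q <- (-cxg * (1 - f) + sqrt(disc)) / (v * (1 - f))
    beta[j] <- beta[j] + b_q
    qtl_snp <- panel$snp_map$snp_id[j]
  }

  g <- drop(W %*% beta)
  if (!is.na(qtl_snp)) {
    j <- match(qtl_snp, panel$snp_map$snp_id)
    realized_qtl <- cor(W[, j], g)^2
  }

  var_g <- var(g)
  h2 <- config$heritability
  sigma2_e <- var_g * (1 - h2) / h2
  if (sigma2_e > 0) {
    # draw residuals, then remove their sample covariance with g and rescale
    # to the analytic variance, so the realized heritability is exact
    e <- rnorm(length(g))
    e <- stats::residuals(lm(e ~ g))
    e <- e / sd(e) * sqrt(sigma2_e)
  } else {
    e <- numeric(length(g))
  }
  y <- g + e
  realized_h2 <- var(g) / var(y)

  # per-chromosome contributions: cov(g_c, g) sums to var(g) exactly
  g_c <- vapply(1:10, function(ch) {
    cols <- which(panel$snp_map$chrom == ch)
    if (!length(cols)) return(rep(0, length(g)))
    drop(W[, cols, drop = FALSE] %*% beta[cols])
  }, numeric(length(g)))
  denom_var <- function(a, b) mean((a - mean(a)) * (b - mean(b)))
  per_chrom <- apply(g_c, 2, denom_var, b = g) / denom_var(g, g)

  truth <- structure(
    list(
      causal_effects = tibble(snp_id = panel$snp_map$snp_id, effect = beta),
      qtl_snp_id = qtl_snp,
      realized_qtl_variance_fraction = realized_qtl,
      genetic_values = setNames(g, rownames(X)),
      realized_h2 = realized_h2,
      per_chromosome_genetic_variance = per_chrom
    ),
    class = "sim_truth"
  )
  trait <- tibble(
    line_id = rownames(X),
    trait = trait_name,
    value = unname(y),
    h2 = realized_h2
  )
  list(trait = trait, truth = truth)
}

#' Serialize simulation ground truth as JSON
#'
#' @param truth A `sim_truth` from [simulate_trait()].
#' @param file Path.
#' @export
write_sim_truth <- function(truth, file) {
  out <- list(
    qtl_snp_id = truth$qtl_snp_id,
    realized_qtl_variance_fraction = truth$realized_qtl_variance_fraction,
    realized_h2 = truth$realized_h2,
    per_chromosome_genetic_variance = unname(truth$per_chromosome_genetic_variance),
    genetic_values = as.list(truth$genetic_values),
    causal_effects = truth$causal_effects
  )
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}
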