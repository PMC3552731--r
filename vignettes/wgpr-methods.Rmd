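---
title: "Whole-genome prediction and genome partitioning with wgpr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome prediction and genome partitioning with wgpr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(wgpr)
```

# Scope

`wgpr` compares five whole-genome prediction (WGP) models with contrasting
assumptions about the distribution of SNP effects — ridge-regression BLUP
(RR-BLUP), the LASSO, the elastic net, reproducing kernel Hilbert space
(RKHS) regression on modified Rogers' distances, and BayesB with uncertain
hyperparameters — on panels of homozygous inbred lines. Around the models it
implements the supporting machinery a study of model-vs-architecture
sensitivity needs: chip-style SNP quality control, genomic relationship
matrices, partitioning of genetic variance across chromosomes by
simultaneous multi-kernel REML with principal-component structure
correction, a Q+K single-marker association scan, and a repeated
cross-validation protocol whose predictive abilities are converted to
accuracies by dividing by the square root of heritability. A synthetic-data
generator emulates a maize-like diversity panel so that every stage is
testable without external data.

# The regression set-up

All five predictors start from the linear model

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{Z}\mathbf{u} + \mathbf{e},
\qquad \mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e),$$

where $\mathbf{Z}$ is the $n \times p$ matrix of column-standardized
allele dosages and $\mathbf{u}$ the vector of SNP effects. The models
differ only in how $\mathbf{u}$ is constrained or shrunk:

* **RR-BLUP** treats $\mathbf{u} \sim N(0, \mathbf{I}\sigma^2_u)$. The
  penalized estimator $\hat{\mathbf{u}} = (\mathbf{Z}'\mathbf{Z} +
  \lambda_{RR}\mathbf{I})^{-1}\mathbf{Z}'(\mathbf{y} - \mathbf{1}\hat\mu)$ with
  $\lambda_{RR} = \sigma^2_e/\sigma^2_u$ is computed in the dual: with
  $\mathbf{G} = \mathbf{Z}\mathbf{Z}'/p$ the model is the genotype-level
  mixed model $\mathbf{y} = \mathbf{1}\mu + \mathbf{g} + \mathbf{e}$,
  $\mathrm{var}(\mathbf{g}) = \mathbf{G}\sigma^2_g$ with
  $\sigma^2_g = p\,\sigma^2_u$; variance components come from REML on that
  form, $\hat{\mathbf{g}}$ is the BLUP, and SNP effects are recovered as
  $\hat{\mathbf{u}} = \mathbf{Z}'\mathbf{G}^{-}\hat{\mathbf{g}}/p$. When
  $\mathbf{G}$ is singular (always when $p < n$, and often numerically
  otherwise) the inverse is taken on the span of $\mathbf{G}$ through its
  spectral decomposition, which reproduces the primal closed form exactly;
  the test suite asserts agreement to $10^{-6}$.
* **LASSO** replaces the $L_2$ constraint by $L_1$, so effects can be
  exactly zero; **elastic net** mixes the two with weight $\alpha$. Both
  use the objective $\mathrm{RSS}/(2n) + \lambda(\alpha\Vert u\Vert_1 +
  (1-\alpha)/2\,\Vert u\Vert_2^2)$ solved by coordinate descent (glmnet).
  glmnet standardizes the response internally, which silently rescales the
  $L_2$ part of its penalty by the standard deviation of $\mathbf{y}$;
  `wgpr` converts $(\alpha, \lambda)$ in both directions so that the
  objective above is solved at exactly the stated penalty. KKT residuals of
  every returned solution are checked in the tests (and reported in the
  fit's diagnostics) at $10^{-6}$.
* **RKHS** replaces the inner-product kernel by a Gaussian kernel on the
  modified Rogers' distance, $K_{ij} = \exp(-GD_{ij}/\theta^2)$.
* **BayesB** places a point mass at zero on each per-SNP effect variance
  with a scaled-inverse-$\chi^2$ slab, making nonzero effects
  $t$-distributed, and treats the hyperparameters as uncertain.

## Hyperparameter selection

"Lowest mean squared error in the training population" is implemented as
5-fold cross-validation *inside the training data*: raw training MSE is
monotone in model complexity and would always select $\lambda \to 0$. For
the elastic net, the $(\alpha, \lambda)$ grid search breaks ties toward
larger $\lambda$, then larger $\alpha$, preferring sparser models. The
$\theta$ of RKHS is chosen on a grid (default 30 log-spaced points in
$[0.1, 100]$) at the maximum of the REML profile likelihood. In repeated
cross-validation every one of these selections — along with imputation
means, standardization statistics and REML variances — is re-estimated from
the training folds only; an instrumented test verifies that no statistic
ever sees a held-out line.

# REML machinery

Two fitters are used:

* `reml_kernel()` for single-kernel models: the variance ratio
  $\gamma = \sigma^2_g/\sigma^2_e$ is profiled on the spectral
  decomposition of the kernel, so each candidate is evaluated in closed
  form and a one-dimensional search (`optimize` on $\log\gamma \in
  [-25, 25]$, tolerance $10^{-10}$) is exact for practical purposes.
* `reml_multi()` for the 11-component chromosome partition model:
  average-information (AI) updates with step-halving whenever a step would
  decrease the restricted likelihood or leave the parameter space, and an
  active set that pins components at zero yet lets them re-enter when their
  score turns positive. Traces $\mathrm{tr}(\mathbf{P}\mathbf{K}_i)$ are
  computed as Frobenius inner products ($O(n^2)$ per kernel), so a fit at
  $n = 300$ with 10 chromosome kernels takes seconds. The response is
  scaled to unit variance internally and components are scaled back, making
  the convergence tolerance ($10^{-6}$ on the restricted log-likelihood,
  at most 200 iterations) uniform across traits. Non-convergence is
  reported as a flag, not an error.

Both are validated against an independent oracle that maximizes the dense
restricted likelihood with a generic optimizer.

# Genome partitioning

The partition model regresses the trait on the first ten principal
components of the SNP matrix (fixed) and fits one random genetic effect per
chromosome, $\mathbf{g}_c \sim N(0, \mathbf{G}_c \sigma^2_{g_c})$ with
$\mathbf{G}_c = \mathbf{Z}_c\mathbf{Z}_c'/p_c$, plus a residual — all
simultaneously, which avoids the bias corrections needed when chromosome
segments are fitted one at a time. The share of chromosome $c$ is
$\sigma^2_{g_c} / (\sum_c \sigma^2_{g_c} + \sigma^2_e)$. On simulated
traits the summed shares track the trait heritability, and for polygenic
traits the per-chromosome shares align with chromosome length
(`chromosome_length_regression()`); a chromosome carrying a major QTL
stands out far above that line. Chromosome kernels are frequently singular,
so any kernel whose smallest eigenvalue falls below $10^{-8}$ is repaired
to the nearest positive definite matrix (Higham's alternating projections
via `Matrix::nearPD`, then an explicit eigenvalue floor of $10^{-8}$).

The association scan is the two-step approximation used by EMMAX-style
software: null-model variance components (whole-genome kernel plus PCs) are
estimated once and reused for every SNP's generalized-least-squares Wald
test. This trades a small loss of power for a factor-$p$ saving in REML
fits and is flagged in the output. A SNP's "explained genetic variance" is
its squared dosage–phenotype correlation divided by $h^2$ — the simplest
estimator that converts a phenotype-level $R^2$ to a fraction of genetic
variance; no sharper definition is attempted.

# BayesB sampler

Priors (shape/scale parameterization for the Gammas):
$\Pi_u \sim \mathrm{Beta}(7, 3)$ on the probability of a *zero* effect
variance, $\nu_u \sim \mathrm{Gamma}(5, 2)$,
$S^2_u \sim \mathrm{Gamma}(0.1, 10)$, and
$\sigma^2_e \sim \chi^{-2}(\nu_e = 4.001, S^2_e)$ with $S^2_e$ matched to
the REML residual variance by $S^2_e = \hat\sigma^2_e(\nu_e - 2)/\nu_e$.
The scaled-inverse-$\chi^2$ is parameterized so that $\nu S^2 / s \sim
\chi^2_\nu$ (mode $S^2\nu/(\nu + 2)$); the source conventions leave this
ambiguous and this choice is used consistently for priors and full
conditionals. The sampler (compiled code) sweeps SNP by SNP: the variance
state is proposed from its prior mixture and accepted by a Metropolis
ratio with the effect integrated out — only the scalar projection of the
running residual on that SNP enters — then the effect is drawn from its
Gaussian full conditional. $\Pi_u$ and $\sigma^2_e$ have conjugate
updates; $\nu_u$ and $S^2_u$ move by Gaussian random walks on the log
scale whose steps adapt during burn-in toward roughly 30% acceptance.
($S^2_u$ actually admits a conjugate Gamma update under these priors; the
random-walk design was kept deliberately so both hyperparameters go
through the same adaptive machinery.) Acceptance rates outside
$[0.05, 0.95]$ raise a warning in the diagnostics, never an error. The
default protocol is 50,000 iterations, 5,000 burn-in, thinning 10, with an
optional reduction to 5,000 markers evenly spaced by map position; all
randomness flows through R's RNG so a seed fixes the posterior summaries
bit for bit. Setting `include_all = TRUE` with fixed common effect and
residual variances collapses the model to conjugate Bayesian ridge, whose
analytic posterior mean the sampler must reproduce within Monte-Carlo
error — the strongest correctness check available for a sampler.

Whether BayesB should run on standardized or raw dosages is not fixed by
the source material; standardized dosages are used for consistency with
the other effect-based models.

# Validation protocol

`make_cv_plan()` partitions genotypes (never observations) into 5 balanced
disjoint folds, independently 20 times, giving 100 runs. Predictive
ability is the Pearson correlation $r(y, \hat{y})$ per run; accuracy is
$r(g, \hat{g}) = \bar{r}(y, \hat{y})/h$, dividing the *mean* ability by
$h = \sqrt{h^2}$ (both the per-run abilities and the summary are written
out, so the per-run division can be recomputed if preferred). A fold with
constant predictions — e.g. a LASSO that selected the empty model — scores
$r = 0$ with a warning rather than being dropped, keeping all models
comparable on the same 100 runs. For synthetic traits $h^2$ is the
realized heritability recorded by the generator; for user data it is a
required phenotype column.

# The synthetic panel generator

The generator emulates the structure that matters for these methods, not a
full population-genetic history:

* **Genome**: 10 chromosomes. Default desk scale is 300 lines × 5,000 SNPs
  (500 per chromosome) standing in for a real panel of ~289 lines × ~38,000
  post-QC SNPs. Chromosome lengths default to maize-proportional values
  scaled down (~275 Mb total) so the marker spacing (~55 kb) matches a 50k
  chip on the real genome; with real lengths at desk-scale SNP counts the
  adjacent-pair spacing would approach the LD decay distance and no
  parameterization could show both strong adjacent LD and decay to
  $r^2 = 0.1$ at 500 kb.
* **LD**: each line is a Markov mosaic of 20 founder haplotypes, and the
  founder haplotypes themselves carry Markov LD along the chromosome
  (latent Gaussian AR(1) thresholded at the per-SNP allele frequency). With
  i.i.d. founder alleles the mosaic alone would produce only
  $O(1/n_\text{founders})$ background correlation, which is why the founder
  pool must supply the local structure. The combined correlation length is
  calibrated so the empirical $r^2(d) \approx 0.47\,e^{-d/\Lambda}$ curve
  crosses 0.1 at `ld_decay_bp`; at the default 500 kb this puts the mean
  adjacent-SNP $r^2$ near 0.41 — inside the 0.25–0.45 band the panel is
  meant to emulate, though somewhat above the 0.34 a real panel shows,
  because a single-exponential decay cannot hit both calibration points
  exactly. What the generator does **not** reproduce: heterotic-pool
  substructure, allele-frequency spectra shaped by selection, long-range
  admixture LD, genotyping-error patterns. Tests passing on this generator
  therefore certify the estimators, not field performance.
* **Traits**: polygenic effects are i.i.d. normal on a dense random subset
  (default 10%) of polymorphic SNPs — several hundred causal loci at
  default dimensions. This is the realistic reading of "highly polygenic"
  for agronomic traits; under a strict infinitesimal model (every SNP
  causal) the LASSO degenerates to the null model on held-out folds, which
  real panels do not show. A major-QTL trait adds one QTL whose effect is
  solved in closed form so the squared correlation between QTL dosage and
  total genetic value equals the requested fraction exactly. Residuals are
  drawn normal (nothing in the source constrains their distribution),
  orthogonalized against the genetic values and rescaled, so the realized
  line-mean heritability matches the target exactly rather than within
  sampling noise. Per-chromosome genetic variances are defined as
  $\mathrm{cov}(g_c, g)/\mathrm{var}(g)$, which sum to one as an exact
  identity even with cross-chromosome sampling covariance.
* Heterozygous and missing calls are injected *after* trait simulation, so
  the recorded truth is unaffected; dominance and epistasis are out of
  scope (fully homozygous material).

# Numerical and design choices

* Standardization uses the population (denominator-$n$) standard deviation
  so that $\mathrm{diag}(\mathbf{G})$ averages exactly 1; dosages are
  re-oriented to count the minor allele after QC, with ties keeping input
  orientation.
* Missing dosages are SNP-mean imputed (before standardization; new lines
  at prediction time fall back to *training* means). No fancier imputation
  is attempted.
* The modified Rogers' distance uses the normalizer $1/(4p)$, mapping the
  maximal biallelic contrast (opposite homozygotes at every SNP) to exactly
  1, a heterozygote contributing half.
* QC keeps a SNP when missingness $\le$ 10%, MAF strictly $>$ 2.5%, at
  most 3 heterozygous calls, and replicated check genotypes agree; the
  filters are per-SNP predicates, hence order-independent. The
  replicate-check rule is generalized from one specific check genotype to
  any declared replicate group.
* Ties and degenerate cases: monomorphic SNPs are an error by default and
  silently dropped only inside CV training folds; constant predictions
  score $r = 0$; a degenerate chromosome-length regression (constant
  shares) is an explicit error.
* Problem sizes in the shipped test suite are chosen so the whole suite
  runs in well under half an hour on one core: unit tests use panels of
  30–300 lines and 50–5,000 SNPs; the model-ranking experiment uses 20
  traits per architecture at 300 lines × 5,000 SNPs with one 5-fold CV
  repeat per trait, a reduced elastic-net grid ($\alpha \in \{0.25, 0.75,
  1\}$, 50-point $\lambda$ paths, coordinate-descent threshold $10^{-8}$)
  and a 10-point $\theta$ grid; BayesB joins the end-to-end runs at
  reduced settings (2,000 iterations, 2,000 markers) rather than the full
  50,000-iteration protocol.

# Known limitations

* The ranking experiments are qualitative reproductions at desk scale:
  absolute accuracies depend on the generator and are not comparable to
  any particular real panel.
* The two-step GWA approximation underestimates significance for SNPs with
  large effects (their variance is partly absorbed by the kinship term).
* The elastic-net grid search refits the full path per $\alpha$; for very
  large panels this is the dominant cost.
* BayesB's inclusion probabilities are prior-sensitive at small $n$; the
  defaults follow the published priors rather than attempting to tune
  them.
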