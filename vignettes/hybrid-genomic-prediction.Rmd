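---
title: "Two-stage genomic prediction of combining abilities in hybrid potato"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage genomic prediction of combining abilities in hybrid potato}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diploid hybrid potato breeding evaluates F1 hybrids produced by crossing
homozygous inbred parent lines. Phenotyping every candidate cross is
impossible — the crossing space grows quadratically in the number of parents
while field capacity does not — so breeders want to predict the performance
of untested crosses from molecular markers. Two questions drive the
modelling: how much of the genetic variance among hybrids is additive
(general combining ability, GCA, a property of parents) versus
cross-specific (specific combining ability, SCA, driven by dominance), and
whether marker-based prediction of either transfers to hybrids whose parents
carry little or no phenotypic information.

`hybridgp` implements the full analysis path for this setting: marker
quality control and relationship matrices, per-trial spatial mixed models,
a multi-trial variance model, second-stage genomic combining-ability models,
and an evaluated-parent cross-validation scheme, plus a synthetic
hybrid-breeding data generator with known ground truth so that every stage
can be validated end to end.

## Stage 1: per-trial spatial models

Each field trial is a randomized complete block design (RCBD) on a
row-by-column grid, with every hybrid replicated once per block. For one
trial and trait the base model is

$$y_{hb} = \mu + \alpha_h + \gamma_b + \varepsilon_{hb},$$

with fixed hybrid effects $\alpha_h$ and fixed block effects $\gamma_b$; a
second base adds a random column effect $c_m \sim N(0, \sigma^2_c)$ to
absorb column-wise management trends. Four residual structures are crossed
with the two bases:

1. independent errors, $\operatorname{var}(\varepsilon) = \sigma^2_e I$;
2. first-order autoregressive (AR1) correlation along field columns,
   $\sigma^2_e\, I_r \otimes \Sigma_c(\rho_c)$ with
   $\Sigma_{c,ij} = \rho_c^{|i-j|}$;
3. the column-AR1 plus a spatially independent *nugget* $\sigma^2_\eta$
   (harvest and measurement error unrelated to field position);
4. separable AR1$\times$AR1 correlation along rows and columns plus nugget,
   $\sigma^2_e\, \Sigma_r(\rho_r) \otimes \Sigma_c(\rho_c) + \sigma^2_\eta I$.

All eight combinations form the model ladder of `fit_ladder()`. Entries are
compared by AIC ($-2\,\mathrm{logLik} + 2k$, $k$ the number of *estimated*
variance parameters; components held fixed do not count), which is valid
under REML here because both bases share the same fixed effects. The winner
supplies hybrid BLUEs with standard errors (`select_and_extract()`). BLUEs
are computed as cell means averaged over sum-to-zero block contrasts, so a
complete RCBD under the IID entry reproduces raw hybrid means exactly — a
useful identity that the test suite asserts. Incomplete grids are handled by
marginalizing the full-grid covariance to observed cells, which the AR1
family supports by construction (entries depend only on coordinate
distances). `semivariogram()` provides the classical residual diagnostic.

## The multi-trial model and prediction targets

Raw plot data from all trials feed a single model with fixed trial
intercepts and within-trial block effects, and a random hybrid-by-location
effect $a_{ht}$ with an *unstructured* covariance across the two locations
(a variance per location plus their covariance), plus IID error:

$$y_{bfht} = \beta_f + \gamma_{fb} + a_{ht} + \varepsilon_{bfht},\qquad
a \sim N(0, \Sigma_a \otimes I_H).$$

From this fit come broad-sense heritabilities per location
$H^2 = \sigma^2_{a}/(\sigma^2_{a} + \sigma^2_\varepsilon)$, the
inter-genotype coefficient of variation $CV_G = 100\,\sigma_a/\mu_{loc}$
(location mean), the intra-genotype coefficient
$CV_\varepsilon = 100\,\sigma_\varepsilon/\mu$ (grand mean), and each
hybrid's across-location BLUP. The BLUP plus the mean trial intercept is the
`AVG` prediction target used in cross-validation; adding the intercept puts
the target on the observed trait scale so that scaled errors are meaningful
(correlations are unaffected by this choice).

## Stage 2: combining-ability models on weighted BLUEs

Stage-1 BLUEs $\hat\mu_{ijf}$ (hybrid $ij$, trial $f$) become the response
of the genomic models. Their squared standard errors form a **known**
diagonal residual ($R_f = \mathrm{Diag}(\hat s_f^2)$, never rescaled), so
precise trials carry more weight. The GCA model is

$$\hat\mu_{ijf} = \beta_f + g_i + g_j + \delta_{ij} + t_{ijf} + r_{ijf},$$

with one parental GCA vector $g \sim N(0, \sigma^2_{gca} G_p)$ entering once
per parent of a cross, an IID genetic residual $\delta$ per hybrid, and a
hybrid-by-trial interaction $t \sim N(0, \sigma^2_{gxt}\, I_t \otimes G_h)$.
$G_p$ and $G_h$ are VanRaden additive relationship matrices of parents and
hybrids ($G = ZZ'/2\sum p_j(1-p_j)$ on column-centred dosages). The GCA+SCA
model adds $s_{ij} \sim N(0, \sigma^2_{sca} D)$ with $D$ the Vitezica
dominance relationship matrix (dosage codes $-2p^2, 2pq, -2q^2$, scaled by
$\sum (2p_jq_j)^2$).

Estimation is the constrained two-step procedure: $\sigma^2_{gca}$ and
$\sigma^2_{gxt}$ are estimated in the GCA model, then held exactly fixed in
the GCA+SCA model, where only $\sigma^2_{sca}$ and $\sigma^2_\delta$ are
re-estimated. This partitions dominance variance out of the genetic residual
instead of letting it erode the additive terms; `fit_gca_sca()` enforces and
records the equality. The genetic residual is deliberately not orthogonal to
SCA — with a sparse crossing design the two compete, which is worth knowing
when reading the partition.

`partition_variance()` reports the proportions of
$\sigma^2_G = 2\sigma^2_{gca} + \sigma^2_{sca} + \sigma^2_\delta$
attributable to each component, using the scalar $2\sigma^2_{gca}$
bookkeeping conventional in combining-ability work (the parental variance
counted once per parent of a cross). Note that the incidence-implied hybrid
additive variance is $\sigma^2_{gca}(G_{p,ii} + G_{p,jj} + 2G_{p,ij})$,
whose panel average for unrelated inbred parents ($G_{p,ii} \approx 2$) is
about $4\sigma^2_{gca}$; the scalar convention is a reporting device, not
the model covariance, and the package uses it only in the partition.

Predictions for any cross in the plan use the kernel structure: BLUPs exist
for *every* parent in $G_p$ and every hybrid in $G_h$/$D$, because a level
without records receives its kernel-conditional expectation given observed
levels (`predict_random()`), which is precisely a genomically estimated
breeding value. The AVG prediction of a cross is $\hat g_i + \hat g_j$
($+\,\hat s_{ij}$); per-trial predictions add $\hat\beta_f$ and
$\hat t_{ijf}$.

## The REML engine

All models above are instances of one dense-matrix REML problem,
$y = X\beta + \sum_k Z_k u_k + e$ with
$V(\theta) = \sum_k \sigma^2_k Z_k K_k Z_k' + R(\theta)$, solved by
`reml_fit()`. Numerical choices:

* **Parameterization.** Variances on the log scale, correlations through
  $\tanh$ — the optimizer works unconstrained inside a box, estimates are
  positive by construction, and $|\rho| \le 0.999$.
* **Optimizer.** L-BFGS-B with analytic gradients
  $\partial\ell/\partial\theta_j = -\tfrac12[\operatorname{tr}(P\,\partial V) -
  \hat e'V^{-1}\partial V V^{-1}\hat e]$, with the trace computed without
  forming the projector $P$ explicitly. Convergence: relative objective
  change below `factr` $\times$ machine epsilon ($\approx 2\times10^{-9}$),
  at most 200 iterations, reported in the `converged` flag. The engine's
  optimum matches an independently coded grid search to $10^{-4}$ on small
  instances (asserted in the tests).
* **Initialization and restarts.** Deterministic: the phenotypic variance
  *net of fixed effects* (the OLS residual variance) is split equally
  across variance components, correlations start at zero — so refits are
  bit-for-bit reproducible. Using the raw `var(y)` instead is a trap worth
  documenting: when fixed effects (trial means) carry most of the spread,
  all components start too large, the joint shrink path reaches the
  variance floor where log-scale gradients vanish
  ($\partial\ell/\partial\log\sigma^2 = \sigma^2\,\partial\ell/\partial\sigma^2
  \to 0$), and the line search stalls in a corner. If the optimizer reports
  failure or parks a component at the floor, the engine retries from a
  deterministic set of alternative starts (all shares divided by ten, and
  one-component-dominant starts) and keeps the best optimum. Convergence is
  finally judged by the projected gradient at the solution, so a genuine
  boundary estimate (a true zero variance) is not misreported as a failed
  fit.
* **Fixed components.** Any parameter (and the whole known-diagonal
  residual) can be pinned; pinned parameters are excluded from the AIC
  count.
* **Degenerate inputs.** Aliased fixed-effect columns are dropped
  left-to-right with a warning; a variance simulated at zero lands on the
  box boundary ($10^{-10}\times$ phenotypic variance) rather than failing;
  non-positive-definite kernels raise an error naming the offender, with a
  one-shot ridge retry for numerically marginal cases.

## Marker quality control

`filter_snps()` applies minor-allele-frequency ($\ge 0.05$, boundary
inclusive) and missingness ($\le 0.10$) filters. Redundant markers are
removed by `prune_ld()` using the kinship-corrected LD statistic $r_{V}^2$
(`ld_rv2()`): both dosage vectors are whitened by the inverse Cholesky
factor of a kinship matrix before correlating, which removes the LD
inflation that shared population history induces. The kinship used for
whitening is the VanRaden GRM of the same panel (with a small ridge), and
whether it is built from all filtered markers or a pre-pruned set is left to
the caller. Conflicting pairs ($r_V^2 \ge 0.5$) are resolved in favour of
the higher polymorphism information content
($PIC = 1 - p^2 - q^2 - 2p^2q^2$); candidates are scanned in decreasing-PIC
order (ties by genome position), which guarantees that in any clique of
mutually correlated sites exactly the most informative one survives and
makes the outcome order-stable. Missing dosages are mean-imputed per SNP
before centring for PCA and the relationship matrices; `snp_pca()` is the
standard SVD of the column-centred dosage matrix.

## The synthetic generator

`simulate_dataset()` emulates the study system: 16 founders; several hundred
fully homozygous inbred parents built as founder-haplotype mosaics (a
first-order Markov chain along each chromosome with a configurable switch
probability, giving geometric segment lengths); a sparse random crossing
plan over two nursery years with a thin fraction of hybrids shared between
years; and four trials (two locations by two years), each an RCBD with two
replicates on a near-square grid. Phenotypes decompose exactly as the
second-stage model assumes: true GCA from Gaussian per-SNP additive effects,
true SCA from per-SNP dominance effects, hybrid-by-trial deviations drawn
from $N(0, \sigma^2_{gxt} G_h)$ with the simulated hybrids' own kinship, an
IID genetic residual, random block effects, an AR1$\times$AR1 spatial error
surface and an independent nugget. Realized GCA/SCA/GxT variances are
rescaled to hit their configured targets exactly, which makes recovery tests
sharp. Because parents are fully homozygous, hybrid genotypes are
deterministic given the cross plan — `hybrid_dosages()` is pure bookkeeping.

For parameter-recovery work the plot-level generator is the wrong scale:
rescaled realized variances are not the kernel-scale parameters REML
estimates. `simulate_blues()` therefore draws effects *exactly* from the
stage-2 kernels and emits BLUE-like observations with known standard errors.

What the generator does **not** emulate: linkage maps in centimorgans and
realistic LD decay (the mosaic model gives blocky LD), selection during
inbreeding, multi-trait genetic correlations, and trial-specific agronomic
artefacts (edge effects, harvest order). Passing tests on synthetic data
therefore demonstrate correctness of the estimation machinery under the
stated generative model, not robustness to every field pathology.

## Cross-validation scheme

`split_hybrids()` assigns every parent in the cross plan to an *evaluated*
set with probability one half; hybrids inherit their role from the count of
evaluated parents — two: training; one: the 1EP test set (a test cross of an
elite and a novel parent); zero: the 0EP set (a cross of two novel parents).
The expected training:0EP and training:1EP size ratios are 1 and 0.5, a
deliberately harsher split than k-fold schemes. `run_crossval()` repeats the
split, refits both genetic models on the training hybrids only (the audit
that no test phenotype enters training is asserted every repetition), scores
Pearson accuracy and trait-mean-scaled RMSE against per-trial BLUEs and the
AVG target on identical splits (so model comparisons are paired within
repetition), and summarizes cells by medians. Degenerate splits and failed
fits are resampled with a logged note; more than 10% failures aborts.

## Study conditions used by the checks

The test suite runs the whole analysis at sizes chosen to finish on a single
CPU while leaving each check statistically meaningful; they are stated here
as the package's simulation-study designs.

* **Quarter-scale cross-validation**: 120 parents, 200 hybrids, 300 SNPs,
  four trials, additive-only trait ($\sigma^2_{gca}=1$, all non-additive
  components zero) with plot residual 0.857 giving $H^2 \approx 0.7$;
  spatially uncorrelated errors, so stage 1 fits the IID ladder entry (the
  generating model); 30 repetitions. Expected outcome, mirroring the
  motivating study: 1EP accuracy strictly above 0EP, and no measurable
  GCA-vs-GCA+SCA difference (median gap below 0.03 on the AVG target).
* **Parameter recovery**: 400 hybrids from 160 parents, two trials, known
  SE 0.7, truth $(\sigma^2_{gca}, \sigma^2_{sca}, \sigma^2_{gxt},
  \sigma^2_\delta) = (1.0, 0.5, 0.6, 0.5)$, 20 replicates; every estimator
  mean within 3 Monte-Carlo standard errors of truth and the two-step
  equality exact. A caution discovered while designing this study: with a
  much denser crossing of fewer parents (80 parents for the same 400
  hybrids) the hybrid kernels become collinear ($D$ with $I$, $G_h$ with the
  GCA incidence structure) and conditional-on-kernel REML shows a mild
  downward bias in $\sigma^2_{sca}$ — a property of sparse-parent designs
  worth remembering when interpreting SCA variance in real programmes.
* **Spatial model selection**: single trials of 128 hybrids (16$\times$16
  fields) under AR1$\times$AR1+nugget with $\rho_r=\rho_c=0.5$,
  $\sigma^2_e=3$, $\sigma^2_\eta=0.5$ — the spatial magnitudes are chosen so
  the row-and-column structure is detectably superior, since no real-trial
  magnitudes are published; the residual-(6) family must win the AIC ladder
  in at least 80 of 100 replicates. IID fields (64 hybrids) must select the
  IID/column-AR1 family and show a replicate-mean $\hat\rho_c$ within 0.1
  of zero.
* **Engine oracle**: 25 random instances with at most 30 observations and
  two free parameters; the REML optimum must match an independently coded,
  iteratively refined grid search to $10^{-4}$ log-likelihood units.

## Known limitations

* The engine is dense: cost grows cubically with observations. Designed-for
  sizes (trials of a few hundred plots, a few hundred hybrids in stage 2)
  fit comfortably; tens of thousands of plots would need sparse or
  eigendecomposition tricks it does not have.
* The multi-trial model supports any number of locations in principle but
  is exercised with two, matching the emulated design.
* Stage-1 standard errors enter stage 2 as a diagonal approximation of the
  full BLUE covariance; this is the standard weighted two-stage shortcut,
  exact only when stage-1 BLUEs are uncorrelated.
* Variances pinned at zero sit on an optimizer boundary of
  $10^{-10}\times$ phenotypic variance, not exactly zero; tests compare
  against that behaviour.
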