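---
title: "Models and methods behind retrowas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retrowas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retrowas)
```

`retrowas` performs transcriptome-wide association analysis over a
feature set that includes locus-resolved human endogenous retroviruses
(HERVs) next to canonical genes. This vignette is the package's own
account of the models it fits, the tunable parameters that matter, what
the synthetic-data generator does and does not emulate, and the
numerical decisions taken where the design was genuinely open.

## 1. Fragment reassignment by EM

Short-read fragments from HERV loci often align to several homologous
copies. `em_reassign()` fits a mixture over source features: given
candidate alignment scores $s_{ij}$, the E-step sets

$$P(\text{source}=j \mid i) \propto \pi_j \exp(s_{ij} / s),$$

over fragment $i$'s candidates plus a reserved *no-feature* slot, and
the MAP M-step updates $\pi_j = (\sum_i p_{ij} + \alpha) / (N + K\alpha)$
with a symmetric Dirichlet prior over all $K$ categories (features plus
the no-feature slot). Iteration stops when the log-posterior changes by
less than `tol` (default 1e-6, cap 200 iterations); the log-posterior is
non-decreasing by construction and is asserted on every test run.

Parameters and defaults:

* `score_scale` $s = 20$ — the softmax temperature mapping aligner
  scores to likelihoods. A single-parameter exponential map is the
  minimal choice; it is also exactly the inverse of the generator's
  score model (below), which makes recovery a consistency check.
* `prior_strength` $\alpha = 10^{-3}$ — small MAP regularisation so
  empty features do not collapse the posterior.
* The no-feature slot scores `min(score) - 2 * score_scale`, a fixed
  pseudo-score that absorbs off-target fragments without modelling the
  whole genome background.
* `assign_counts()` materialises counts as `best` (argmax posterior,
  ties to the lowest feature index and tallied), `fractional`, or
  `unique`. Which reassignment mode produced a given published count
  matrix is generally not stated by quantifiers' users; `best` is the
  default and both others are exposed.

## 2. Expression preparation

* **Filter**: a feature is expressed if `count >= 6` **and**
  `TPM >= 0.1` jointly in the same sample, in at least 20% of samples.
  The joint per-sample reading is the stricter of the two possible
  readings of the usual GTEx-style phrasing, and is the one implemented.
* **TMM** (`tmm_factors()`): delegated to edgeR's `calcNormFactors`
  (trim 30% on M, 5% on A, precision weighting, reference sample by
  upper-quartile proximity); factors are rescaled to geometric mean 1.
  The test suite keeps an independently coded straight-from-definition
  oracle.
* **logCPM**: `log2((count + 0.5) / (lib * factor + 1) * 1e6)`.
* **Surrogate variables**: `residualize()` regresses each feature on
  known covariates (institution, diagnosis, RIN, sex, PMI, ordinal age
  bins, 10 genotype PCs) plus the top principal components of the
  known-covariate residual matrix. The PC proxy replaces the iterative
  surrogate-variable algorithm deliberately: it is deterministic and
  testable, at the cost of ignoring the re-weighting iterations. The
  default number of components follows the transcriptome-scale rule
  (30 for 150 ≤ N ≤ 250, 60 for N > 350, linear in between, 15 below
  150). That rule presumes thousands of features; the bundled synthetic
  study has 120, where 30 PCs of the residual matrix would absorb the
  per-feature cis signal itself, so its configuration pins `n_sv = 5`
  (two planted module factors, two covariate channels, depth).

## 3. Cis heritability and SNP weights

For each feature, cis SNPs are taken from an inclusive ±500 kb window
(≈ 1 Mb total, configurable; the alternative ±1 Mb reading is wider but
changes little on blocks this size). `reml_h2()` fits

$$y \sim N(0,\; \sigma^2_g K + \sigma^2_e I), \qquad K = XX'/m$$

by one-dimensional profile likelihood over $h^2 = \sigma^2_g /
(\sigma^2_g + \sigma^2_e)$ using the eigendecomposition of $K$. The
likelihood-ratio test against $\sigma^2_g = 0$ uses the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (the variance component sits on
the boundary under the null); the gate is nominal p < 0.01. The mixture
choice is documented here because upstream tools do not state theirs;
its null size is verified at ≈1% by simulation.

`cv_select()` runs 5-fold cross-validation (folds fixed by seed,
genotype standardisation refit inside each training fold) over four
weight methods — top eQTL, lasso, elastic net (mixing 0.5), and the BLUP
ridge closed form $w = (X'X + m(1-h^2)/h^2 I)^{-1}X'y$. The penalised
methods choose their penalty by inner cross-validation (3 folds, 20 path
points — kept small so nested CV stays affordable) restricted to path
points whose in-sample $R^2$ does not exceed the feature's $h^2$. The
winner is the method with the best out-of-fold squared correlation,
ties broken toward sparser weights. A Bayesian sparse linear mixed model
is intentionally absent from the method list: it is the one standard
weight method with documented convergence fragility at these panel
sizes, and the four remaining methods reproduce the selection logic.

## 4. Association and secondary analyses

`twas_stat()` computes $Z = w'z / \sqrt{w'Rw}$ with $R$ the LD
correlation of the weight panel. The degenerate-variance check
($w'Rw \le 10^{-8}$, feature skipped) runs on the unridged quadratic
form; `run_rtwas()` then stabilises the denominator with
`ridge_eps = 0.1` as $(1-\epsilon)R + \epsilon I$, which preserves the
unit diagonal and is logged in every result. Bonferroni correction uses
one m — the number of features actually tested per trait, genes and
HERVs together. Features with under half their weight SNPs present in
the harmonized summary statistics are flagged `low_coverage` but kept.

**Conditional/joint** (`joint_conditional()`): greedy forward selection
on the predicted-expression correlation $\Omega_{ij} = w_i'Rw_j /
\sqrt{(w_i'Rw_i)(w_j'Rw_j)}$, entering the feature with the smallest
conditional p while it stays below the per-trait Bonferroni threshold.
Joint statistics are the generalized-least-squares re-fit
$b = \Omega_{SS}^{-1} Z_S$, $Z_j = b_j / \sqrt{(\Omega_{SS}^{-1})_{jj}}$;
for sparse loci this is numerically close to the marginal Z, which is
the behaviour reported tables show. Candidates with conditional variance
below $10^{-4}$ are flagged collinear; $\Omega_{SS}$ inversions get a
$10^{-6}$ ridge when needed.

**Fine-mapping** (`finemap_pip()`): full enumeration of causal
configurations $c$ with $|c| \le 3$ plus the null,
$Z \mid c \sim N(0, \Omega + v\,\Omega_{\cdot c}\Omega_{c\cdot})$,
prior $p^{|c|}(1-p)^{K-|c|}$ with $p = 10^{-3}$ and $v = 40$. The prior
and variance multiplier are configuration keys and logged; the upstream
fine-mapping tool's exact settings are not published, so these defaults
were fixed once as typical values for expression fine-mapping and are
verified against a closed-form single-feature Bayes factor
($\sqrt{1/(1+v)}\exp(z^2v/(2(1+v)))$) and brute-force enumeration for
every $K \le 4$ test case. Enumeration refuses $K > 25$; larger blocks
must be split. The 90% credible set is the smallest PIP-ranked feature
set whose configurations' posterior reaches 0.9.

**High confidence** = jointly selected at the Bonferroni entry threshold
AND PIP > 0.5; intermediate tiers (Bonferroni-only, joint-only,
PIP-only) are emitted alongside.

## 5. Co-expression network

Signed adjacency $a_{ij} = ((1+\mathrm{cor}_{ij})/2)^\beta$ with β
chosen as the smallest power whose scale-free fit $R^2$ (signed by the
negated slope of the log-log connectivity regression) reaches 0.8.
Topological overlap follows the standard formula, and modules come from
average-linkage clustering on $1-\mathrm{TOM}$ with a **static** cut
(default height 0.99) followed by iterative eigengene merging (merge
while eigengene correlation exceeds 1 − 0.25). The static cut replaces
the dynamic tree cut deliberately: published findings at this step are
reported as robust to the cut arguments, and the static cut is exactly
reproducible; the height is a configuration key. Pearson correlation on
TMM logCPM is the co-expression measure (the network input; the
covariate/SV-adjusted matrix is a sensitivity variant, since surrogate
vectors absorb exactly the broad factors modules are made of). Module
colours are assigned by descending size from the conventional palette,
so the largest module is always "turquoise" and unassigned features are
"grey". GO enrichment is an upper-tail hypergeometric test over each
module's **gene-class** members against the expressed-gene universe
(background choice: all post-filter gene-class features), Bonferroni
over all module × term tests.

## 6. The synthetic-data generator

The generator defines the study conditions; its defaults are fixed and
are not tuned per run.

* **Genotypes**: two haplotypes per individual from a latent AR(1)
  Gaussian chain thresholded at each SNP's MAF. The latent step
  correlation is pre-compensated by tetrachoric inversion so the
  realised adjacent-SNP dosage correlation targets the block's `rho`;
  when margins make a target infeasible (very different MAFs admit only
  bounded binary correlation) the latent correlation caps at its
  maximum. Blocks are independent — there is no recombination map, no
  sex chromosomes, and admixture only as a two-population toy for PC
  tests.
* **Expression**: latent per-feature Gaussian with an exact
  $\mathrm{Var}(g)/\mathrm{Var}(\text{latent})=h^2_{cis}$ decomposition,
  optional planted module factors and covariate effects, then
  Poisson-lognormal counts with class-specific mean log abundance
  (genes $e^5 \approx 150$, HERVs $e^{2.5} \approx 12$ — HERV loci sit
  well below genes, as they do in cortex). Note the Poisson layer means
  the *observed-scale* heritability of a low-abundance HERV is
  materially below its latent $h^2$; tests that assert $h^2$ recovery
  work on the latent scale, and the end-to-end study absorbs the
  attenuation in its power budget.
* **GWAS summary statistics**: per LD block,
  $z = \sqrt{N}\,R\,b + \varepsilon$, $\varepsilon \sim N(0, R)$, where
  marginal effects $b$ compose per-feature mediation effects α with the
  standardized eQTL loadings — exactly the model the association stage
  assumes, so null calibration is a clean test.
* **Fragments**: ambiguous candidates get Gaussian scores whose source
  mean is shifted by $\sigma^2/s$ (exponential tilting), making the
  EM's softmax likelihood the true generative model; recovery of
  $\pi$ is then consistency, not approximation. An earlier exponential
  degradation model was replaced for exactly this reason — under it the
  EM provably over-separates the mixture.
* **What is not emulated**: real aligner score distributions, spliced
  or paired fragments, batch structure beyond the covariate channels,
  trans-eQTL effects, and population LD beyond AR(1) blocks. Passing
  tests demonstrate internal correctness and calibration under the
  assumed model, not performance on real cohort data.

## 7. The bundled study and problem sizes

`retrowas_config()` defaults to 200 samples, 10 × 200 SNPs (5 kb
spacing, `rho = 0.6`), 120 features (80 genes, 40 HERVs in 8 families),
half the features cis-regulated at $h^2 = 0.2$, one mediated HERV at
$h^2 = 0.4$ with α = 0.04 against a GWAS of N = 100,000, fragment
ambiguity rate 0.3 with clearly degraded secondary hits. These sizes
keep a full run under a minute on one CPU while leaving the mediated
HERV comfortable power margins through the gate, the association, the
joint analysis, and fine-mapping; the acceptance script repeats the
study over ten seeds and reports the high-confidence flag rate. A master
seed fans out to per-stage seeds by fixed offsets, and identical
configurations reproduce byte-identical artifacts.

## 8. Known limitations

* The surrogate-variable proxy is principal components, not the
  iterative algorithm; with strong signal-correlated batch effects the
  two can differ.
* The REML fit is a single genetic variance component; no trans
  effects, no sex-stratified weights.
* Fine-mapping enumerates configurations — intended for expression
  blocks of tens of features, not SNP-level fine-mapping.
* `harmonize_sumstats()` matches variants by identifier; positional
  matching across genome builds is out of scope.
* The hypergeometric GO test treats genes as exchangeable; no
  gene-length or expression-level bias correction.
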