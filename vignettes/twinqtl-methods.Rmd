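---
title: "Methods: twin-based meQTL and eQTL analysis with twinqtl"
author: "twinqtl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-based meQTL and eQTL analysis with twinqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinqtl)
```

# Overview

`twinqtl` implements the statistical machinery of a twin-cohort analysis of
a tissue methylome and transcriptome: per-CpG ACE variance decomposition,
covariate/kinship/latent-factor adjustment of phenotypes, cis/trans QTL
scanning with two flavours of permutation-based FDR control, exact stepwise
conditional analysis, Bayesian colocalization of methylation and expression
signals, SNP–CpG–gene mediation, cross-dataset replication statistics, and
interval/catalog enrichment. Because individual-level cohort data of this
kind is access-controlled, the package ships a synthetic twin-cohort
generator with planted genetic architecture; every downstream stage is
exercised and validated against that generator's ground truth.

This vignette records the models, the defaults and why they were chosen,
the numerical choices, and what the synthetic experiments do and do not
demonstrate about real data.

# The synthetic twin cohort

`sim_config()` / `simulate_twin_cohort()` generate:

* **Pedigree** — MZ pairs, DZ pairs and singletons. The default cohort (35
  MZ pairs, 70 DZ pairs, 204 singletons = 414 individuals) mirrors the kind
  of population twin registry the methods target.
* **Genotypes** — founder haplotypes per chromosome from a first-order
  Markov chain with adjacent-allele correlation `ld_rho` (default 0.7, an
  adjacent-variant r of common imputed panels at ~100 kb spacing) and MAF
  uniform on (0.05, 0.5] (common variants only, matching the usual MAF > 5%
  filter). Families receive genotypes by explicit parental transmission:
  each parent transmits one whole chromosome haplotype per meiosis, so DZ
  IBD varies around 1/2 per locus instead of being a fixed correlation; MZ
  co-twins duplicate one offspring. Dosages are oriented to the minor
  allele.
* **Methylation** — per CpG, a latent value
  $y = \sum_k \beta_k g_k + A + C + E$ with the classical twin covariance
  structure ($A$ correlated 1 in MZ and 0.5 in DZ pairs, $C$ shared within
  any pair, $E$ independent). Planted meQTLs count toward the additive
  target: the residual polygenic variance is $a^2 - \sum_k \beta_k^2$
  (an error if negative). Latent values map to (0,1) beta-values through a
  logistic curve around a per-CpG baseline; the slope is a nuisance
  parameter (default 1) because all downstream analysis is rank-based and
  only monotonicity matters. Default ACE targets are (0.10, 0.05, 0.85):
  a mostly environment-driven methylome with mean narrow-sense heritability
  around 10%, the low-heritability regime typical of environmentally
  exposed barrier tissues such as skin.
* **Expression** — planted local eQTL effects plus optional family-shared
  variance and noise, unit total variance. SME triplets
  (SNP → methylation → expression) route a configured proportion of the
  total SNP effect $\tau$ through the CpG's latent value: with upstream
  path $a$, the mediator path is $b = p\tau/a$ and the direct path
  $(1-p)\tau$. SEM triplets are the mirror image and rewrite the CpG's
  latent value, so `simulate_expression()` returns the updated methylation
  matrix as well.

Per-stage seeds are derived deterministically from the master seed, so a
configuration reproduces byte-identically.

**What the generator does not emulate:** realistic haplotype panels and
recombination, population structure, cell-type composition, probe-level
array artifacts, count noise in RNA-seq, X/Y chromosomes. Passing tests
demonstrate that the estimators recover the structure they model, with
calibrated error control, under clean Gaussian noise — not that they are
robust to the technical artifacts a real cohort adds on top.

# Phenotype adjustment

`adjust_phenotypes()` freezes the four-step recipe used before QTL
scanning:

1. **Outlier masking** (`mask_outliers`): iterative, values more than 10 SD
   from the mean, exactly three rounds, mean/SD recomputed on unmasked
   values each round.
2. **RINT** (`rint`): rank $r$ of $n$ maps to $\Phi^{-1}((r-0.5)/n)$,
   average ranks for ties. The offset convention matches the twin-genetics
   toolchain this pipeline emulates.
3. **Kinship residualization** (`lmm_residualize`): $y = Xb + u + e$,
   $\mathrm{cov}(u) = \sigma_g^2 K$ with the pedigree kinship $K$ (MZ 1, DZ
   0.5). The variance ratio $\lambda = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$
   is maximized on a grid [0, 0.99] in steps of 0.01 after rotating into
   $K$'s eigenbasis; the block-diagonal structure makes each grid point a
   closed-form GLS fit, so a general REML solver adds nothing. Ties on the
   grid resolve to the smallest $\lambda$, which makes $K = I$ reduce
   exactly to OLS. The BLUP of $u$ is subtracted along with $X\hat b$.
4. **Latent factors** (`latent_factor_adjust`): masked values are set to the
   probe mean, PCA on the most variable probes (default cap 20,000), each
   candidate component is scanned against all variants and dropped if any
   association has $p < 10^{-7}$ (a component that *is* a genetic signal
   must not be regressed out), the surviving components are projected out
   and each row re-RINTed. The genetic check uses a plain per-variant
   linear scan on the component; the source pipeline does not state whether
   its check adjusted the genotypes first, so the simplest version is used.

Each output row is centred and scaled to unit variance after the final
RINT. This is deliberate: the raw sample variance of fixed normal scores is
slightly below 1 (about 0.993 at $n = 400$), and downstream contracts
assume exactly standardized rows.

Two properties worth knowing:

* The pipeline is exactly idempotent on its own output when the kinship
  BLUP is inactive (singleton cohorts, $K = I$). With twin pairs present, a
  re-run refits $\lambda$ on what is now pure noise; about half the time
  the boundary estimate is positive and pair means get shrunk again,
  perturbing ranks at the margin. This is inherent to boundary ML, not a
  defect.
* Under a true null ($\sigma_g^2 = 0$), $\hat\lambda$ is a boundary
  estimator: roughly half its mass sits exactly at 0 and the rest is a
  half-normal whose scale shrinks like $1/\sqrt{n_\text{pairs}}$. Tests
  assert this sampling law rather than an arbitrary small quantile.

The number of expression latent factors is chosen by the discovery-count
procedure (`choose_n_factors`): adjust with each candidate count, count
genes with a local eQTL at BH FDR 5% (per-gene best p, Bonferroni-corrected
within the gene's cis window), and keep the smallest count attaining the
maximum. PCA factors stand in for the probabilistic latent-factor model
used on real data; the selection procedure, which is the part defined by
the method, is implemented exactly.

# Heritability (ACE)

`fit_ace_ml()` maximizes the bivariate-normal pair likelihood with
within-pair covariance $a^2 + c^2$ (MZ) and $a^2/2 + c^2$ (DZ), total
variance constrained to 1, over the simplex $\{a^2, c^2 \ge 0,\ a^2 + c^2
\le 1\}$. Values are standardized first (equal means/variances across
zygosity are assumed), so the reported quantities are proportions. The
likelihood depends on the data only through three sufficient statistics per
zygosity, which makes a dense lattice evaluation cheap: the optimizer
scores a 0.005 simplex lattice, then polishes with Nelder–Mead under
boundary projection (tolerance 1e-12, multiple starts including the
clamped Falconer point). The fit therefore always dominates a 0.005-lattice
oracle, and boundary solutions ($\hat a^2 = 0$ when $r_{MZ} \approx
r_{DZ}$) are exact. `falconer_estimate()` gives the unclamped closed form
$a^2 = 2(r_{MZ}-r_{DZ})$ for reference. Singletons and incomplete pairs
are dropped (pairwise per feature).

Sampling error matters when judging recovery: at 1,000 pairs per zygosity
and an interior truth such as $(a^2, c^2) = (0.4, 0.2)$,
$\mathrm{sd}(\hat a^2) \approx 0.067$, so per-replicate errors of 0.05–0.1
are expected; the mean estimate over replicates is what converges.

# QTL scanning and FDR

`association_scan()` fits the simple regression $y = \alpha + \beta g$
per variant–feature pair on fully adjusted residuals, the design the source
pipeline uses (family structure lives in the residualization and in the
permutation scheme, not in the scan). Betas are minor-allele oriented.
Retention: cis ($p < 10^{-3}$, same chromosome, distance strictly under
1 Mbp) and trans ($p < 10^{-5}$); a distance of exactly 1 Mbp is assigned
to trans, since the cis definition is strict.

**Genome-wide (meQTL-style) FDR**: `twin_aware_permutation()` shuffles
genotype columns with twin pairs moving as units within zygosity groups, so
the permuted null preserves within-family genotype sharing. With the best
per-feature p value observed and under each of 20 permutations,
$\widehat{\mathrm{FDR}}(t) = \frac{\text{mean permuted count} \le
t}{\text{observed count} \le t}$ over candidate thresholds $t$ (the
observed best p values — the estimate only changes there), monotonized by
$\min_{t' \ge t}$, and the largest $t$ with
$\widehat{\mathrm{FDR}}(t) \le 0.05$ is returned. When no threshold
qualifies (e.g. an exchangeable null), a sentinel is returned and nothing
is discovered. Under strong LD, discoveries arrive in correlated clusters,
so null-calibration experiments use unlinked variants where counts are
near-Poisson.

**Gene-level (eQTL-style) FDR**: per gene, a two-parameter beta
distribution is fitted by ML to the minima of 1,000 (at least 100)
within-gene permutations; the observed minimum converts to an empirical p
through the fitted CDF (minima of $M$ independent uniforms follow
Beta(1, M), which anchors the fit); Storey–Tibshirani q values across genes
(single $\lambda = 0.5$, robust at small gene counts) define the
significant set, and each significant gene's nominal threshold is the beta
quantile at the boundary empirical p.

# Conditional analysis

`stepwise_select()` is exact forward–backward stepwise regression on
individual-level data: add the candidate with the smallest conditional p if
below `p_enter` and not collinear (pairwise $r^2 \le 0.9$ by default, a
conventional cutoff the source does not specify) with the selected set;
drop any selected variant whose joint p rises above `p_enter`; iterate to a
fixpoint with deterministic (p, then position) tie-breaks. This replaces
the summary-statistic stepwise approximation used on real data — with
individual-level genotypes available the approximation is unnecessary, and
the exact version is testable against exhaustive best-subset enumeration.
`joint_cis_trans_conditional()` reruns the selection over the union of a
feature's selected cis signals and its trans candidates; trans signals that
fail conditionally are flagged *cis-confounded* — long-range LD echoes of a
cis effect, not genuine distal signals.

# Colocalization

`wakefield_log_abf()` is the standard single-variant approximate Bayes
factor: $\log\mathrm{ABF} = \tfrac12\log(1-r) + r z^2/2$ with
$r = W/(V+W)$. The prior effect SD is 0.15 on the standardized-trait scale
— the quantitative-trait convention of the colocalization framework; the
source does not print its value, so this default is configurable.
`coloc_abf()` enumerates the five hypotheses (none / trait 1 only / trait 2
only / distinct variants / shared variant) in log-sum-exp arithmetic; it
matches a direct $(i,j)$ enumeration to 1e-9 and PP4 is monotone in the
p12 prior.

Priors are count-derived (`priors_from_counts`): $p_1 + p_{12}$ is the
ratio of independent trait-1 signals to variants tested, similarly for
trait 2, and $p_{12}$ is a shared fraction of the former. The shared
fraction is chosen (`select_shared_fraction`) from {0.10, 0.25, 0.50,
0.75} as the value whose prior expectation of colocalization (flat-evidence
H4 mass summed over pairs) best matches the posterior expectation (sum of
PP4) — ties resolve downward.

`multi_signal_coloc()` relaxes the single-causal-variant assumption by
exact conditional decomposition: for each pair of independent signals, each
trait's per-variant summaries are recomputed conditioning on the trait's
*other* selected signals (exact regression, since individual-level data is
available), and single-signal colocalization runs on the conditional
summaries. This is a deliberate stand-in for a sum-of-single-effects
regression: identical intent, exactly testable.

# Mediation

For a colocalized triplet (lead variant $g$, CpG $m$, gene $y$),
`mediation_test()` fits $y \sim g$, $y \sim g + m$ and $m \sim g$;
the proportion mediated is
$(\beta_\text{unadj} - \beta_\text{adj})/\beta_\text{unadj}$ and the Sobel
statistic is $z = ab/\sqrt{a^2 s_b^2 + b^2 s_a^2}$. Both directions (SME:
methylation mediates; SEM: expression mediates) are tested;
`resolve_model()` takes the model(s) passing BH FDR 5% within their family
and, when both pass, the one with the larger proportion mediated.

A structural caveat the synthetic experiments exposed: in a linear-Gaussian
triplet the SME and SEM proportions coincide exactly when the total
SNP-on-outcome effect equals the upstream SNP-on-mediator path, so model
preference is uninformative precisely there. Recovery experiments use an
upstream path (0.6) stronger than the total downstream effect (0.4), the
regime typical of meQTL-versus-eQTL effect sizes and the one in which the
larger-proportion rule discriminates.

Co-methylated CpGs are collapsed before counting mediated genes:
single-linkage clusters at pairwise $|r| \ge 0.9$ (the source does not
define its collapse precisely; this default is ours and configurable),
keeping the smallest Sobel p per (cluster, gene, variant).

# Replication statistics

`harmonize_alleles()` aligns effect alleles across datasets (sign flip on
swapped alleles; strand-ambiguous A/T and C/G variants excluded).
`estimate_pi1()` is Storey's $\pi_1 = 1 - \pi_0$ at a single
$\lambda = 0.5$ — robust at the small lookup sizes replication uses.
`estimate_rb()` corrects the effect correlation for estimation error:
$r_b = \frac{\mathrm{cov}(b_1,b_2) - \rho_e\,\overline{s_1 s_2}}
{\sqrt{(\mathrm{var}(b_1)-\overline{s_1^2})(\mathrm{var}(b_2)-\overline{s_2^2})}}$,
clamped to [−1, 1]; $\rho_e = 0$ by default because non-overlapping cohorts
share no estimation error. With noise SE at half the effect-size SD, the
naive Pearson correlation attenuates by $1/(1+0.25)$ per trait (0.8 true →
~0.64 naive) and $r_b$ removes the attenuation. `bonferroni_validate()` is
the 0.05/n lookup threshold.

# Enrichment

Annotations are BED-convention half-open 0-based intervals; CpGs and
variants are 1-based points (a point $p$ is inside $[s,e)$ iff
$s < p \le e$), strand ignored, membership is set membership.
`fisher_enrichment()` tests the 2×2 table {feature in/out} × {non-feature
universe in/out} with the exact two-sided p; the odds ratio is the sample
cross-product ratio with a Haldane 0.5 correction on zero cells (not the
conditional MLE — simpler and the convention of the enrichment tooling
emulated). Catalog mode (`catalog_enrichment`) requires at least five
signals present, BH-corrects across traits, and calls enrichment only with
OR > 1, q < 0.05 and at least five signals in the tested set; the GWAS-style
background excludes QTL variants, the annotation-style background is the
full universe, following the two different designs of the source analyses.

# Pipeline

`run_pipeline()` chains simulate → preprocess → herit → scan → conditional
→ coloc → mediate → compare → enrich with stage toggles, writes TSV/JSON
outputs and a manifest, and is byte-deterministic for a fixed
configuration. The `compare` stage demonstrates the replication statistics
by split-half scanning of the simulated cohort. A thin command-line wrapper
lives at `inst/cli/twinqtl.R`; the R functions are the primary interface.

# Problem sizes used in tests

The shipped experiments use cohorts of 200–414 individuals, 100–800
variants, 100–500 CpGs and tens of genes; ACE recovery uses 1,000–4,000
pairs per zygosity where the twin-correlation bands require it; FDR
calibration uses 200 CpGs × 500 variants with 20 twin-aware permutations
over 20 seeds; colocalization uses 50-variant regions at n = 400; mediation
n = 350 per triplet. These sizes were chosen so each experiment's
Monte-Carlo error is small relative to the property being asserted.

# Known limitations

* The ACE model reports point estimates only (no profile-likelihood
  intervals) and assumes equal means/variances across zygosity.
* The scan assumes exchangeable residuals; family structure must be removed
  upstream (it is, by the LMM step) — a mixed-model scan is out of scope.
* The multi-signal colocalization is a conditional decomposition, not a
  variational sum-of-single-effects fit.
* Mediation is observational: measurement error in the mediator biases the
  proportion mediated, and no sensitivity analysis is implemented.
* Catalog/annotation enrichment consumes fixture files; no live catalog
  retrieval.
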