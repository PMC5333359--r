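---
title: "Mapping protein quantitative trait loci: models, thresholds and design choices"
author: "pqtlpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein quantitative trait loci: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqtlpipe)
```

# The analysis problem

A protein quantitative trait locus (pQTL) study asks, for every common
genetic variant and every measured plasma protein, whether allele dosage
predicts protein abundance. The pipeline implemented here covers the
full arc of such a study: variant quality control, a genome-wide
additive-model scan, the collapse of correlated association signals into
a ranked list of loci, replication in an independent cohort, a
conditional dissection of multi-variant loci, ratio-trait (p-gain)
statistics, and finally a Gaussian graphical model (GGM) of the protein
panel that is merged with the genetic and disease-annotation layers into
one network.

Because individual-level cohort data of this kind are access-restricted,
the package ships a synthetic-cohort generator with known ground truth.
Every statistical claim the test suite makes is a claim about recovery
of planted truth or about reproduction of published summary arithmetic —
never about private data.

# The association model

For each variant–trait pair the scan fits ordinary least squares

$$y_i = \beta_0 + \beta\, g_i + \gamma^\top c_i + \varepsilon_i,$$

where $g_i \in \{0,1,2\}$ is the additive allele dosage, $c_i$ the
covariates (age, sex, BMI in a discovery cohort; additionally diabetes
state and the first three genotype and proteome principal components in
the replication design), and $y_i$ the trait on the analysis scale. The
default scale is the rank-based inverse-normal transform
$\Phi^{-1}\{(r_i - 0.5)/n\}$ with average ranks for ties; `raw` and
`log` scales are available for sensitivity analyses. The reported P
value is the two-sided t-test of $\beta$ with $n - k - 1$ residual
degrees of freedom, not a normal approximation — at these sample sizes
the difference is negligible, in small subsamples it is not. Missing
values are dropped listwise per fit and the analysis $n$ is recorded.

The transform convention deserves one note: published pipelines rarely
state the rank offset. We use $(r - 0.5)/n$, which is symmetric, exactly
zero-mean for tie-free input, and deterministic under ties via average
ranks; any strictly monotone transformation of the raw trait leaves the
result unchanged, which the suite asserts as an invariant.

When the aligned data are complete, the scan residualizes traits and
dosages on the covariates once and obtains every per-pair statistic from
cross-products (Frisch–Waugh); tests verify this equals per-pair OLS to
1e-8. A screening threshold (default $P \le 10^{-5}$) bounds what is
retained in memory.

## Multiple testing

All thresholds are plain Bonferroni arithmetic, computed by
`bonferroni_threshold()`:

* genome- and proteome-wide: $0.05 / 509{,}946 / 1{,}124 = 8.72\times10^{-11}$
  at the reference study's panel sizes;
* locus-wide secondary tier: $0.05 / L / T$ with $L$ the *realized*
  number of primary loci (e.g. $0.05/451/1{,}124 = 9.86\times10^{-8}$);
* replication: $0.05 / n_\text{attempted}$ (e.g. $0.05/462 =
  1.08\times10^{-4}$);
* GGM edges: $0.05 / \binom{T}{2}$ (e.g. $7.9\times10^{-8}$ for
  $T = 1{,}124$).

Genomic inflation $\lambda_{GC}$ (median 1-df $\chi^2$ quantile over
0.4549) is reported per trait; no genomic-control rescaling is ever
applied — the pipeline deliberately has no correction mode, it only
diagnoses.

# Loci: two-stage lumping

Association signals are collapsed in two stages, both driven by
composite LD (squared Pearson correlation of dosages):

1. **per trait** (`lump_per_trait`): greedily, the lowest-P unassigned
   variant becomes a sentinel and absorbs unassigned variants within a
   10 Mb window at $r^2 > 0.1$;
2. **across traits** (`define_loci`): sentinel variants are merged
   transitively (graph components) at $r^2 > 0.9$ within 10 Mb, the
   locus sentinel is the smallest-P member, and loci are ranked 1..L,
   strongest first.

Merging is transitive because grouping "all highly correlated
sentinels" implies closure; a greedy non-transitive rule would give a
different locus count, which is why the choice is documented and
tested. Ties on P are broken by (chromosome, position). Windows are
measured between variant base positions, symmetric and half-open; the
anchor choice (sentinel to candidate) is a documented convention.

An association is **cis** when the variant lies on the trait's gene
chromosome at a distance strictly below 10 Mb from the 1-based inclusive
gene interval; everything else, including every cross-chromosome pair,
is **trans**; traits without coordinates are `unknown`, counted
separately.

`conditional_joint_fit()` re-fits a locus's variants jointly; each
conditional P value tests one dosage given the others, and the jointly
explained variance is $R^2(\text{full}) - R^2(\text{covariates only})$.
A collinearity guard (pairwise $r^2 < 0.95$) rejects designs where
"conditionally independent" is not estimable.

# Replication and the p95 power estimate

For each primary association, a tag SNP is the replication-panel variant
with the strongest discovery association among those at discovery-panel
$r^2 > 0.8$ with the sentinel (the sentinel itself qualifies at
$r^2 = 1$); without one, the association is untestable. The search runs
over genotyped variants only — the original study also searched imputed
variants, a fidelity gap we accept and flag. Effect alleles are
harmonized between panels (match, else swap-and-flip-sign);
strand-ambiguous A/T and C/G pairs are harmonized by label and flagged,
since coding changes are a documented source of apparent sign flips.

Replication power is estimated by subsampling: draw the replication
sample size $m$ from the discovery cohort *without replacement*, refit,
repeat (default 100 times), and report the $\lceil 0.05\,
\text{reps}\rceil$-th largest P value — the "p95", the P value
achievable with 95% power at size $m$. Two properties matter and are
tested: p95 is monotone non-increasing in the true effect, and for a
null association p95 sits near 0.95, the 95th percentile of a uniform.
The second holds only when $m/n$ is modest (the study's 338-of-997 is
fine); as $m \to n$ the subsamples become near-identical and p95
collapses toward the full-sample P — the package makes no attempt to
"fix" this, it is a property of the estimator.

# p-gain for ratio traits

For two strictly positive traits the ratio is formed on the raw scale,
all three series are moved to the analysis scale, and
$\text{p-gain} = \min(p_a, p_b) / p_\text{ratio}$. A p-gain above
$10^4$ (configurable) marks the ratio as carrying information beyond
either component. A constant denominator is a rescaling, so after the
inverse-normal transform the p-gain is exactly 1; a genotype moving both
components in parallel cancels in the ratio and the p-gain drops below
1. Both limits are tested.

# The Gaussian graphical model

The trait panel's conditional-dependence network is estimated on the
*raw* scale after residualizing age, sex and BMI (matching the reference
analysis, which used unscaled residualized data). The sample correlation
matrix $R$ is shrunk toward the identity,

$$R^* = (1-\lambda) R + \lambda I, \qquad
\lambda = \frac{\sum_{i<j}\widehat{\mathrm{Var}}(r_{ij})}{\sum_{i<j} r_{ij}^2},$$

the Schäfer–Strimmer analytic optimum clamped to $[0,1]$, which keeps
$R^*$ positive definite even when traits rival samples in number.
Partial correlations are
$-\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$ with $\Omega = (R^*)^{-1}$.

Edge P values default to the Fisher z-approximation with effective
degrees of freedom $n - (T-2) - 3$ (the $T-2$ remaining traits are
conditioned on); when that quantity falls below 3 the function refuses
and points to the permutation mode (independent column permutations,
pooled null over pairs), which brackets the under-documented
empirical-Bayes null used by some published GGM tools. Edges are pairs
with $p < 0.05/\binom{T}{2}$. The mode used is recorded in the output
metadata.

One behaviour worth understanding: $\lambda$ adapts to how dense the
true correlation structure is. A plasma proteome is dense (the reference
analysis reports $\lambda = 0.187$), so shrinkage is mild. A synthetic
panel of mostly independent traits pushes $\lambda$ toward 1 and
attenuates everything — correctly so. Synthetic GGM tests therefore
plant strong conditional dependencies (partial correlation 0.6), and
the demo cohort carries a dense planted precision structure.

# The synthetic cohort generator

`simulate_genotypes()` draws dosages from a latent-threshold model: per
LD block a latent AR(1) Gaussian with adjacent correlation $\rho$ is
thresholded at each variant's allele-frequency quantile to give one
haplotype; two independent haplotypes sum to the dosage. This is the
simplest model with tunable LD decay; note the thresholding attenuates
correlation, so dosage $r^2$ is substantially below latent $\rho^2$
(a latent $\rho = 0.995$ with equal MAFs is needed for dosage
$r^2 > 0.8$). Blocks are placed 20 Mb apart along chromosomes 1–22 so
distinct blocks never share a 10 Mb window. Target MAFs are uniform on
the configured range (default 0.05–0.5, lower bound never below 0.01);
columns whose realized MAF dips below 0.01 are redrawn so the panel
stays common-variant.

`simulate_traits()` builds each trait as planted genetic effects +
covariate effects + correlated Gaussian residual. Genetic coefficients
are scaled against the realized dosage variance so each planted
`target_variance_fraction` holds in expectation, with the residual
standard deviation absorbing the remainder; fractions on one trait must
sum below 1. The residual precision matrix realizes a user-specified
set of nonzero partial correlations (rejected unless positive
definite). The latent trait is exponentiated so raw values are positive
and log-normal-like, leaving room for the raw/log/inverse-normal scale
machinery to matter.

The replication cohort (default 338 samples) adds three realistic
complications: Balding–Nichols cluster allele frequencies
($F_{ST}$-like parameter 0.05, 3 clusters) that genotype principal
components separate; a Bernoulli(0.5) diabetes covariate (a case–control
design); and a latent haemolysis-like factor loading a random 30% of
traits at 0.4 SD, which the proteome principal components must absorb.
Discovery covariates are age ~ Uniform(32, 81), sex ~ Bernoulli(0.5),
BMI ~ Normal(27, 4); the replication cohort uses the younger age range
23–71 typical of such a study. All draws flow from one master seed via
deterministic per-stage sub-seeds, so identical configurations give
byte-identical cohorts.

What the generator does *not* emulate: real haplotype panels and
recombination hotspots, imputation uncertainty, X-chromosome traits,
assay-specific normalization artefacts, and the heavy-tailed
measurement noise of affinity proteomics. Passing recovery tests
therefore demonstrate the pipeline's statistical machinery, not
robustness to every failure mode of real data.

# Numerical and degenerate-input choices

* HWE: Wigginton-style exact test (plain, not mid-p), recurrence from
  the modal heterozygote count; validated against a log-factorial
  enumeration oracle for every table up to 200 alleles.
* Variant filters run in the fixed order duplicates → missingness →
  MAF → HWE with per-stage counts, and the report checker re-derives
  the chain arithmetic; the filter is idempotent.
* Zero-variance dosages give a flagged result with missing P rather
  than an error; a constant outcome gives $\beta = 0$, $p = 1$.
* Rank-deficient designs error and name the collinear columns.
* P values are floored at the smallest positive double, never 0.
* All genomic coordinates are 1-based inclusive (VCF convention);
  BED-like gene maps are converted on read.
* Equal-P sentinel ties break by (chromosome, position).

# Problem sizes used by the test suite

The suite validates at sizes chosen to make Monte-Carlo error small
relative to each tolerance while keeping a laptop-scale run: null
calibration on 10,000 fits (100 variants × 100 traits, n = 500); the
three-variant conditional decomposition at n = 997 (fractions 0.30 +
0.21 + 0.10 = 0.61); locus recovery with 20 planted loci on two-variant
LD blocks over 20 fixed seeds; p95 at the study's 338-of-997 sampling
fraction over 50 seeds; GGM recovery at T = 50, n = 500 over 10 seeds;
and an end-to-end demo at 1,000 samples × 5,000 variants × 200 traits
run twice to assert byte-identical outputs.

# Known limitations

Relatedness and population structure in the *discovery* cohort are not
modelled (no kinship/mixed-model machinery); binary outcomes are not
supported (no logistic scan); the tag search cannot use imputed
variants; the GGM edge null is an approximation bracketed by two modes
rather than the exact finite-sample law of shrunken partial
correlations; and the manual biological curation that a published
SNP–disease network receives is reduced to its mechanical rules
(P filter, unique pairs, self-protein exclusion).
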