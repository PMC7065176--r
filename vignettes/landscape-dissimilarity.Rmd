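---
title: "Modelling isolation by distance and environment with landgdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling isolation by distance and environment with landgdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landgdm)
```

# The problem

Across the range of a widespread, continuously distributed species,
individuals sampled further apart tend to be more genetically dissimilar
(isolation by distance, IBD), and individuals from environmentally
different sites may be more dissimilar than geography alone predicts
(isolation by environment, IBE). Distinguishing the two is hard because
environmental variables are themselves spatially autocorrelated. landgdm
implements a dissimilarity-based workflow for this question: pairwise
genetic distances between individuals are regressed on monotone transforms
of geographic distance and of site-level environmental predictors, with
permutation, jackknife and cross-validation machinery to keep the
inference honest.

# The model

## Genetic distances

Dosage genotypes (0/1/2 copies of the alternate allele) give a
frequency-standardized genomic relationship matrix

$$C_{ij} = \frac{1}{L'_{ij}} \sum_l
  \frac{(g_{il} - 2p_l)(g_{jl} - 2p_l)}{2 p_l (1 - p_l)},$$

with pooled frequencies $p_l$, monomorphic loci excluded, and
pairwise-complete handling of missing genotypes ($L'_{ij}$ loci observed
in both samples). The Gower transformation
$D_{ij} = C_{ii} + C_{jj} - 2C_{ij}$ turns this covariance into the
squared Euclidean distances of any embedding realizing $C$. We feed the
Gower output to the dissimilarity model exactly as the formula yields it
(a squared-Euclidean quantity); whether a square root should be taken
first is a genuinely open convention, so `gower_distance(sqrt_dist =
TRUE)` exposes the alternative without changing the default. Negative
entries, numerically possible under missingness, are clipped to zero and
counted (`attr(, "n_clipped")`).

## Generalized dissimilarity model

Raw distances are scaled into $[0, 1)$ by their maximum times
$(1 + 10^{-6})$; the divisor is stored in the model so reports are
invertible. Only pairs more than 10 km apart enter the table — closer
pairs are within-locality comparisons that carry no landscape signal and
would otherwise dominate the fit.

Each predictor is transformed by three monotone I-spline basis functions
of order 2 (integrated tent densities) with knots at the 0th, 50th and
100th percentiles of its pair-level values, the default of the standard
GDM formulation. Geographic distance is splined on the pair's distance;
an environmental variable contributes $|f_k(x_i) - f_k(x_j)|$ per basis
function, the defining asymmetry between "distance" and "site" predictors
in GDM. The expected dissimilarity is
$\mu = 1 - \exp(-\eta)$, $\eta = \alpha + \sum_{p,k}\beta_{pk}
x_{pk}$, with $\alpha, \beta \ge 0$, so every fitted partial response is
monotone non-decreasing and predictions stay in $[0, 1)$. Coefficients
minimize the binomial-style deviance

$$D = 2 \sum_\text{pairs} w \left[ d \log\frac{d}{\mu} +
  (1-d)\log\frac{1-d}{1-\mu} \right]$$

($0\log 0 := 0$; $\mu$ clamped to $[10^{-9}, 1-10^{-9}]$) by L-BFGS-B with
an analytic gradient, multi-started from all-zeros and from the
intercept-only optimum $\alpha_0 = -\log(1-\bar d)$. Deviance explained is
$100\,(1 - D_\text{model}/D_\text{null})$ against the intercept-only fit.
Unit pair weights are used throughout; the `weight` column is reserved.

## Selection and validation

* **Forward selection** runs independently within each variable category,
  accepting the best variable while it gains at least 1 percentage point
  of deviance explained. The threshold is in percentage points (not
  relative), the natural reading of "1% of additional deviance" and
  scale-free. Within a category the model grows as variables are accepted;
  whether candidates should instead be scored against the geography-only
  base alone is ambiguous in the field's practice, so
  `cumulative = FALSE` exposes the alternative.
* **Permutation importance / significance** permute environmental values
  across *localities*, never across samples: environment is a locality
  attribute, and sample-level permutation would break the within-locality
  dependence and inflate significance. Geography is left intact, so the
  tests ask specifically about environment beyond geography.
* **Backward elimination** drops the variable whose removal costs the
  least deviance explained (ties by lower permutation importance, then
  lexicographic). The "inflection" (largest second difference of the
  trajectory) is *reported* as a suggested size, not silently applied —
  the criterion is visual in origin and deserves a human look.
* **Cross-validation** splits localities 90/10; training pairs have both
  endpoints in training localities, test pairs at least one endpoint in a
  test locality. Only this convention reproduces the characteristic
  81:19 pairwise train:test ratio ($\mathrm{C}(t,2)/\mathrm{C}(L,2)
  \to 0.81$); assigning mixed pairs to training would leak test localities
  into the fit.
* **Jackknifing** refits after dropping $\lceil 0.1 L\rceil$ whole
  localities and evaluates all splines on the full-data grid, giving the
  envelope of curves that quantifies how much any single part of the
  sampling design drives the fit.

## LD decay

Composite (genotype-dosage) $r^2$ is used because data are unphased;
within 30 kbp windows advancing by 20 kbp (10 kbp overlap between
adjacent windows — the only reading of "overlap" consistent with a
sliding scan), all SNP pairs with at least 4 pairwise-complete samples
contribute. The Hill–Weir drift-recombination expectation is fitted by
least squares over the single rate $\rho$ (with $C = \rho\,d$), optimizing
$\log\rho$ from three starts ($10^{-5}, 10^{-3}, 10^{-1}$ per bp) so
positivity is structural. The half-decay distance solves
$E[r^2](\rho d, n) = E[r^2](0, n)/2$ by bisection to 0.5 bp and is
*undefined* when the sampling floor $1/n$ exceeds half the zero-distance
value (e.g. $n = 2$) — undefined is a reported value, not an error.
The chromosome count defaults to $n = 2\times$ (diploids with data in the
window); the convention (chromosomes vs individuals) is not universal, so
`n` can be overridden. Windows with fewer than 50 pairs are skipped and
counted.

# The simulator and what a green test establishes

`simulate_landscape()` places localities uniformly in a north–south
elongated lat/lon box (an analysis convenience mimicking a latitudinal
sampling gradient, not a reconstruction of any real design; 39 localities
with 3–15 diploids each by default). Ancestral allele frequencies are
uniform on (0.1, 0.9) — common variants. Locality frequencies are
logit-scale perturbations drawn from a zero-mean Gaussian with covariance

$$\sigma^2_\text{geo}\, e^{-d_\text{geo}/\phi_\text{geo}}
 + \sigma^2_\text{env}\, e^{-d_\text{env}/\phi_\text{env}},$$

where $d_\text{geo}$ is great-circle distance and $d_\text{env}$
Euclidean distance over the standardized causal variables; dosages are
binomial(2, locality frequency). Covariances get a $10^{-8}$ diagonal
jitter before Cholesky factorization; a factorization failure names the
offending parameters rather than limping on. This construction
parameterizes IBD and IBE strength *directly* — the point is ground-truth
recovery, not demographic realism. It deliberately omits coalescent
noise, drift along a pedigree, selection, range expansion and
genotyping error; a green recovery test therefore establishes that the
estimators see the structure that is there, not that they are robust to
demographic features the generator never produces.

Environmental variables are Gaussian fields with exponential covariance
at a stated range (400/600/300 km defaults for the Water/Energy/Soil
exemplars) or i.i.d. noise decoys, standardized per variable. Linked
genotypes come from a founder-mosaic model: haplotypes copy founders in
segments with a per-base switch probability, so halving the switch rate
roughly doubles the LD range — a monotone link the tests exploit
end-to-end.

# Numerical choices

* Dissimilarity scaling guard $10^{-6}$; link clamp $10^{-9}$; GDM
  optimizer tolerance `factr = 1e4` (~$10^{-12}$ relative), 500
  iterations, two starts.
* Hill–Weir fit tolerance $10^{-10}$ on the objective; half-decay
  bisection tolerance 0.25 bp (spec 0.5 bp).
* A tied I-spline median knot (possible with discrete predictors) is
  nudged to the midrange; a fully degenerate predictor (min = max) is
  excluded with a warning rather than an error so selection loops survive.
* Half-calls (`./1`) read as missing — conservative and standard; all
  locus statistics use pairwise-complete observations, and per-pair locus
  counts are carried through the covariance.
* Permutation p-values use the add-one convention
  $(1 + \#\{ \ge \})/(n+1)$, so $p \ge 1/(n_\text{perm}+1)$ always.
* Every stochastic routine takes an explicit seed; the pipeline derives
  per-stage seeds from one master seed (kept under $2^{31}$).

# Calibration evidence (computed in the test suite)

The acceptance tests — not this document — compute the quantitative
claims: exact closed forms (Nei H~e~ at N=2, Gower of an identity, the
Hill–Weir value at C=0 and its 1/n asymptote, the meridian arc);
equivalence against independent oracles (a literal 1984-formula
F~ST~ script, a $10^4$-point random search for the GDM optimum, a log-grid
scan for the LD fit, sort-based quantiles); recovery of $\rho$ to
$10^{-3}$ relative error from noiseless curves and the exact $1/\rho$
scaling of the half-decay distance; monotonicity of LD range in the
mosaic switch rate over 10 seeds per level; forward-selection specificity
(empty selection on decoy-only environments in $\ge 80/100$ replicates)
and sensitivity (a strong causal variable recovered in $\ge 90/100$);
Mantel and model-significance type-I error within their stated bands; and
the analytic 81:19 cross-validation pair ratio, verified by enumeration
at $L \in \{10, 39, 100\}$.

"Strong" causal effect in the sensitivity setting means
$\sigma^2_\text{env} = 2$ against $\sigma^2_\text{geo} = 0.5$ at 20
localities × 6 diploids × 2000 loci — an effect size chosen once, as the
regime the selection procedure is designed for, before the calibration
was run.

# Known limitations

* The genotype simulator draws loci independently given locality
  frequencies; landscape and LD analyses are exercised by *separate*
  generators, and no generator couples spatial structure with linkage.
* GDM pair observations are treated as independent in the deviance, as in
  standard GDM practice; the permutation and jackknife layers, which
  respect locality blocks, are the defence against the resulting
  optimism.
* Jackknife envelopes can shift materially when an extreme locality is
  removed — that spread is information about the design, and the test
  suite bounds the typical, not the worst, replicate.
* The VCF dialect is deliberately narrow: uncompressed, GT-only,
  biallelic SNPs; anything richer should be converted upstream
  (e.g. with bcftools).
* Nucleotide diversity needs an explicit `total_sites` denominator; per
  variant-site values (the default) are only comparable between data sets
  filtered identically.
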