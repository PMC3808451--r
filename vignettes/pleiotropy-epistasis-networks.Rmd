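---
title: "Inferring directed epistasis networks from pleiotropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring directed epistasis networks from pleiotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleionet)
```

## The model and its assumptions

pleionet models the joint effect of a marker pair on a set of quantitative
phenotypes. For each orthogonal eigentrait (ET) $j$ — a column of $U$ from
the singular value decomposition $P = U D V^\top$ of the rank-normalized
phenotype matrix — the two-locus regression is

$$\mathrm{ET}_j = \beta_0 + \gamma^\top c + \beta_1^{(j)} x_1 +
  \beta_2^{(j)} x_2 + \beta_{12}^{(j)} x_1 x_2 + \varepsilon,$$

with $x_1, x_2$ allele dosages in $[0,1]$ and $c$ optional covariates. The
central step replaces the $N$ interaction coefficients with two *directed
influence* coefficients via the identity

$$\beta_{12}^{(j)} = m_{12}\,\beta_2^{(j)} + m_{21}\,\beta_1^{(j)}
  \quad\text{for every ET } j.$$

$m_{12}$ reads "variant 1 rescales variant 2's effective dose": the
generative picture is $x_2^{\mathrm{eff}} = x_2 (1 + m\,x_1)$, under which
the regression interaction is exactly $m \cdot \beta_2$. With $N = 2$ ETs
the $2\times 2$ system is solved exactly and the fit is unchanged — the
reparametrization is a change of coordinates, not a new model. With $N > 2$
the $N \times 2$ system is solved by least squares, which *is* a modeling
assumption: one latent directed interaction must account for all ETs.

Identifiability rests on pleiotropy. If the main-effect vectors
$(\beta_1^{(j)})_j$ and $(\beta_2^{(j)})_j$ are parallel — both variants hit
the phenotypes in the same proportions — the system is singular and the
direction cannot be determined. The solver reports such pairs `unresolved`
when the singular-value ratio of the system exceeds `cond_tol = 1e8`. This
is why the method wants phenotypes with *moderate* correlation
($0.4 \le |r| \le 0.8$): perfectly correlated phenotypes carry one signal
and no orientation information, uncorrelated phenotypes share no genetics to
constrain jointly.

Assumptions, in brief: additive dosage coding in $[0,1]$ with the "perturbing"
allele coded high; complete-case analysis within each pair; interactions are
pairwise (no three-way terms); one directed mechanism underlies all ETs;
covariates act like markers once rescaled to $[0,1]$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_ets` | 2 | leading ETs analyzed (2–12). More ETs add information but each extra component must still be fit by the single pairwise model; noisy components dilute significance. |
| `min_class_count` | 6 | minimum observations in *every* one of the four two-locus genotype classes (counted on dosages rounded to 0/1). Below it, the interaction is unidentifiable and the pair is recorded as untested (LD). |
| `n_perm` | 100 | permutations for the null pools. Pooling across pairs means even small values give usable provisional nulls; the attainable p-value floor `1/(pool+1)` is in the manifest. |
| `method`, `level` | `fdr`, 0.01 | multiple-testing correction and significance level, shared by variant–variant and variant–phenotype edges. |
| `t_threshold` | off | optional |t| cutoff promoting strong main-effect markers to pair-scan covariates, since strong main effects can mask other pairs' interactions. User-triggered, never automatic. |
| `cond_tol` | 1e8 | singular-value ratio above which a pair's direction is declared unidentifiable. |

## Error propagation

Each pair-scan supplies, per ET, the coefficient triple and its $3\times 3$
covariance $\sigma^2 (X^\top X)^{-1}$ block. The influences' covariance is
first-order: $\mathrm{Cov}(m) = J \Sigma_\theta J^\top$, with
$\theta = (\beta_1^{(j)}, \beta_2^{(j)}, \beta_{12}^{(j)})_j$ block-diagonal
(cross-ET covariances are zero — the ETs are orthogonal and fitted in
separate regressions; this is an approximation, since they share samples)
and $J$ computed analytically from the matrix perturbation identity
$dm = P\,(dy - dX\,m) + (X^\top X)^{-1} dX^\top r$. The analytic Jacobian is
verified against central differences in the tests, and the delta-method SEs
against Monte-Carlo propagation ($10^5$ coefficient draws): agreement is
within a few percent when coefficient SEs are a few percent of the
coefficients, the regime pair scans on a few hundred samples deliver.
First-order propagation degrades for near-singular systems; those are
filtered by `cond_tol` or flagged by the validation's condition cutoff.

## Permutations and the pooled null

The permutation unit is the ET matrix: rows are permuted jointly against
fixed genotypes. This breaks exactly the genotype–phenotype association
while preserving both linkage disequilibrium (which otherwise produces false
positives between linked markers) and the inter-ET structure. The fixed ETs
are permuted rather than re-deriving ETs from permuted phenotypes; both
break the association, but the fixed-basis choice keeps the variance
fractions constant across permutations and lets the per-pair design
factorizations be reused, which is what makes 100 permutations over
thousands of pairs affordable (cost grows with pairs × permutations).

All resolved standardized effects from all pairs and permutations are pooled
into a single null per statistic kind. One subtlety the package documents
deliberately: the standardized influence is **not symmetric about zero under
the null**. The influence estimate is a ratio involving correlated noise
coefficients ($\mathrm{cov}(\beta_2, \beta_{12}) < 0$ because $x_2$ and
$x_1 x_2$ are collinear in 0/1 designs), so the null $z$ has a negative
median. This does not bias the test: empirical p-values compare $|z|$
against the pooled $|z_{\mathrm{null}}|$, and observed statistics under the
null share the construction exactly — the tests verify distributional
agreement (two-sample KS) and uniform null p-values rather than symmetry.
P-values use the two-sided add-one estimator
$p = (1 + \#\{|z_0| \ge |z|\}) / (1 + n_0)$, which cannot return zero. A
single master seed derives per-permutation seeds by a fixed splitting rule,
so results are reproducible and independent of execution order.

Local FDR is concretized as $\pi_0 f_0(z)/f(z)$ with kernel densities on a
shared Silverman bandwidth from the null pool and the conservative
$\pi_0 = 1$.

## Main-effect consolidation

A marker's main effect is estimated once per tested pair containing it. The
network reports, per marker and ET, the entry with the **largest empirical
p** across pairings — an effect is claimed only if it survives conditioning
on every tested partner. A marker whose apparent effect is borrowed from a
linked neighbour loses it in the pairing with that neighbour, and that
vanishing pairing is the one reported. Selected ET effect vectors are
back-projected to phenotype space through $V$ and the singular values
(coefficients on the phenotype scale; the dimensionless $z$ display weights
are scaled by per-sample singular values so they remain comparable to the
variant–variant $z$'s).

## Numerical choices and degenerate inputs

- OLS uses one QR factorization per pair design, shared across ETs and all
  permutations; coefficients and $(X^\top X)^{-1}$ come from the same $R$
  factor. Rank-deficient designs (e.g. a marker paired with itself or with a
  declared covariate) are flagged, never fatal.
- Normalization is rank-based inverse-normal (Blom offset 3/8, average
  ties), then z-scoring; the empirical value→score map is stored so held-out
  values can be transformed by interpolation. Constant columns are an error.
- SVD sign convention: each right-singular vector's largest-|loading| entry
  is positive, so eigentraits are reproducible across linear-algebra
  backends.
- Rows with any missing phenotype are dropped before the SVD (and reported);
  missing genotypes are handled per pair by complete-case analysis.
- Noiseless inputs give zero propagated SEs; such pairs are flagged
  `degenerate` and excluded from testing instead of dividing by zero.
- Dosage 0.5 (intercross heterozygotes) rounds up in the LD class-count
  filter only; regressions always use raw dosages.
- Marker redundancy means exact equality on jointly observed entries against
  the previous retained marker on the same chromosome (adjacent-only — the
  stated rule is full redundancy with *adjacent* markers).

## What the simulator emulates — and what it does not

`simulate_backcross()` draws 0/1 genotypes with Haldane (no-interference)
linkage: adjacent markers at $d$ cM recombine with probability
$r = \tfrac12(1 - e^{-2d/100})$. `simulate_phenotypes()` implements the dose
model above plus a shared latent trait that induces the moderate phenotype
correlations the method needs, and Gaussian noise. Fixture scenarios:

- `null` — 200 individuals, 20 unlinked markers, 2 phenotypes, no genetic
  effects; used for type-I error and p-uniformity checks.
- `one_directed_edge` — 400 individuals, 12 unlinked markers, source with
  effects (1, 1) on both phenotypes, target with effect 1 on the first only,
  full suppression $m = -1$, noise sd 1, latent loading 0.5. These values
  were calibrated once so that the full pipeline at FDR 0.05 with 50
  permutations recovers the planted orientation in well over 80% of seeds;
  they are the package's own acceptance bar.
- `hub` — one source suppressing three targets.
- `example_like` — the scale of a classic mouse backcross: 203 individuals,
  83 markers on 19 autosomes, 3 phenotypes with pairwise correlations near
  0.6, one binary covariate (`mom`).

The simulator does *not* emulate genotyping error, segregation distortion,
dominance, sex chromosomes, polygenic background beyond the single latent
factor, or non-Gaussian phenotype noise. Passing tests therefore demonstrate
correctness of the inference machinery under the stated generative model,
not robustness to every artifact of real crosses — rank-normalization buys
robustness to monotone phenotype distortions, but linked polygenic
background in real data can still inflate main-effect consolidation.

## Problem sizes used in validation

The acceptance checks run: 1,000 random systems for exactness and the
least-squares oracle; 50 systems × $10^5$ Monte-Carlo draws for error
propagation; 20 replicates of the null scenario (190 pairs, 50 permutations
each) for type-I error and p-uniformity; 20 seeds of the planted-edge
scenario for orientation recovery; and a 10-marker cross with 200
permutations for the pooled-vs-per-parameter null comparison. These sizes
were chosen to estimate each property with comfortable Monte-Carlo margins
while keeping the whole validation in the minutes range on one CPU.

## Known limitations

- Two-allele dosage encodings only; no haplotype probabilities or >2-allele
  loci.
- No kinship/relatedness correction: GWAS-scale or structured populations
  need external care.
- Cross-ET coefficient covariances are approximated as zero.
- Least-squares reduction for $N > 2$ ETs has no per-ET goodness diagnostic
  yet; a pair fitting some ETs and not others is averaged.
- Main-effect consolidation by maximum p is conservative by design; weak but
  real effects conditioned on many partners may be lost.
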