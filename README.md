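# pleionet

Directed, signed variant-to-variant influence networks from multi-phenotype
cross data.

## The problem

Statistical epistasis — a two-locus interaction term in a phenotype
regression — tells you that two variants depend on each other, but not *how*:
which variant modifies the other, and whether the modification is suppressive
or enhancing. An interaction found for one phenotype may vanish for another,
leaving the result ambiguous. pleionet resolves this ambiguity by exploiting
pleiotropy: when the phenotypes of a cross share some genetics but not all,
fitting all phenotypes *simultaneously* constrains the interaction model
enough to orient it.

The package is for geneticists analyzing experimental crosses (backcrosses,
intercrosses) or genetic screens with two or more correlated quantitative
phenotypes — e.g. body weight, serum glucose, and serum insulin in a mouse
backcross. Phenotypes with moderate pairwise correlation (0.4 ≤ |r| ≤ 0.8)
are ideal.

## The model

1. **Eigentraits.** Phenotypes are rank-normalized and decomposed by singular
   value decomposition, `P = U D Vᵀ`. The orthonormal columns of `U` are the
   *eigentraits* (ETs); by default the first two are analyzed (up to 12).

2. **Pair scan.** For every pair of markers not in linkage disequilibrium
   (every one of the four two-locus genotype classes needs ≥ 6 observations),
   each selected ET *j* is regressed on

   ```
   ET_j ~ β0 + covariates + β1⁽ʲ⁾ x₁ + β2⁽ʲ⁾ x₂ + β12⁽ʲ⁾ x₁x₂
   ```

3. **Reparametrization.** The N interaction coefficients (one per ET) are
   replaced by two directed influences `m12` (variant 1 rescales variant 2's
   effective dose) and `m21` via

   ```
   β12⁽ʲ⁾ = m12 · β2⁽ʲ⁾ + m21 · β1⁽ʲ⁾   for every ET j
   ```

   — exact for two ETs (fitted values and residuals unchanged), least squares
   for more. Standard errors are propagated by a first-order delta method,
   and `z = m / se(m)` is the standardized effect: negative = suppressive,
   positive = enhancing.

4. **Significance.** ET rows are permuted against fixed genotypes;
   standardized effects from all pairs and permutations are pooled into one
   null distribution per statistic kind (variant–variant and
   variant–phenotype), giving large null samples at a fraction of the cost of
   per-parameter nulls. Two-sided add-one empirical p-values are corrected by
   Holm, Benjamini–Hochberg FDR (default, level 0.01), or local FDR.

5. **Network.** Significant effects populate an asymmetric adjacency matrix —
   source markers in rows, target markers and phenotypes in columns — plus
   edge-list and GraphML exports.

## Worked example

A built-in simulation plants one directed edge: marker `D3M1` affects both
phenotypes, `D8M1` affects only the first, and `D3M1` fully suppresses
`D8M1` (`m = −1`). The source's independent effect on the second phenotype is
what makes the direction identifiable.

```r
library(pleionet)
fx  <- make_fixture("one_directed_edge", seed = 11)
cfg <- run_config(fx$cross, n_perm = 50, method = "fdr", level = 0.05, seed = 11)
run <- run_full_analysis(cfg)
tidy(run$network)
#> # A tibble: 3 × 5
#>   source target weight sign        kind
#>   <chr>  <chr>   <dbl> <chr>       <chr>
#> 1 D3M1   D8M1    -4.50 suppressive variant_variant
#> 2 D3M1   ph2      4.48 enhancing   variant_phenotype
#> 3 D3M1   ph1      4.48 enhancing   variant_phenotype
```

The planted suppressive edge is recovered with the correct orientation
(`D3M1 → D8M1`, weight = standardized effect −4.50) alongside the source's
positive main effects on both phenotypes. `et_report(run$basis)` shows the
two ETs: the shared signal (59% of variance, equal loadings) and the
phenotype divergence (41%).

Real data enter through the R/qtl `"csv"` single-file format:

```r
x   <- read_cross_csv("cross.csv", genotype_codes("backcross"))
x   <- promote_covariates(x, "mom")   # covariates become pseudo-markers
cfg <- run_config(x, n_perm = 100, out_dir = "results")
run <- run_full_analysis(cfg)         # writes tables, GraphML, manifest, log
```

A thin command-line wrapper with `run` / `decompose` / `pairs` / `simulate`
subcommands is installed at `inst/cli/pleionet`.

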