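# genophen

Can a yeast strain's metabolome be predicted from the DNA barcode loci used
to classify it? `genophen` implements the statistical machinery for asking
that question in closely related strain panels such as the *Saccharomyces
sensu stricto* complex: it correlates per-locus evolutionary distance
matrices against distance matrices computed from whole-cell FTIR
fingerprints and annotated LC-MS metabolite tables, both for whole profiles
and wavelength-by-wavelength, across a series of ethanol-stress conditions.

The package is aimed at microbial taxonomists and chemometricians who have
(i) aligned marker sequences per locus, (ii) an FTIR absorbance matrix on
the standard 4000–400 cm⁻¹ axis and/or an annotated metabolite intensity
table, and (iii) optional viable-count data — or who want to study the
method itself on fully synthetic data with known ground truth, which the
built-in generators provide.

## The statistics at the core

* **Mantel-style matrix correlation.** For labeled distance matrices
  `D₁, D₂` over the same strains, `r = cor(vech(D₁), vech(D₂))` on the
  lower triangles, with significance from row/column permutations of one
  matrix — enumerated exhaustively (all `n!` relabelings) for the small
  strain counts typical of these panels. The parametric `t` p-value from
  `cor.test` is also reported but is anti-conservative on distances.
* **PSW, the percentage of significative wavelengths.** For each single
  descriptor (one wavenumber, one metabolite), strain distances
  `|xᵢ − xⱼ|` are correlated with a locus' genetic distance matrix; PSW is
  the percentage of descriptors with `r > 0.75`. Tracked across ethanol
  doses (0/8/12/16 % v/v), PSW trends are classified as *low*, *high*
  (maximum at a boundary dose, below/above a 5-point split) or
  *non-monotonous* (interior maximum).
* **Evolutionary distances** (p, JC69, K80, TN93 closed forms) with
  neighbor-joining trees and column-bootstrap support.
* **FTIR preprocessing**: SNR quality test (threshold 4000 in the
  2100–1900 cm⁻¹ window), rubberband baseline correction (lower convex
  hull on 64 support points), vector normalization, and the W1–W4
  fingerprint regions (fatty acids, amides, mixed, carbohydrates).
* **Metabolomics processing**: IQR filtering, median normalization,
  optional log2, Pareto scaling, PLS-DA via NIPALS with VIP scores
  (mean squared VIP ≡ 1, so VIP > 1 selects discriminant metabolites),
  and Ward clustering on Euclidean or Spearman distances.
* **Mortality** from plate counts: `M = (1 − Cv/Ct) × 100`.

## Worked example

```r
library(genophen)

sc <- scenario_config(
  seed = 42,
  planted_signals = list(
    planted_signal("W2", "DAL2", amplitude_per_condition = c(0, 0.05, 0.1, 0.2))
  )
)
res <- run_resting(sc, n_boot = 200, seed = 42)
res
#> <genophen_resting>
#>   top FTIR marker: LSU (r = 0.921, p = 0.042)
#>   top LC-MS marker: DAL2 (r = 0.997, p = 0.042)

st <- run_stress(sc, seed = 42)
dplyr::filter(st$psw, marker == "DAL2")
#> # A tibble: 4 × 4
#>   marker condition   psw trend_class
#>   <chr>      <dbl> <dbl> <chr>
#> 1 DAL2           0  4.33 high
#> 2 DAL2           8 11.5  high
#> 3 DAL2          12 11.1  high
#> 4 DAL2          16 12.5  high

head(st$mortality, 4)
#> # A tibble: 4 × 4
#>   strain    condition mortality flag_negative
#>   <chr>         <dbl>     <dbl> <lgl>
#> 1 S_bayanus         0    -0.192 TRUE
#> 2 S_bayanus         8    40.7   FALSE
#> 3 S_bayanus        12    97.2   FALSE
#> 4 S_bayanus        16   100     FALSE
```

What these numbers mean: the scenario plants a condition-dependent signal
in the amide window (W2) driven by the `DAL2` locus' genetic distances. The
resting-state analysis recovers `DAL2` as the best-correlated marker with
the LC-MS profiles (r = 0.997; p = 1/24, the exhaustive-permutation
minimum for four strains), while FTIR at rest shows only the chance-level
inflation expected from six strain pairs. Under stress, `DAL2`'s PSW rises
from the ~4–10% background to its maximum at 16% ethanol and the trend is
classified *high*. The mortality table tracks the planted dose–response
(the sensitive strain loses 40.7% viability at 8% ethanol and saturates by
12%); the slightly negative control entry is Poisson plate-count noise,
flagged rather than clipped.

A command-line wrapper with `simulate`, `resting`, `stress` and `all`
subcommands is installed at `inst/scripts/genophen.R`:

```sh
Rscript inst/scripts/genophen.R all --seed 3 --out run_dir --boot 200
```

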