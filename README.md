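# lingclim

Robustness analyses for claims that languages adapt to their climate.

## The problem

A recurring claim in evolutionary linguistics is that ambient humidity
shapes sound systems: dry air impairs fine vocal-fold control, so complex
lexical tone (three or more pitch contrasts) and heavy vowel use should be
rarer in dry regions. Such claims are tested on databases of thousands of
languages — but languages are not independent data points. They share
ancestry (families) and borrow from neighbours (areas), so naive
correlations are confounded by history and contact: Galton's problem.

`lingclim` implements the statistical toolkit for testing such claims
*robustly*:

* an **independence-constrained percentile resampling test** — each
  Monte-Carlo iteration samples groups of languages with no two sharing a
  family or an area, compares low-humidity percentiles of complex-tone
  (group C), non-complex (N) and all (R) languages, and reports the
  proportion of iterations with (C − N) > (C − R), equivalently
  q(N) < q(R);
* **measurement robustness** diagnostics: Cohen's (weighted) kappa between
  two databases coding the same variable, and a mixed-model bias test that
  asks whether between-source differences are structured by family, area or
  humidity (boundary-corrected ½χ²₀ + ½χ²₁ likelihood-ratio p-values for
  the variance components);
* **structural and estimation robustness** for comparative regressions: a
  Poisson mixed model of tone counts on z-scored humidity with family/area
  intercepts and humidity slopes, the five-row random-effects **ablation
  sweep** that exposes areal confounds, vowel-proportion and vowel-area
  models with interaction LRTs, and optimizer/start-point stability sweeps;
* **vowel-space geometry**: convex-hull areas of (F1, F2) formant charts
  (Hz², with log and Bark options);
* **corpus statistics**: the 2×K tone-category χ² for conversational-repair
  studies, seasonal contour-tone mixed models, per-document vowel/consonant
  phone ratios, and periodic GAM smooths against daily humidity;
* **Brownian-motion ancestral state reconstruction** (exact sparse
  least-squares solution of weighted squared-change parsimony) with
  phylomorphospace coordinates;
* **causal-graph tooling**: d-separation queries with open-path witnesses
  and backdoor screening, which turns "controlling for contact makes the
  disease and demography controls redundant" into a checkable computation;
* a seeded **synthetic world generator** that emulates the dependency
  structure of cross-linguistic databases (families as geographic clusters,
  grid areas, spatially autocorrelated humidity, climate-tracking areal
  borrowing), so every procedure above is validated against ground truth.

No real linguistic databases ship with the package; analyses run on
user-supplied CSV/newick/JSON files or on synthetic worlds.

## A worked example

```r
library(lingclim)

# a synthetic world with NO humidity effect but strong climate-tracking
# areal borrowing: the classic Galton's-problem trap
w <- generate_world(world_config(seed = 5, beta_humidity_tone = 0,
                                 n_areas = 12, borrowing_strength = 0.8,
                                 area_slope_sd = 1.0))

# the naive regression is fooled
round(summary(glm(n_tones ~ scale(humidity), poisson, data = w))$coefficients[2, ], 4)
#>   Estimate Std. Error    z value   Pr(>|z|)
#>     0.9718     0.0326    29.7818     0.0000

# the ablation sweep shows why: the "effect" lives in the areal structure
ablation_sweep(w)
#>                 model  estimate         se        z            p converged
#> 1          Full model 0.2957038 0.21373854 1.383484 1.665166e-01      TRUE
#> 2 No family intercept 0.2726993 0.22208978 1.227879 2.194925e-01      TRUE
#> 3     No family slope 0.2901905 0.22322714 1.299979 1.936083e-01      TRUE
#> 4   No area intercept 0.9529906 0.26335186 3.618697 2.960900e-04      TRUE
#> 5       No area slope 0.3180885 0.07070042 4.499104 6.824062e-06      TRUE
```

The naive model reports a massive humidity effect that does not exist;
the full mixed model (family and area intercepts plus humidity slopes)
correctly finds nothing (p = 0.17); removing either area term re-creates
the spurious significance. The same world passes through the percentile
test, agreement diagnostics, and vowel models — see `run_pipeline()` for
the one-call version that writes per-stage JSON/CSV and a summary report,
and `inst/scripts/lingclim-cli.R` for a shell wrapper.

The printed repair-study table is reproduced exactly from its counts:

```r
tc <- tone_contingency(c(46, 44, 43, 71), c(56, 34, 75, 64))
contingency_test(tc)[c("chi2", "df", "p")]
#> $chi2
#> [1] 9.892933
#> $df
#> [1] 3
#> $p
#> [1] 0.01949852
```

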