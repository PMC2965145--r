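# fragRegime

Multimodel inference for species–patch-area relationships across fragmented
landscapes, and the landscape-scale diversity statistics used to diagnose a
regime shift in community composition.

## The problem

In fragmented landscapes, whether local abundance and richness depend on the
size of a habitat patch is itself expected to depend on the *total* amount of
native vegetation left in the landscape: patch-area effects should be absent
where cover is high (immigration rescues small patches), appear at
intermediate cover, and vanish again after severe loss, when the landscape-wide
species pool has collapsed and even large patches are depauperate. Testing
this requires comparing structured hypotheses about *where* patch-area effects
operate — not fitting a single regression.

`fragRegime` implements that comparison for the canonical design: three
fragmented landscapes ordered by percent forest cover (e.g. 50, 30, 10%),
15–20 even-effort survey sites per landscape, paired continuous-forest
controls, two sampling years, and species grouped a priori into forest
specialists and generalists.

## The candidate set

Let `y_i` be the site response of a guild (total individuals over both years,
or the two-year sum of yearly species counts with a multiplicative offset of
2), and `x_i = log10(patch area in ha)`. Each candidate model is a set of
per-landscape component functions, each constant (`μ = e^c`) or log-linear in
patch area (`μ = e^{a + b x}`):

| M  | structure | error |
|----|-----------|-------|
| A  | one constant everywhere (null) | NB (abundance), Poisson (richness) |
| B  | one shared line everywhere | Poisson |
| C  | one constant per landscape | NB / Poisson |
| D  | per-landscape intercepts, shared slope | Poisson |
| D2 | per-landscape intercepts and slopes | Poisson |
| E  | constant at high cover; line below the cover threshold | Poisson |
| E2 | E with landscape-specific slopes | Poisson |
| F  | constants at the extremes, line only at intermediate cover | Poisson |

Abundance models without patch-area effects (A, C) use a Negative Binomial
error (one shared dispersion `k`, counted in `K`); everything else, and all
richness models, are Poisson. Model F is the regime-shift structure. The
whole-model negative log-likelihood is the sum of the component NLLs and is
minimized numerically (multi-start Nelder–Mead plus a quasi-Newton polish);
models are ranked by `AICc = −2 logL + 2K + 2K(K+1)/(n−K−1)`, with Akaike
weights `w_i` and the ΔAICc < 2 plausibility rule.

Gamma-diversity statistics: sample-based rarefaction (Mao Tau expectation
with the exact conditional variance, 95% normal CIs), Chao2 and first-order
jackknife incidence estimators, Bray–Curtis presence/absence (= Sørensen)
similarity in percent, and representation percentages of each fragmented
landscape against its paired control.

## Worked example

```r
library(fragRegime)
x <- generateScenario(presetScenarios()[["regime_shift"]], seed = 7)
resp <- aggregateResponses(x, "specialist")
mods <- enumerateCandidates(landscapeOrder(x), "abundance")
fits <- lapply(mods, function(m) fitModel(m, resp))
buildSelectionTable(fits)
#>   model_id K   logL  AICc deltaAICc     weight plausible
#> 1        F 4 -120.4 249.7     0.000  7.266e-01      TRUE
#> 2       E2 5 -120.4 252.1     2.447  2.137e-01     FALSE
#> 3       D2 6 -120.4 254.7     5.019  5.907e-02     FALSE
#> 4        E 4 -127.5 263.8    14.098  6.309e-04     FALSE
#> ...
```

The generating world here *is* the regime shift: high flat mean at 50%
cover, a positive patch-area slope only at 30%, low flat mean at 10%. Model
F wins (w = 0.73) and its coefficients recover the truth — `const[L50]` =
3.41 (true log 30 = 3.40), `slope[L30]` = 1.14 (true 1.056), `const[L10]` =
1.10 (true log 3 = 1.10). The only other plausible-adjacent candidates are
the more flexible structures (E2, D2) that contain F's shape.

```r
dv <- diversityReport(x, "specialist")
dv$richness
#>   landscape_id S_obs chao2 jackknife1
#> 1          L50    19 19.50   20.88
#> 2          L30    17 32.00   22.65
#> 3          L10     9 11.00   10.88
#> ...
round(dv$similarity, 1)      # Bray-Curtis % between fragmented landscapes
#>       L50   L30   L10
#> L50 100.0  77.8  64.3
#> L30  77.8 100.0  69.2
#> L10  64.3  69.2 100.0
```

Observed gamma diversity drops from 19 and 17 species to 9 in the most
deforested landscape — the abrupt loss of specialist taxa the regime-shift
world encodes — and the two most-forested landscapes are the most similar
pair in composition.

`runAnalysis(list(scenario = "regime_shift", seed = 1, outdir = "out"))` runs
all four guild × response analyses plus the diversity reports and writes
tab-separated tables; `readStudy()`/`writeStudy()` move real study tables in
and out. A thin command-line front end is in `inst/scripts/run_pipeline.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch — generates the
regime-shift and generalist-release worlds at the given seed, fits all eight
candidate models for the four guild × response combinations, builds the AICc
selection tables and diversity reports — and writes the acceptance JSON
object to `--out`.
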