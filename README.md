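# gridtrend

Population-trend estimation for unbalanced, spatially biased count surveys.

Volunteer waterbird censuses (the International Waterbird Census and its
relatives) count birds on thousands of wetland sites every winter, but with
no sampling design: effort clusters in hotspots, sites differ by orders of
magnitude in the numbers they hold, and site-year records are missing
irregularly. Estimating a flyway-scale trend from such data has to deal with
spatial autocorrelation induced by uneven effort and with strong
overdispersion. `gridtrend` implements a complete workflow for this:

1. a **preliminary diagnosis** — a Poisson mixed model with site intercepts,
   site random year-slopes and observation-level overdispersion, followed by
   a Moran's I test of the fitted site slopes on a relative neighborhood
   graph;
2. **grid standardization** — sites are grouped into square metric cells
   (default 75 × 75 km, equal-area ETRS89-LAEA projection) so each occupied
   cell is one sampling unit of equal weight;
3. the **hierarchical trend model**

       N_it ~ Poisson(lambda_it)
       log lambda_it = alpha_i + (beta0 + d_i) * t + e_it
       d_i ~ N(b_q(i), sigma_d),  b_q ~ N(gamma * L_q, sigma_b),
       e_it ~ N(0, sigma_e)

   with `t` the year centered mid-window, `L_q` the cell centroid latitude,
   fitted by maximizing a Laplace-approximated marginal likelihood built on
   sparse Newton solvers (REML-type treatment of the site intercepts);
4. **post-fit verification** — Moran tests on the predicted random-effect
   deviations, normality checks, residual-by-year pattern checks;
5. **summaries** — percentage declines `r = 100 (1 - exp(D (beta0 + gamma L)))`
   with delta-method SEs, typical cross-cell/cross-site decline ranges,
   an equal-cell-weight flyway mean trend, and nested trajectory bands.

A synthetic-data generator (`generate_landscape()`, `generate_counts()`)
draws surveys from exactly this model with known ground truth, so the whole
chain is testable end to end; its defaults emulate the NW-European pochard
winter-count study conditions (about 200 occupied cells between 46° and
60°N, heavy lognormal overdispersion, 0–4 missing years per site).

## Worked example

The numbered scripts under `analysis/` run the full study on a simulated
survey (200 cells × 5 sites × 11 years from the default truth). The same
can be done in one call:

```r
library(gridtrend)
report <- run_pipeline(list(
  synthetic = list(n_cells = 200, sites_per_cell = 5),
  seed = 20, outdir = "results/pipeline"))
```

Running the staged scripts prints, e.g.:

```
$ Rscript analysis/02_preliminary_diagnosis.R
retained 982 sites surveyed >= 7 of 11 years
preliminary mean slope: -0.0300 (SE 0.0052) -> 3.0%/yr decline
Moran's I = 0.1223 (E[I] = -0.0010, sd = 0.0294), z = 4.19, p = 1.4e-05
```

The significant positive Moran statistic on the site slopes is the symptom
of spatially uneven sampling; it motivates the gridding. After the
hierarchical fit (`analysis/03_fit_hierarchical.R`):

```
<trend_fit: hierarchical> logLik = -44008.90, converged
        estimate     se
beta0     0.4564 0.0693
gamma    -0.0092 0.0013
sigma_b   0.0401 0.0084
sigma_d   0.0763 0.0079
sigma_e   1.1950 0.0113
```

all five parameters sit within two standard errors of the generating truth
(0.38, -0.008, 0.033, 0.073, 1.18), the latitude effect is negative
(steeper declines further north), and the post-fit Moran tests on the
slope deviations are non-significant — the grid absorbed the spatial
structure. `analysis/04_trend_summaries.R` then converts the fit into
percentage declines by latitude, the flyway mean (equal weight per occupied
cell), typical decline ranges, the intercept–slope correlation, and
log-scale trajectory bands whose width is zero at the centering year.

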