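# ecarbon

Estimation of **eco-morphodynamic Carbon Export (eCE)** — the annual mass of
organic carbon that large free-flowing tropical rivers mobilize from their
floodplain forests through channel migration, bank erosion, and flood-driven
reworking. The package is aimed at river scientists and carbon-cycle
modellers who want to run, probe, or extend the satellite-based eCE
estimation framework on their own regions of interest, and to validate every
stage of it against synthetic scenes with known ground truth.

## The method in brief

For a region of interest (ROI) `j` gridded into pixels `k`:

```
eCE_j = Σ_k L_jk · ρ_jk ,   L_jk = A_jk · P_jk / T
```

* `P_jk` — probability that the observed forest loss at the pixel was
  **river-driven** rather than urbanization, wildfire, or anthropic
  land-cover change: `P = P_u · P_wf · P_lc`, with
  `P_u = 1 − 0.333·log10(PD+1)` (0 beyond 1000 people/km²) and the event
  filters `P = Π (1 − f(Δt))` using a ±5 yr causal step window `f`.
* `ρ_jk` — biomass carbon density at the time of loss
  (carbon = 50% of AGB + BGB, `BGB = 0.489·AGB^0.89`), assessed four ways:
  constant year-2000 density (**M1**), a calibrated logistic growth update
  to the loss year (**M2**, per-block growth factor identified from two
  biomass epochs 8 yr apart), or ROI spatial means of the fine (**M3**) /
  coarse (**M4**) maps.
* `A_jk` — pixel area; `T = 20` yr (2000–2019).

Around the estimator: a carbon-signature classifier that labels each ROI's
density distribution as negatively skewed / multimodal / positively skewed /
bell-shaped, and an uncertainty module propagating Bernoulli × density
errors (Goodman's product-variance formula) through autocorrelation blocks
to ROI and continental scale. A synthetic floodplain scene generator with
per-pixel ground-truth cause labels makes the whole chain testable offline.
See `vignettes/ece-methods.Rmd` for the full account.

## Worked example

```r
library(ecarbon)

spec  <- grid_spec(64, 64, cell_size = 30, coarse_factor = 16)
scene <- simulate_scene(spec, scene_params(), seed = 1)
scene
#> <ece_scene> 64 x 64 (coarse factor 16); 328 loss pixel(s); truth eCE = 117.1 MgC/yr
#> landcover     river     urban  wildfire
#>        41       205        41        41

res <- run_pipeline(scene)
round(res$ece, 2)        # MgC/yr by density method
#>     M1     M2     M3     M4
#> 107.01 108.90 105.84 113.94
round(res$ece_A, 2)      # MgC/km2/yr (ROI area 3.6864 km2)
#>    M1    M2    M3    M4
#> 29.03 29.54 28.71 30.91
res$a_rdfl               # river-driven forest loss, km2/yr
#> [1] 0.009225
res$signature
#> <signature_class> 4 = Bell-shaped (BS)
```

Reading the output: of the 328 simulated loss pixels, only the 205
river-caused ones pass the probabilistic filter (the scene's confounded
losses receive `P = 0` exactly), giving an RDFL area of 0.0092 km²/yr. The
four density methods agree within a few percent, bracketing the generator's
truth of 117.1 MgC/yr — they fall slightly below it because M1/M3/M4 ignore
the vegetation growth between 2000 and each loss year, and the M2 growth
factors are calibrated, not read from the generator. The ROI-scale
uncertainty (Cv = 1, perfectly correlated within the ROI) is 100% of the
estimate, reproducing the expected conservative limit.

A command-line wrapper is available after install:

```sh
Rscript inst/cli/ece run-all --config cfg.yaml --seed 9 --outdir out/
```

which writes the 22-field ROI attribute table (`results.csv`), polygon and
centroid GeoJSON layers, probability rasters, and a JSON summary.

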