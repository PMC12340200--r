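# gliaquant

Quantification of synaptic amyloid-beta accumulation and glial engulfment of
synapses in 4-channel 3D confocal image stacks, with a synthetic-microscopy
generator and a mixed-model inference layer so that the whole pipeline is
testable end-to-end without access to original tissue images.

## Who this is for

Neuropathology and neurodegeneration labs quantifying immunofluorescence
z-stacks stained for astrocytes (GFAP), amyloid-beta (4G8), presynaptic
terminals (synapsin-1) and microglia (IBA1) — the standard panel for asking
whether amyloid accumulates inside synapses and whether glia preferentially
internalise amyloid-bearing synaptic material, as studied in Alzheimer's
disease tissue and in naturally occurring animal models such as feline
cognitive dysfunction syndrome (CDS).

## What it computes

Each stack is segmented per channel (3D Otsu by default; fixed and
percentile thresholds available) and reduced to voxel-level percentages of
total stack volume:

- **burden** of channel *A*: `100 · |A| / N` voxels;
- **pairwise colocalization**: `100 · |A ∧ B| / N`;
- **triple colocalization**: `100 · |A ∧ B ∧ C| / N`;
- **engulfment enrichment**: with synapsin mask *S*, amyloid mask *β* and a
  glial mask *G*,

  `ratio = [ |S∧β∧G| / |S∧β| ] / [ |S∧¬β∧G| / |S∧¬β| ]`

  — a ratio above 1 means amyloid-positive synaptic voxels are
  preferentially located inside glia. Undefined denominators propagate as
  `NA`, never as fabricated zeros.

Study design helpers implement plaque detection (connected amyloid
components by equivalent spherical diameter), the plaque/adjacent paired-ROI
plan, random-field plans for plaque-free cases, and per-case top-k stack
selection by amyloid burden.

Inference follows the field's standard hierarchy of stacks within ROIs
within cases: linear mixed-effects models `y ~ Group + (1|Case)` and
`y ~ PlaqueStatus * Group + (1|Case/ROI)` (lme4, REML), assumption checks by
residual diagnostics with an automatic transformation ladder (sqrt, log,
arcsine-sqrt, Tukey ladder of powers), AIC/BIC model choice, estimated
marginal-mean contrasts with Tukey studentized-range adjustment (containment
degrees of freedom, method recorded in every row), and case-level Spearman
correlations.

The synthetic generator renders punctate synapses, diffuse
Gaussian-falloff plaques, branched glial arbors, amyloid-positive synaptic
cores, engulfment by relocation of puncta into glial volumes, Gaussian PSF
blur and Poisson/Gaussian noise — and returns exact voxel-count ground truth
computed on the pre-blur geometry, so every downstream number has an oracle.

## Worked example

```r
library(gliaquant)

sc <- generate_scene(scene_params(plaque_present = TRUE), seed = 17)
m  <- measure_stack(sc$stack, case_id = "demo", stack_id = "S01",
                    plaque_status = "plaque")
```

prints (values from this exact seed):

```
Abeta burden: 14.71%  IBA1 burden: 3.14%
synapsin-in-microglia colocalization: 0.421%
triple (Abeta+synapsin+IBA1): 0.1381%
microglial engulfment enrichment ratio: 1.24
```

i.e. in this simulated plaque field, 14.7% of voxels are amyloid-positive,
0.42% are synapsin-and-microglia double-positive, and amyloid-positive
synaptic voxels are 1.24 times more likely to sit inside microglia than
amyloid-negative ones.

The packaged 25-case cohort table reproduces the cohort arithmetic exactly:

```r
demographics(parse_case_table(case_table_fixture()))
#> groups: Young=7, Aged=10, CDS=8
#> sex:    F=16 (64%), M=8 (32%), Unknown=1 (4%)
#> mean ages: Young=4.71, Aged=17.10, CDS=16.75
#> CDS vs Aged age: Wilcoxon W = 37.0, p = 0.822
#> sex x group: Fisher exact p = 0.354 (Unknown excluded)
```

And a paired plaque contrast on a simulated measurement cohort:

```r
d <- simulate_lmem_cohort(c(8, 8, 8), n_pairs = 3, plaque_effect = 1, seed = 1)
f <- fit_lmem(d, model_spec("y", "plaque_by_group", "nested"))
posthoc_contrasts(f, "plaque_within_group")
#>                   comparison estimate    t df  p_adjusted
#> 1 plaque - no_plaque | Young    1.297 4.66 69     1.5e-05
#> 2  plaque - no_plaque | Aged    0.883 3.17 69     2.3e-03
#> 3   plaque - no_plaque | CDS    1.285 4.61 69     1.8e-05
```

## Command line

```sh
Rscript inst/scripts/gliaquant.R simulate --out demo --seed 1
Rscript inst/scripts/gliaquant.R quantify --out demo --seed 1
Rscript inst/scripts/gliaquant.R analyze  --out demo --seed 1
Rscript inst/scripts/gliaquant.R report   --out demo
```

All outputs are tab-separated text with provenance columns (seed, config
hash); stacks are multi-page TIFF with channel names and voxel size in the
metadata.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model, the
synthetic world and its limits, the numerical conventions and the design
decisions. Function-level documentation is in the roxygen comments in `R/`.
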