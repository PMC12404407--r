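# qmephantom

Digital breast-tissue phantoms and a full quantitative micro-elastography
(QME) simulation/reconstruction workflow in R.

QME images tissue stiffness by compressing a sample against an imaging
window while acquiring phase-sensitive OCT: local displacement comes from
the interferometric phase difference between loaded and unloaded
acquisitions, axial strain from a weighted least-squares depth gradient of
displacement over a 100 μm window, surface stress from the strain of a
pre-characterized compliant layer (500 μm, 16 kPa) via its stress–strain
curve, and elasticity as

    E(x, y, z) = σ(x, y) / |ε(x, y, z)|

under a uniform-uniaxial-stress assumption. Boundary sharpness is quantified
by fitting step responses to an error function
`A·erf((x − x0)/(σ√2)) + B`; the derivative is a Gaussian whose FWHM
(`2√(2 ln 2)·σ`) is the local spatial resolution.

The package builds the digital analogues of two phantom designs used to
study elastogram formation at tissue boundaries:

- an **IDC-mimicking phantom** — adipose (18 kPa), stroma (48 kPa) and
  invasive-ductal-carcinoma (230 kPa) regions extruded from nested binary
  masks, with OCT backscatter contrast 17/30/23 dB;
- a **duct-mimicking phantom** — a 58 kPa disc with a 1 mm main duct and a
  0.8 mm branch at 11 mm arc length, in hollow or fluid-filled states.

It then simulates compression (per-column series-spring mechanics, with an
explicit lateral-coupling emulation), synthesizes correlated speckle
tomogram pairs with displacement encoded in phase, reconstructs
displacement → strain → stress → elasticity, segments en-face images
(23 dB threshold, hole filling, 10,000 px area criterion), fits boundary
step responses, and exports watertight STL mold meshes.

## Worked example

```r
library(qmephantom)

cfg <- experiment_config(seed = 1,
                         meta = acquisition_meta(pitch_um = c(40, 40, 10)),
                         coupling_fwhm_um = 200)
rep <- run_idc_experiment(cfg)
rep$region_stats[, c("region", "elast_median_kpa", "strain_median")]
#>    region elast_median_kpa strain_median
#> 1 adipose            18.08    -0.0009954
#> 2  stroma            47.66    -0.0005033
#> 3     idc           163.43    -0.0001746
```

The adipose and stroma medians recover the 18 and 48 kPa ground truths to
well under 1 kPa; the small IDC inclusion reads below its 230 kPa truth
because the 200 μm lateral-coupling kernel mixes it with the surrounding
stroma — the boundary-blurring effect the phantom exists to study. The
|strain| ordering (adipose > stroma > IDC) is the stiffness ordering
reversed, as compression mechanics requires.

```r
res <- rep$resolution
res[, c("label", "fwhm_um", "r_squared")]
#>                       label fwhm_um r_squared
#> 1     stroma_adipose_strain   759.1    0.9788
#> 2 stroma_adipose_elasticity   397.5    0.9701
#> ...
```

Each row is an error-function fit across a region boundary; `fwhm_um` is the
transition width (the local resolution of the map along that line) and rows
with R² below 0.93 are flagged.

The numbered drivers under `analysis/` run the full studies and write their
tables to `results/`:

```sh
Rscript analysis/01_build_phantoms.R    # phantom geometry summary
Rscript analysis/02_idc_experiment.R    # region stats + boundary FWHMs
Rscript analysis/03_duct_experiment.R   # hollow vs fluid duct comparison
Rscript analysis/04_mold_export.R       # watertight STL molds
```

`03_duct_experiment.R` prints, for example, that hollow duct interiors are
masked (about 4% valid voxels) while fluid-filled ducts remain valid and
deform roughly five times more than the bulk, with a wider cross-duct
elasticity transition (≈220 μm vs ≈64 μm FWHM at 50 μm pitch).

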