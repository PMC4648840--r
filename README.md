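# tendondic

Full-field strain analysis of tendon tissue under uniaxial load by
three-dimensional digital image correlation (DIC), with a seeded synthetic
test rig providing exact ground truth.

Soft tissue is anisotropic, non-linear and strongly inhomogeneous, so point
sensors (strain gauges, extensometers, LVDTs) miss regional strain and
strain gradients. DIC tracks a random speckle texture painted on the
specimen: small square image patches ("facets") act as thousands of virtual
extensometer points, each located with subpixel accuracy in every frame;
two calibrated cameras triangulate the facets to 3D surface coordinates,
removing the out-of-plane error of single-camera setups. `tendondic`
implements the complete measurement chain and the analyses used to validate
it on tendon tensile tests.

## What is inside

| Layer | Contents |
|---|---|
| Synthetic rig | `speckle_scene()`, `simulate_experiment()`, `render_frame()`, `ground_truth_maps()` — stereo speckle-image sequences of a loaded tendon with analytic displacement/strain ground truth, grip slip, hysteresis and sensor noise |
| DIC core | `build_facet_grid()`, `zncc()`, `integer_search()`, `subpixel_refine()` (inverse-compositional Gauss–Newton on ZNSSD, bicubic interpolation), `track_sequence()` |
| Stereo | `calibrate_dlt()`, `stereo_match()`, `triangulate()`, `reconstruct_displacements()` |
| Strain | `local_gradient()`, `strain_from_gradient()` (engineering / Green–Lagrange), `tangent_project()`, `surface_strain()`, `average_over_region()` |
| Analysis | `virtual_extensometers()` (DIC-1 grip-to-grip vs DIC-2 on-specimen), `quantify_slip()`, `assess_scatter()`, `linear_agreement()`, `fit_modulus()`, `cumulative_distribution()`, `area_fraction_exceeding()`, `hysteresis()` |
| Pipeline / IO | `run_stage()` (simulate → calibrate → track → strain → analyze → report), YAML run configs, TIFF/PNG/CSV/JSON readers and writers, run manifest; CLI at `inst/cli/tendondic.R` |

The core statistic chain in the field's notation: facets are matched by
zero-mean normalized cross correlation (ZNCC) and refined on the ZNSSD
criterion with an affine shape function; displacement gradients come from
local weighted least squares, giving the surface strain tensor
(ε_xx transverse, ε_yy longitudinal, ε_xy shear, reported in %); grip slip
is the DIC-1 − DIC-2 elongation difference; the cumulative strain
distribution A(x) is the fraction of 1 × 1 mm squares whose strain is ≤ x.

## Worked example

A desk-scale rig (8 × 12 mm specimen, 220 × 400 px images, ~1 min):

```r
library(tendondic)

specimen <- specimen_model(ref_width_mm = 8, ref_gauge_length_mm = 12,
                           cross_section_area_mm2 = 20, modulus_E_MPa = 500,
                           hysteresis_offset_mm = 0.1,
                           inhomogeneity_corr_length_mm = 2)
protocol <- load_protocol(preload_N = 48.9, step1_increment_N = 20,
                          step1_limit_N = 100, step2_increment_N = 50,
                          max_load_N = 300, unload_increment_N = 100,
                          frames_per_step = 2)
slip    <- grip_slip_model(bone_block_slip_fraction = 0.33,
                           tissue_slip_fraction = 0.20)
speckle <- speckle_params(image_width_px = 220, image_height_px = 400)

scene <- speckle_scene(specimen, protocol, slip, speckle, seed = 5,
                       plate_width_mm = 10, plate_height_mm = 3)
sim <- simulate_experiment(scene)
res <- analyze_experiment(sim)
```

Formatting the key results (`res$agreement`, `res$slip`, `res$modulus`)
prints:

```
DIC-1 vs reference displacement: R^2 = 1.00000, slope = 1.000
grip slip at max load: 0.403 mm (62.8% of grip travel)
strain overestimation factor (grip-to-grip / on-specimen): 1.93
fitted Young's modulus: 510.5 MPa (generated with 500 MPa)
```

Reading these numbers: the grip-to-grip virtual extensometer reproduces the
rig's commanded displacement essentially perfectly (R² = 1.000); more than
half of the apparent grip travel is clamp slip, not tissue stretch (the
measured 62.8% on this short-gauge rig corresponds to the scheduled 53%
slip measured between on-specimen bands 0.95 mm inside the clamps), so a
grip-based strain would overestimate tissue strain by a factor ≈ 2; and the
stress–strain slope over the central 4 mm disc recovers the generating
modulus within ~2%.

A full pipeline run from a YAML config (writes frames, calibration,
extensometer/strain CSVs, `analysis_report.json` and a manifest):

```sh
Rscript inst/cli/tendondic.R all --config inst/config/default.yaml
```

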