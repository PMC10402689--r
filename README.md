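# lumenreg

Rigid 2D/3D registration of endoscopic views to a preoperative surface
model of a branched luminal organ — the initial-alignment problem of
image-guided retrograde intrarenal surgery, where a ureteroscope's 2D
view must be located inside a CT-derived model of the renal collecting
system.

## Method

`lumenreg` estimates the 6-DOF transform `T` (model → camera, mm) by
matching two sparse 2D point sets in every candidate view:

* **Generated contours** — 3D *salient structural points* of the cavity
  mesh (points whose normal can be perpendicular to a sight line from
  the pelvic volume `V_p` and which are visible from it, i.e. calyx rims
  and pelvis–calyx junctions), re-selected per pose by a
  perpendicularity test `θ_i = arccos|ĝ_i·ŵ_i| ≥ θ_T` plus an occlusion
  test, and projected through a pinhole camera.
* **Actual contours** — barycenters of dark, high-contrast SLIC
  superpixels of the 2D image (contrast `max|l_sp − l_neighbour| ≥ τ_gc`,
  size `≥ τ_n`).

Alignment is scored by a joint-probability mutual information over
pairwise affinities, `p_ij ∝ exp(−d_ij/s)`,
`C_p = Σ_ij p_ij ln(p_ij / (Σ_k p_kj Σ_l p_il))`, with a gradient
analogue `C_grad` built from `exp(−(m_ij + o_ij))`, and an auxiliary-view
term `C_p(p, T_n)` with `T_n = T_0n·T_0` obtained from known inter-frame
motions. The pose is recovered by a coarse-to-fine differential-evolution
search: a location-only stage over the full ±15° / ±10 mm box that
shrinks the range, then the full weighted cost
`C_fine = w1·C_p + w2·C_grad + w3·C_p_aux` inside it.

A synthetic branched-cavity generator (watertight kidney-like meshes,
exterior evaluation markers, interior endoscope poses) and a software
Phong-headlight ray-casting renderer make the entire pipeline testable
with no external data. Accuracy is evaluated as mean target registration
error (mTRE) over ten marker points, orientation error (geodesic angle)
and position error.

See the methods vignette (`vignettes/contour-registration.Rmd`) for the
model, parameter defaults, and design rationale.

## Worked example

```r
library(lumenreg)

# a simple 3-calyx phantom with 10 exterior markers and 4 rendered views
scene <- build_scene(scene_spec_k2(), n_poses = 4, seed = 1)

# register view 2 (the frame with the most contour structure) starting
# from a perturbed pose (+/-15 deg / +/-10 mm); the other frames are
# auxiliary multi-view constraints
gt <- scene$gt_poses[[2]]
T0 <- perturb_pose(gt, search_range(gt, 15, 10), seed = 3)
res <- register_views(scene, T0 = T0, range = search_range(T0, 15, 10),
                      cfg = de_config(rng_seed = 7), view = 2,
                      aux_view = c(1, 3, 4))
evaluate_registration(res, gt, scene$markers, T0 = T0)
#> # A tibble: 3 x 4
#>   stage    mtre    oe    pe
#>   <chr>   <dbl> <dbl> <dbl>
#> 1 initial  6.65 14.2  4.52
#> 2 coarse   1.62  5.01 1.11
#> 3 fine     1.07  3.96 0.536
```

The start pose has 6.7 mm of mean marker error (mTRE) and a 14°
orientation error; the coarse location-only search brings the markers to
1.6 mm, and the fine stage (gradient + multi-view terms at a sharper
matching scale) to 1.1 mm with 4.0° orientation and 0.5 mm position
error. `tidy(res)` returns the per-generation best-cost trace and
`autoplot(res)` plots it by stage.

A command-line wrapper is installed with the package
(`system.file("cli", "lumenreg", package = "lumenreg")`) with
`simulate`, `extract-features`, `register` and `evaluate` subcommands
over scene directories.

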