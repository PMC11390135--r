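# holoflow

Rapid 3D localization of cells flowing through a microfluidic channel,
recorded as off-axis digital hologram video — without reconstructing a
single hologram.

## The problem

In holographic imaging flow cytometry an off-axis interferometer records
cells translating through a channel; every frame carries high-frequency
carrier fringes whose modulation encodes the cells' complex optical
field.  The conventional way to track cells in 3D demodulates **every
frame** in the Fourier domain, unwraps the phase, segments the phase map,
and numerically refocuses each cell — accurate, but expensive for long
recordings.  `holoflow` implements a spatiotemporal alternative that
stays in the spatial domain:

* **Transverse (x, y):** holograms are down-sampled by 2×2 binning (which
  cancels the near-Nyquist carrier), the static background is removed
  by the *superimposed spectrum method* (SSM: average the frame spectra,
  equivalently the temporal mean) or the *static background matching
  method* (SBMM: per-block, adjacent frames whose normalized correlation
  ≥ 0.98 are declared static and averaged), and cells are localized on
  the normalized frames by a morphological chain (Gaussian blur →
  gradient edges → Otsu threshold → closing/filling → centroids).
  Detections over time form the spatiotemporal tracking line (STTL)
  matrix whose quasi-straight lines are the flowing cells.
* **Axial (z):** for each cell, the three frames in which it advances by
  one diameter per step are selected; the carrier phase then steps by
  ≈ π/2 between the three cell-registered regions of interest, so the
  three-step combination

  E = 1 + (i/4)·[(U₁ − U₂) + i·(U₃ − U₂)]

  assembles a partial complex amplitude of the cell (spatiotemporal
  phase shifting, STPS).  Propagating E − 1 with the angular-spectrum
  method and minimizing the Tamura coefficient TC = √(σ/μ) of the
  amplitude gives the in-focus z, assigned to the middle frame.

The package also provides a physically faithful synthetic hologram-video
simulator (phase-only cells with parabolic phase caps, NA-limited pupil,
tilted reference, static illumination envelope, shot-noise approximation)
with exact 3D ground truth, and the conventional
demodulate–unwrap–refocus pipeline as the reference oracle.

## Worked example

Simulate a two-cell recording with the standard optics (532 nm, NA 0.65,
40×, 5.86 µm camera pixels, Δt = 0.998 ms) on a 600×960-px sensor, run
the full proposed pipeline, and compare with ground truth:

```r
library(holoflow)

optics   <- default_optics(sensor_rows = 600L, sensor_cols = 960L)
scenario <- sim_scenario_flow(optics, n_cells = 2, n_frames = 120, seed = 42)
video    <- render_video(scenario)
video$stack
#> hologram_stack: 120 frames of 600 x 960 px, dt 0.998 ms, pitch 0.1465 um

result <- track_proposed(video$stack, optics, background_method = "ssm")
for (tr in result$tracks) print(tr)
#> cell_track 1: 120 detections, frames 1-120, v = 625.6 um/s, slope = 0.01 um/s, 1 z estimates
#> cell_track 2: 120 detections, frames 1-120, v = 564.1 um/s, slope = -0.01 um/s, 1 z estimates

study <- match_truth(result$tracks, video$truth)
study$matches[, c("track", "cell_id", "v_err_rel", "z_mean_abs_err_um")]
#>   track cell_id     v_err_rel z_mean_abs_err_um
#> 1     1       1 -0.0003745558        1.23176629
#> 2     2       2  0.0001048092        0.08224503
sprintf("transverse error: %.3f um (x), %.3f um (y)",
        mean(abs(study$dx)), mean(abs(study$dy)))
#> "transverse error: 0.005 um (x), 0.008 um (y)"
```

Velocities are recovered to a few 0.01 %, transverse positions to
hundredths of a micrometer, and the STPS axial estimates land within the
micrometer-level band expected of the method (here 1.23 and 0.08 µm for
the two cells).  Utility summaries follow the standard worked formulas,
e.g. the monitoring period of an 11 618-frame recording:

```r
monitoring_period(11618, 0.998e-3)
#> [1] 11.59476        # ~11.6 s
cell_throughput(2, optics, 120)  # cells per m^3 per second in this clip
#> [1] 1.956779e+13
```

See the vignette
(`vignettes/spatiotemporal-holographic-tracking.Rmd`) for the recording
model, the reasoning behind every numerical choice (carrier placement,
notch demodulation, quadrature-snapped triplet spacing, guarded
sub-pixel registration), and the known limitations.

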