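---
title: "Spatiotemporal 3D localization of flowing cells in off-axis holographic video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal 3D localization of flowing cells in off-axis holographic video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(holoflow)
```

## The problem

Holographic imaging flow cytometry records cells translating through a
microfluidic channel with an off-axis interferometer: the tilted reference
beam imprints high-frequency carrier fringes on every frame, and the
interference term encodes the complex amplitude of the light scattered by
each cell.  Conventional 3D tracking demodulates every frame in the
Fourier domain, unwraps the phase, segments the quantitative phase map
(QPM), and refocuses a complex region of interest (ROI) per cell to find
its axial position.  That per-frame reconstruction dominates the cost of
long recordings.

`holoflow` implements the rapid alternative: transverse (x, y) positions
are measured *directly on the holograms* after carrier-cancelling
down-sampling and background elimination, and the axial position is
recovered from just three hologram ROIs per cell by spatiotemporal phase
shifting (STPS), so no frame-by-frame reconstruction is ever performed.
The package also contains a full synthetic-hologram simulator (the study's
ground truth) and the conventional pipeline (the reference the proposed
method is compared against).

## Recording model and coordinate conventions

A frame is an `sensor_rows x sensor_cols` intensity raster; rows map to
the transverse channel cross-section (x), columns to the flow axis (y).
Pixel `m` (1-based) sits at object-space coordinate `(m - 1) * Delta`,
with `Delta = camera_pitch / magnification` (0.1465 um for the default
5.86 um / 40x configuration).  Frame `f` is acquired at
`t = (f - 1) * frame_interval`.  All lengths are meters internally; track
tables report micrometers.

The simulator renders

`I = V * |1 + sum_j exp(2 pi i z_j / lambda) P_{-z_j}[t_j - 1] + R|^2`

where `t_j = exp(i phi_max,j max(0, 1 - r^2/R_j^2))` is a phase-only cell
with a parabolic phase cap, `P_z` is angular-spectrum propagation over the
signed distance `z`, `R = a_R exp(2 pi i (f_x m + f_y n))` is the tilted
reference, and `V` is a static radial illumination envelope.  Three
modelling details matter and were validated against the conventional
reconstruction:

* each scattered wave carries the plane-wave phase `exp(2 pi i z/lambda)`
  the illumination accumulates between the cell plane and the focal
  plane — without it the rendered defocused field is not the true
  propagation of the in-focus cell and no refocusing criterion can
  recover `z`;
* the scattered spectrum is clipped by the objective pupil at
  `NA / lambda`, as in any real microscope;
* multiple cells superpose to first order (`U - 1` adds), which is exact
  for the sparse flows the method targets; multiple scattering between
  cells is out of scope.

The carrier defaults to `(0.47, 0.25)` cycles/pixel: fringes of period
about two pixels across the channel (near half the sampling frequency, as
in the emulated instrument) and a quarter of the sampling frequency along
the flow axis.  The choice is deliberate on three counts: (i) 2x2 binning
almost nulls the x-carrier, (ii) the flow-axis component can realize
quarter-period STPS steps (below), and (iii) the ~6% fringe residual that
survives binning gives the static background measurable structure, which
the background-recovery accuracy statistic (a normalized correlation)
needs — a perfectly flat background would make that statistic undefined.
The multiplicative noise model (relative Gaussian, default 0.5%) is a
standard approximation to shot noise at high photon counts.

## Transverse localization

1. **Down-sampling** (`downsample_half`): 2x2 mean binning.  Binning, not
   decimation: the average of adjacent pixel pairs nulls a period-2
   carrier exactly and suppresses near-Nyquist carriers strongly, whereas
   decimation would alias them into the pass band.
2. **Background elimination**: either the superimposed spectrum method
   (`ssm_background` — average the frame spectra and invert, which by
   linearity equals the temporal mean, an identity the tests use as an
   exact oracle) or the static background matching method
   (`sbmm_background` — per block, adjacent frame pairs whose normalized
   correlation reaches 0.98 are declared static and averaged; blocks that
   are never static fall back to the temporal median).  Near-constant
   blocks carry no correlation signal and are treated as static.
   Dividing by the recovered background leaves frames that are ~1
   everywhere except on moving cells.
3. **Detection** (`locate_cells_frame`): Gaussian blur (sigma 2
   down-sampled px), gradient-magnitude edges, Otsu threshold floored at
   `median + 8 * mad` of the gradient (so cell-free frames yield nothing),
   closing, hole filling, connected components, area filter (20 px), and
   per-component centroid plus equivalent radius `sqrt(area/pi)`.
4. **STTL and linking**: detections are stamped into the spatiotemporal
   tracking-line matrix (full-resolution x rows times frames) and linked
   into tracks by greedy nearest-neighbour association (gate 3 um per
   frame step, one-frame gap bridging, minimum five detections).  The
   transverse drift rate is the least-squares slope of x against t; the
   flow velocity is traversed distance over duration, per the constant
   flow assumption `y(t) = y_first + v (t - t_first)`.

On the default synthetic scenarios the transverse errors are ~0.01 um —
far below the half-micron scale of real recordings, because the simulated
point-symmetric diffraction patterns have unbiased centroids.  What the
passing tests show is that the chain is unbiased and internally
consistent; they do not certify real-data accuracy, where asymmetric
aberrations, debris, and cell shape variability dominate.

## Axial localization by spatiotemporal phase shifting

For each track the triplet of frames in which the cell advances by one
diameter per step is selected (`select_triplet`), three cell-registered
ROIs are cut from the *original full-resolution* holograms
(`extract_roi`), and the field

`E = 1 + (i/4) [(U1 - U2) + i (U3 - U2)]`

is assembled (`stps_field`).  Because the ROIs are registered on the
cell, the static scene's carrier phase steps by
`2 pi f_y * (displacement in px)` between ROIs; with quarter-period steps
the combination cancels the static content and extracts one interference
sideband, i.e. a partial complex amplitude of the cell — sufficient for
refocusing, not for quantitative phase.  The field is refocused by
scanning the Tamura coefficient `TC = sqrt(sd/mean)` of the propagated
amplitude (`autofocus_tc`, coarse 1 um / fine 0.1 um over +/-15 um by
default); the TC of a phase-only object is minimal in focus.  The
minimizing `z` is assigned to the middle frame.

Numerical choices that proved necessary (each one traceable to a
controlled experiment in the development history):

* **Guarded sub-pixel registration.**  The spectral shift that registers
  an ROI is circular; a tapered 16-px guard band is cropped around the
  ROI, tapered to its mean, shifted, and trimmed, so neither wrap-around
  nor boundary ringing reaches the data.
* **Notch, not band-pass.**  Imperfect steps and registration leave
  residuals of the static scene at baseband and of the conjugate sideband
  at minus the carrier.  Both are notched out (0.2 cycles/px disks).
  Band-passing around the object sideband instead was measurably worse:
  it clips object signal the focus metric needs.
* **Fine carrier compensation.**  The carrier rarely falls on an integer
  FFT bin; after integer-bin re-centering the residual linear phase ramp
  is estimated from the mean phase gradient and divided out.  Without it
  the relative phase between the transmitted background and the scattered
  wave varies across the ROI and the TC minimum collapses to `z = 0`.
  The same compensation is applied in the conventional demodulator.
* **Sideband-resolved sign.**  A positive quarter step extracts the
  *conjugated* object wave, whose TC minimum appears at `-z`; a negative
  step extracts the direct wave.  The implementation decides by testing
  which of `+carrier` / `-carrier` the dominant sideband occupies, which
  stays correct even when the realized step is far from quadrature.
* **Quadrature-snapped spacing.**  The equivalent radius measured on a
  defocused hologram overestimates the true radius (a 6 um cell reads
  ~7.6 um), so the literal one-diameter rule `k = round(2R/(v dt))` can
  land the carrier step far from pi/2.  `select_triplet` therefore snaps
  `k` within +/-5 frames of the one-diameter value to the step closest to
  +/-pi/2 (`quadrature_window = 0` restores the literal rule).  The
  simulator's velocity helper (`stps_matched_velocity`) performs the
  complementary arrangement on the generation side.

Cells whose triplet cannot be formed — too slow, too close to the frame
edge for a padded 256-px ROI, or invisible in the hologram domain —
simply get no axial estimate; error statistics are computed over cells
with an estimate, mirroring per-triplet availability accounting.

A physical limitation worth stating: a *phase-only cell exactly in focus
is invisible in intensity*.  Near `z = 0` the hologram-domain detector can
miss cells entirely (the package's weak-phase failure-mode test
constructs exactly this), while the QPM-domain detector of the
conventional baseline still sees them.  Likewise, nearby cells whose
defocused patterns overlap merge into one hologram-domain detection.
Both behaviours are documented contracts, not defects to be fixed.

## Conventional baseline

`conventional_track` implements the reference pipeline: circular-aperture
Fourier filtering around the carrier peak (aperture = half the carrier
offset), inverse transform, least-squares phase unwrapping (Poisson solve
under Neumann boundaries via the DCT, followed by congruence rounding so
the output differs from the wrapped input by integer multiples of 2 pi
per pixel — exact for residue-free phases and fully vectorized, which is
why it was preferred over a pixel-by-pixel reliability sort), QPM-domain
detection with the same morphological chain, and per-track TC refocusing
of a complex ROI.  On the default scenarios it recovers positions to
0.003 um (x, y) and 0.05 um (z), which qualifies it as the oracle for the
proposed method's error analysis (`compare_tracks`).

## Problem sizes in the validation studies

The emulated instrument's full sensor is 1200 x 1920 px at 11618 frames;
the package's simulated studies run on a 600 x 960 px sensor with
videos of 100-120 frames and two cells each, which keeps one video below
a gigabyte in memory and a full multi-video study on a laptop scale while
preserving every optical parameter (wavelength, NA, magnification, pixel
pitch, frame interval, carrier).  Two cells per video places their
diffraction patterns ~43 um apart so that no neighbour enters a 256-px
STPS ROI; denser packings measurably contaminate the ROI differences
(the overlap failure mode above).  The axial-accuracy study accumulates
videos until at least 20 cells carry an axial estimate (~11-12 videos)
and reports the mean absolute error against ground truth; the acceptance
script (`scripts/acceptance.R`) reruns exactly this computation from
scratch under a caller-supplied seed.

## Known limitations

* First-order superposition: dense flows with overlapping diffraction
  patterns violate the simulator's model and the tracker's assumptions
  alike.
* The STPS field is a partial reconstruction; no quantitative phase can
  be read off it.
* Transverse drift during a triplet perturbs the realized carrier step
  (the x-carrier is near Nyquist); the axial scenario therefore keeps
  drift at zero, and drifting scenarios are used for the slope comparison
  only.
* The least-squares unwrapper degrades gracefully (but not exactly) in
  the presence of phase residues; residue counts are reported.
* Timing claims of the underlying approach are hardware-dependent and
  deliberately not asserted anywhere in the test suite.
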