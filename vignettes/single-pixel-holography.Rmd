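---
title: "Heterodyne single-pixel holography: model, simulation and reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterodyne single-pixel holography: model, simulation and reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holopix)
```

## The measurement model

Single-pixel holography images a complex-valued object
$O(\vec r) = A(\vec r)\,e^{i\phi(\vec r)}$ — $A$ the transmissivity in
$[0,1]$, $\phi$ the accumulated phase — with one bucket detector instead of
a camera. The object is decomposed on the orthogonal Hadamard basis
$H_n(\vec r)\in\{+1,-1\}$,

$$O(\vec r) = \frac{1}{\sqrt N}\sum_{n=1}^{N} a_n e^{i\varphi_n} H_n(\vec r),
\qquad
a_n e^{i\varphi_n} = \frac{1}{\sqrt N}\sum_{\vec r} O(\vec r)\,H_n(\vec r),$$

with $N$ the pixel count. Two experimental facts shape the computation:

1. **Binary-amplitude illumination.** A micromirror device can only display
   0/1 patterns $\tilde H_n = (H_n + H_1)/2$, which are *not* orthogonal.
   The fix is one linear identity per order, using the all-ones (DC)
   measurement:
   $$a_n e^{i\varphi_n} = 2\,\tilde a_n e^{i\tilde\varphi_n} -
     \tilde a_1 e^{i\tilde\varphi_1}.$$
   `dc_correct()` applies exactly this and nothing else.

2. **Phase stepping in time.** Offsetting the reference arm by a beat
   frequency $\Delta f$ makes the detector voltage oscillate as
   $\tilde a_n \cos(2\pi\Delta f\,t + \tilde\varphi_n)$ on top of a DC
   pedestal, so amplitude *and* absolute phase of each coefficient are read
   from a short time series while a single pattern is displayed — one
   pattern per coefficient, no phase-shifted pattern triplets.

The package simulates this chain end to end: `acquire()` synthesises the
digitised beat records, `batch_demodulate()` recovers
$\tilde a_n e^{i\tilde\varphi_n}$, `dc_correct()` moves to the orthogonal
basis, and `reconstruct_image()` inverts the transform.

## Conventions that fix the mathematics

* **Sequency ordering.** 1D Walsh rows are ordered by their number of sign
  changes (`walsh_sequency_matrix()`), the Hadamard analogue of spatial
  frequency; 2D bases are outer products of rows $u$ and $v$. The linear
  order $n$ enumerates $(u, v)$ along the *square sampling path*: expanding
  shells of $\max(u,v) = 0, 1, 2, \dots$, boustrophedon within each shell
  ($(0,k)\dots(k,k)$ then $(k,k-1)\dots(k,0)$). Any shell-complete
  traversal gives identical reconstructions at shell-aligned sampling
  ratios; the within-shell direction is our choice, made once.
* **Normalisation.** Symmetric $1/\sqrt N$ on both directions, so the
  transform is unitary, Parseval holds, and `fwht2()`/`ifwht2()` are the
  same self-inverse operation (the sequency Walsh matrix is symmetric).
  The butterfly runs in $O(N\log N)$.
* **Demodulation.** Three-parameter linear least squares per record —
  intercept plus the $\cos/\sin$ quadrature pair at the *known* $\Delta f$,
  on absolute timestamps. This is exact for noise-free records with integer
  cycles, needs no windowing at 20 samples per cycle, rejects any constant
  offset exactly, and degrades gracefully for fractional cycle counts
  (then each record is fit with its own absolute time grid; with integer
  cycle locking one shared pseudoinverse serves every record). The
  convention `coeff = (c_cos - i c_sin) / (2 gain)` is the single place the
  $e^{+i\omega t}$ sign is fixed; synthesis followed by demodulation is the
  identity.
* **Phase is always wrapped** to $(-\pi, \pi]$ and never unwrapped,
  matching how holographic phase images are displayed; all phase metrics
  use circular means and phase *differences*, since a heterodyne system
  carries an arbitrary global phase from the reference arm.

## Acquisition defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `beat_freq` | 62,500 Hz | difference of the two arm frequency shifts; 16 us period |
| `sample_rate` | 1.25 Ms/s | digitiser rate; 20 samples per beat cycle |
| `refresh_time` | 48 us | display time per pattern; 3 beat cycles, 60 samples |
| `noise_rel` | 0.001 | noise std as a fraction of the measured value (0.1%) |
| `dc_reference` | 1 | reference-arm intensity pedestal (arbitrary units) |
| `gain` | 1 | interference scaling; cancels up to a global factor |

`refresh_time * beat_freq` should be an integer ("cycle locking"); a
fractional value is accepted with a warning and handled correctly through
absolute timestamps. The Nyquist bound `beat_freq <= sample_rate / 2` is
enforced. The absolute interference scale is not physically meaningful
here, so `gain = 1`; reconstruction fidelity metrics are scale- and
global-phase-invariant where appropriate.

The forward model deliberately includes a *pattern-dependent* DC term (the
transmitted intensity $\sum_r |O \tilde H_n|^2$, same $1/\sqrt N$
normalisation) so that demodulation must genuinely reject a varying
pedestal, not just a constant one. Noise is multiplicative Gaussian — the
stated noise magnitude is a relative standard deviation and Gaussian is the
conventional detector model; photon statistics and detector bandwidth
roll-off are out of scope. There are no settling samples between patterns.

## Compressive sensing by zero-filling

The sampling ratio SR is the number of measured coefficients over the
number of reconstructed pixels. A measurement keeps the first
$\lceil \mathrm{SR}\cdot N\rceil$ orders of the square path (lowest
spatial frequencies); reconstruction zero-fills the rest and applies the
same inverse fast transform — no iterative solver. Consequences worth
knowing:

* the noise-free $L_2$ reconstruction error equals the energy of the
  dropped coefficients, hence is non-increasing in SR;
* resolution degrades roughly with $\sqrt{\mathrm{SR}}$ (the kept square in
  sequency space has side $\approx$ `side` $\cdot\sqrt{\mathrm{SR}}$);
* under measurement noise, high-order coefficients carry little signal but
  full noise, so a *moderate* SR often yields a higher contrast-to-noise
  ratio than a large one — the simulation reproduces this regime at 0.1%
  noise on bar targets.
* DC-record noise has one conspicuous signature: the correction subtracts
  $\tilde a_1$ from every order, so its noise lands coherently on the one
  pixel where all Walsh patterns are $+1$ (the image corner), not spread
  across the field.

## Phantoms — what they emulate and what they do not

`bar_target()` builds positive three-bar elements with USAF geometry (bar
width $w$, length $5w$, gap $w$); `phase_step_target()` is a unit-amplitude
object with a two-level phase (nominal step 1.795 rad in the quantitative
phase-target configuration); `tissue_phantom()` is a seeded smoothed
Gaussian random field with controllable amplitude contrast, phase range and
correlation length — low amplitude contrast plus rich phase emulates
unstained tissue, higher amplitude contrast emulates stained sections.

These phantoms exercise the *computational* chain: pattern projection,
beat-signal encoding, demodulation, basis correction, compressive
truncation. They do not model diffraction or defocus between modulator and
sample (the 4f relay images one onto the other, and the method needs only
the spatial sum of the transmitted field), speckle, sample scattering, or
partial light collection — so passing tests validate the measurement
mathematics, not optical image formation in real tissue.

## System geometry calculators

`derive_geometry()` turns hardware constants into the mode table:
`res_x = diag_factor * binning * mirror_pitch * (f_rear / f_front)`,
`res_y = anisotropy * res_x`, FOV = `n_super` resolution elements per axis,
and throughput `sbp_t = 2 / refresh_time` (amplitude and phase both count),
independent of lens pair and binning. The $\sqrt 2$ diagonal factor and the
y/x anisotropy (default $43.1/58.0 \approx 0.743$) are configuration
constants standing in for the 45-degree diagonal mounting of the mirror
device; the anisotropy is numerically close to the cosine of the blaze
diffraction angle, but we do not assert that relation. With the defaults
this yields 58.0 x 43.1 um resolution and a 14.86 x 11.04 mm field — note
the y figure prints as 11.0 mm at three significant figures while the
quoted mode table says 11.1 mm, an inconsistency of rounding in the source
constants that we keep visible rather than tune away; the x-direction pair
is the anchored one. `timing_report()` gives the beat/sampling budget: 3
cycles and 60 samples per pattern, and 3.146 s for a full 65,536-pattern
acquisition.

## Numerical choices and degenerate inputs

* Order 1 (the DC pattern) is mandatory in every sampling plan and every
  demodulated set — the basis correction is undefined without it.
* The least-squares design is rank-checked; a (numerically) zero beat
  frequency raises a degenerate-fit error rather than returning nonsense.
* Records need at least 3 samples (3 parameters); amplitude rasters are
  validated into $[0,1]$ on read, phase rasters are wrapped with a warning.
* Phantom generators and the noise stream are seeded (`withr::with_seed`),
  so every pipeline run is bitwise reproducible for a fixed seed.
* Float TIFF output is written by a minimal single-strip 32-bit IEEE
  writer, because phase rasters hold radians and must not be quantised or
  clamped to $[0,1]$; reading goes through libtiff.

## Problem sizes used in the test suite

Unit and property tests run on sides 2–64, where brute-force oracles
(explicit basis projection, per-record fits) are cheap and exact; the
end-to-end suite includes one full-scale side-256 acquisition — 65,536
patterns of 60 samples — which exercises the fast-transform path and the
shared-pseudoinverse demodulation at the size the system actually runs,
in a few seconds. Noise-regime checks (CNR versus sampling ratio) use ten
seeded repeats at side 64, enough for a stable majority without burning
minutes. These sizes are the package's choice of a thorough-but-quick
default; all generators scale to larger sides with the same code path.

## Known limitations

* Zero-filled inverse transform only; no iterative or learned
  reconstruction.
* No optical propagation model (defocus, diffraction, speckle,
  aberrations); the anisotropy of the resolution is imposed, not derived
  from the mirror-tilt geometry.
* The exact within-shell ordering of the reference square path is not
  public; ours matches its low-to-high-frequency structure and is identical
  at shell-aligned sampling ratios.
* Absolute radiometry (laser power, responsivity) is not modelled; `gain`
  and `dc_reference` are arbitrary units.
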