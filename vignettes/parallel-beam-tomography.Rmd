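---
title: "Parallel-beam slice tomography with tomoslice: models, operators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel-beam slice tomography with tomoslice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomoslice)
```

# The problem

A parallel-beam tomography experiment measures, for each rotation angle
$\theta$ and detector coordinate $t$, the attenuation line integral

$$p(\theta, t) = \int_{x\cos\theta + y\sin\theta = t} f(x, y)\, dl,$$

where $f$ is the attenuation coefficient of one slice of the sample. What
the detector actually records is raw counts corrupted by the source
profile, detector gain structure, dark current, stray high-energy events
("zingers"), and — for partially blocked samples such as one inside a
diamond anvil cell — a missing wedge of angles. `tomoslice` implements the
full slice workflow: correction of those effects, estimation of the
rotation center, and a suite of analytic and iterative reconstruction
algorithms behind one dispatch function, plus a plugin registry so that
user-written solvers dispatch exactly like built-ins.

All angles are radians in memory and degrees on disk and at the command
line. Detector bins and pixels are indexed 0-based in user-facing
coordinates (centers, offsets); bin $j$ of a detector with rotation center
$c$ sits at $t_j = (j - c)\,\Delta_d$. The image raster is centred on the
rotation axis.

# Pre-processing model

**Normalization.** With per-pixel flat-field mean $\bar F$ and dark-field
mean $\bar D$, transmittance is $T = (I - \bar D)/(\bar F - \bar D)$,
clipped to $[\varepsilon, \mathrm{cutoff}]$ with $\varepsilon$ the
smallest positive normal double. The cutoff defaults to 1 (absorbing
samples); values above 1 are legitimate for propagation-enhanced data.
Beer–Lambert then gives $p = -\ln T$. If the flat fails to exceed the dark
on more than 1% of pixels the data are rejected with the measured
fraction, rather than silently producing garbage.

**Zingers** are replaced by the local 2-D median when the ratio to that
median exceeds a threshold; a ratio (not a difference) keeps the test
exposure-independent. The operator is idempotent: pixels at or below the
threshold are never touched.

**Ring artifacts.** Detector columns whose gain differs between the flats
and the scan leave angle-constant stripes in the sinogram that reconstruct
into rings. The wavelet–Fourier filter decomposes the sinogram; at each
level the band that is high-pass along the detector axis and low-pass
along the angle axis condenses the stripes, and its FFT along the angle
axis is damped by $g(k) = 1 - e^{-k^2/(2\sigma^2)}$, removing the
stationary component. Two facts drove the defaults
(`sym8`, 5 levels, $\sigma = 2$):

* white per-column stripes carry a fraction $2^{-L}$ of their energy below
  the depth-$L$ detail scales, so the achievable column-mean suppression
  is about $1 - \sqrt{2^{-L}}$ minus band leakage — depth is what removes
  stripes, $\sigma$ mainly protects moving structure;
* any object of finite width has *angle-static* detector detail at deep
  scales (a Gaussian profile of 45-pixel width keeps roughly 9% of its
  amplitude in the level-6 band), which the filter cannot distinguish from
  a broad stripe. Depth beyond the feature scale therefore buys stripe
  suppression at the price of background distortion. Five levels with the
  comparatively long `sym8` filter (sharpest band split implemented)
  measured best on both sides of this trade-off.

Internally the sinogram is extended mirror-periodically before the
periodic wavelet transform; without this, the jump between the left and
right detector edges masquerades as angle-static detail and is damped,
distorting the result. Sinograms whose features linger near a detector
position (every sinusoidal trajectory has turning points) are still
distorted slightly there; this is inherent to the method, not a tuning
failure.

**Phase retrieval.** Single-distance Paganin filtering assumes a
homogeneous object ($\delta/\beta$ constant) and retrieves projected
thickness
$t = -\mu^{-1} \ln \mathcal F^{-1}\!\left[\mathcal F[T] / (1 + (z\delta/\mu)k^2)\right]$
with $\mu = 4\pi\beta/\lambda$ and $k^2 = 4\pi^2(u^2 + v^2)$ in physical
units set by the pixel size. Published variants differ by $4\pi$ factors;
this convention is pinned by two exact identities that the tests assert:
the filter's DC gain is 1, and $\delta \to 0$ degenerates to
$-\ln(T)/\mu$. Projections are padded symmetrically to powers of two;
non-positive filtered values are floored at $\varepsilon$ and counted.

**Rotation center.** The entropy search reconstructs the slice for a grid
of trial centers and keeps the one minimizing the Shannon entropy of a
256-bin histogram taken over the robust 1st–99th percentile range;
miscentring spreads mass into arcs and raises entropy. Ties break toward
the smaller center; an optional refinement pass repeats at a tenth of the
step.

# Projectors

Both discretizations are built from one weight enumeration shared by the
forward and the backward direction, so the adjoint identity
$\langle Ax, y\rangle = \langle x, A^{T}y\rangle$ is structural (the dot
test passes at $10^{-10}$ by construction, not by calibration):

* **strip** — exact area of the pixel/strip intersection divided by the
  bin width. The footprint of a square pixel on the detector axis is a
  trapezoid whose CDF is evaluated in closed form.
* **line** — Joseph's kernel: rays at bin centres, stepping along the
  dominant axis with linear interpolation transverse, weighted by the
  step length.

Rays are cast at detector bin centres; a fractional rotation-center offset
displaces the detector, never the image, so no sinogram interpolation
happens anywhere. `as_matrix()` assembles the identical weights as a
sparse matrix (guarded at $10^7$ potential entries) and is the basis of
the dense oracles in the test suite. The `cuda` kernel name is recognized
and rejected: this build is CPU-only by scope.

# Reconstruction suite

**FBP.** Rows are zero-padded to at least twice the detector length (next
power of two), multiplied in the frequency domain by the DFT of the
classical band-limited ramp kernel
($h_0 = 1/(4\Delta_d^2)$, $h_n = -1/(\pi^2 n^2 \Delta_d^2)$ for odd $n$)
times the chosen window (`ram-lak`, `shepp-logan`, `cosine`, `hamming`,
`hann`), and backprojected with per-angle trapezoidal weights. Those
weights extend the boundary gaps one step so a uniform half-turn list
reduces exactly to the textbook $\pi/N$; non-uniform lists need no special
casing. Amplitude calibration is fixed by the analytic unit disk (interior
mean 1), not by matching any external implementation.

**Gridrec.** The Fourier-slice path: each filtered projection spectrum
samples the 2-D spectrum along a diametral line; samples are spread onto a
2× oversampled Cartesian grid through a width-7 separable Kaiser–Bessel
kernel (shape $\beta$ from the standard oversampling prescription), with
polar density compensation $|f|\,df\,d\theta$; one inverse 2-D FFT and
division by the kernel's closed-form transform (including its absolute
gain, which keeps the amplitude calibrated) yield the slice. The radial
spectrum is sampled at four times the detector length so interpolation
error stays below the window roll-off. Two numerical details matter: the
$f = 0$ polar cell carries the mean of $|f|$ over its own half-width
($df/8$) — dropping it loses the image DC entirely — and the center
offset enters as a frequency-domain phase ramp. The residual few-percent
difference from FBP is dominated by the strip backprojector's
pixel-footprint smoothing, which the pure-Fourier path does not share;
the two agree within 5% relative RMS on the Shepp–Logan phantom, the
"usually similar" regime expected of these two analytic methods.

**SIRT.** $x_{k+1} = \mathrm{clamp}(x_k + C A^T R (b - A x_k))$ with $R$,
$C$ the reciprocal row/column sums (zero-guarded), $x_0 = 0$, optional
bounds applied each sweep. With full column rank it converges to the
row-sum-weighted least-squares solution; the tests verify this against a
dense solve on a 16×16-pixel, 24-angle system. These systems have
condition numbers around $10^6$, so convergence of components along the
smallest singular vectors is slow; the oracle uses a smooth consistent
target, for which 2000 iterations reach $10^{-3}$ relative error.

**CGLS.** Textbook conjugate gradient on the normal equations, zero
start, no constraints, early exit with a message on a vanishing direction
norm. Exact arithmetic would finish in `n_pixels` iterations; at the
oracle system's conditioning, finite precision needs roughly 2–3× that to
pass $10^{-6}$, and the residual-monotonicity property is asserted
separately over 100 iterations on noisy data.

**ML-EM / OSEM.** Multiplicative Poisson EM from a uniform positive
start, $\varepsilon$-guarded divisions, subsets as round-robin interleaved
angle blocks. One subset reduces bit-for-bit to classical ML-EM (the test
compares against an independently hand-rolled loop). A subset design in
which some pixel is seen by only part of the subsets is rejected rather
than silently biased. The Poisson log-likelihood is verified
non-decreasing over 50 iterations.

**FISTA-TV (reference plugin).** Minimizes
$\frac12\|Ax - b\|^2 + \lambda\,\mathrm{TV}(x)$ (isotropic TV, reflective
boundaries). The Lipschitz constant comes from 20 power iterations on
$A^TA$ with a 5% safety factor, started from a fixed deterministic vector
so results are bit-reproducible; the TV proximal step runs a Chambolle
dual iteration (step $1/8$, 20 inner iterations by default); momentum is
the standard $t_{k+1} = (1 + \sqrt{1 + 4t_k^2})/2$ extrapolation. FISTA is
not monotone — the tests assert the *running minimum* of the objective is
non-increasing, which is the honest invariant.

**Dispatch.** `recon()` builds the scan geometry from the data shape,
angles and center, translates it to the projector-level form
(`center_offset = center - (n_det - 1)/2`, an exact bijection), and hands
each slice independently to the named algorithm or registered plugin —
switching methods is a one-argument change. `gpu_list` is accepted and
ignored with a single warning; `art`, `bart`, `sart`, `pml`, `ospml`
raise a clear out-of-scope error rather than a generic unknown-name one.

# The synthetic data generator

`simulate_counts()` emulates what the real acquisition chain does to a
clean sinogram $p$: ideal counts $I_0 e^{-p}$; per-column lognormal gains
shared by flats and data *plus an independent lognormal drift applied to
the data only* — the component that flat-field normalization cannot
remove and therefore the mechanism behind ring artifacts; optional Poisson
noise; zingers as multiplicative spikes on raw counts (they are detector
events, so they hit counts, not line integrals); a constant dark floor.
All randomness flows through one seeded generator, so a dataset is
bit-reproducible from its seed, and the generator restores the caller's
RNG state.

`make_limited_angle_dataset()` reproduces the wedge-blocked acquisition
of the motivating experiment: a half-turn list at 0.5° spacing
(endpoint excluded, final angle dropped to give the canonical 359
projections ending at 179°), with every angle above 136° blocked —
leaving 273 usable projections and 86 blocked. Defaults:
$I_0 = 10^4$ counts, 10 flats, 10 darks, dark level 10 counts, Poisson
noise on; ring gain and zinger rates default to zero and are switched on
explicitly where a test exercises them (0.02 lognormal sd and $10^{-4}$
per pixel respectively, values chosen to be clearly visible above the
Poisson floor at $I_0 = 10^4$ without dominating the data). The spec of
the emulated experiment prints a "137° range" alongside "273 projections
at 0.5°"; those two statements are mutually inconsistent (273 steps of
0.5° span 136°), and the package follows the self-consistent
359 − 86 = 273 arithmetic.

What the generator does *not* emulate: wave-propagation/Fresnel fringes,
detector point-spread blur, beam hardening, scatter. Passing tests on
these phantoms therefore demonstrate algorithmic correctness on the
stated corruption model, not end-to-end fidelity to any particular
beamline.

# Problem sizes and numerical choices

The test and acceptance workloads run on deliberately modest sizes chosen
as the smallest at which each property is cleanly exhibited: analytic
reconstruction accuracy at $256^2$ with 360 angles, the limited-angle
comparison at $128^2$ with the full 273-angle wedge geometry, dense-matrix
oracles at $16^2$ with 24 angles (552 rays), center search at $128^2$.
Divisions are guarded at the smallest positive normal double throughout;
guarded events are counted and reported rather than hidden. Ties in the
center search break toward the smaller center; angle lists are half-open
by default so 0 and $\pi$ never coincide.

# I/O and configuration

Datasets travel in a data-exchange-style HDF5 layout (`exchange/data`,
`exchange/data_white`, `exchange/data_dark`, `exchange/theta` in degrees;
simulator ground truth under a separate `truth/` group that standard
readers ignore). Angle conversion happens only at the I/O boundary.
Reconstructions are written as one single-strip 32-bit IEEE float TIFF
per slice; the writer is implemented in-package because raster-oriented
TIFF writers clamp to the display range [0, 1], which is meaningless for
physical attenuation values, and files are read back through libtiff as
an independent implementation. Configuration files are flat-key YAML
mirroring the command-line flags; explicit flags win over the file. The
`tomoslice` script under `inst/scripts/` is a thin launcher over
`run_cli()`; every subcommand is a shell over exported functions, so
nothing is computable only from the command line.

# Known limitations

* Parallel-beam, single-slice geometry only — no fan/cone/helical beams,
  no fully 3-D regularization coupling slices.
* The ring filter removes genuinely angle-static detector structure at
  scales up to $2^{n_\mathrm{levels}}$ pixels; samples with strong static
  fine structure need a shallower depth.
* Gridrec assumes approximately uniform angles (it warns otherwise);
  strongly non-uniform lists should use FBP, whose trapezoidal weights
  handle them exactly.
* The iterative solvers expose no stopping rule beyond the iteration
  count; convergence monitoring is the caller's job (DEBUG logging
  reports residuals where available).
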