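---
title: "Quantifying cilia-driven flow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cilia-driven flow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaflow)
```

## The measurement problem

Respiratory cilia move the airway mucus layer by beating in a coordinated,
wave-like fashion. Standard high-speed video-microscopy of nasal brushing
samples quantifies the motion of the cilia themselves — beat frequency,
amplitude, pattern — but says nothing about how much fluid that motion
actually transports. `ciliaflow` implements a micro-bead-tracking (MBT)
analysis that closes this gap: polystyrene micro-beads suspended with the
sample act as flow tracers, their velocity profile above the ciliated edge
is fitted, and the wall shear stress

$$\tau_w = \frac{2 \mu U_w^*}{h}$$

is extracted as a single global index of ciliary beating efficiency. Here
$U_w^*$ is the bead velocity extrapolated to the ciliated wall, $h$ the
x-intercept of the fitted profile (the height above which the fluid is
effectively stagnant) and $\mu$ the dynamic viscosity (default
$10^{-3}$ Pa s; the survival medium is essentially water). With $U_w^*$ in
um/s and $h$ in um the index lands in the millipascal range.

The package has five parts: a synthetic movie generator with known ground
truth, ciliary beat analysis, bead tracking, an envelope-model Stokes flow
simulator, and the profile fit / index / statistics layer.

## Ciliary beat analysis

**Beat frequency (CBF).** Two estimators that should agree. `cbf_fft()`
resamples the operator polyline (5 points, 4 segments) at one-pixel
curvilinear steps, averages the grey level per frame, and takes the
highest-power FFT frequency within a physiological search band (default
0.5–30 Hz, excluding DC; observed beat frequencies span roughly 3.5–15 Hz).
Resolution is `frame_rate / n_frames` (about 0.2 Hz for the reference
1800-frame, 358 fps acquisition). A peak must exceed `flatness_k` (default
10) times the median in-band power; otherwise the movie has no dominant
frequency and an error is raised rather than a junk estimate.
`cbf_kymograph()` instead stacks the resampled line over all frames,
averages the temporal autocorrelation over kymograph columns, and converts
the dominant positive-lag peak into a period. The integer-lag quantisation
(e.g. 358/26 vs 358/25 Hz around a 14 Hz beat) is removed by quadratic
interpolation around the peak.

**Beat amplitude (CBA).** From three operator landmarks — cilium base
`P0`, tip before the effective stroke `P1`, tip before the recovery stroke
`P2` — the amplitude is the tip excursion $|P_1 P_2|$ and the cilium length
is taken as the mean of $|P_0P_1|$ and $|P_0P_2|$ (the two tip positions
need not be exactly equidistant from the base; the mean is the obvious
symmetric choice, which the source material leaves unspecified).

**Metachronal wavelength.** 104 segments of 24 pixels are laid
perpendicular to the wall at equal curvilinear spacing, centred on the
polyline. Each segment's mean grey oscillates at the CBF; its phase is the
argument of the FFT coefficient at the CBF bin. Phases are unwrapped along
the curvilinear abscissa *before* the linear regression
$\theta(x) = p\,x + c$, and $\lambda = 2\pi/|p|$. Using $|p|$ makes the
estimate invariant under reversal of the polyline orientation. Two failure
modes are reported explicitly: a phase span below 0.1 rad (all segments in
phase — the wavelength is effectively infinite) and a regression $R^2$
below `min_r2` (default 0.8, miscoordinated edges). A constant phase
offset common to all segments — e.g. the spectral-leakage phase rotation
of an off-bin beat frequency — cancels in the slope, which is why the
estimator needs no windowing.

**Cilia density.** Cilia appear darker than the background. The density
$\rho_c$ is the fraction of cilia-zone pixels of the *time-averaged* frame
darker than the mean background-zone grey (which frame to use is not
specified by the source protocol; the temporal average is the least noisy
choice and is what the synthetic generator is tested against). Under a
homogeneous model of parallel cilia of diameter $e_c$ (0.2 um) separated
by gaps $d_c$, $\rho_c = e_c/(e_c + d_c)$, so the gap length is
$d_c = e_c(1-\rho_c)/\rho_c$ and the uncovered fraction $f_c = 1-\rho_c$.
The estimator is invariant under affine grey rescaling applied to both
zones.

## Bead tracking

Frames are thresholded (beads darker than threshold, default 80 with an
Otsu fallback), connected components labelled (`EBImage::bwlabel`), and
components kept inside area gates bracketing a 4.5 um bead
($\pi \cdot 2.25^2 \approx 15.9$ um², default gates 8–32 um²). Components
touching the image border are discarded: a clipped disc has a biased
centroid, which would otherwise drag the mean track speed down by around a
percent. Centroids are darkness-weighted for sub-pixel accuracy on
anti-aliased discs.

Linking is greedy nearest-neighbour frame-to-frame with a distance gate
(default 3 um): at 358 fps even the fastest observed beads (~254 um/s)
move under a micrometre per frame, so global assignment would add
complexity without changing the result. Ties are broken deterministically
by lowest track index, then detection index, making the linking invariant
to detection input order. There is no gap closing; a missed detection ends
the track.

Kinematics are forward differences times the frame rate, decomposed into
components parallel and perpendicular to the *nearest* edge segment;
distance to the edge is the minimum point-to-segment distance over the 4
segments. Selection keeps tracks that are straight — total-least-squares
line fit with $R^2 \ge 0.9$; "straight trajectories" is all the protocol
prescribes, the numeric floor is this package's choice — and essentially
parallel to the edge, $|\bar u_y| \le 0.25\,|\bar u_x|$, the 25% threshold
under which nearly all observed beads fall. Every rejection is labelled
with the failed criterion.

## The envelope flow model

The discrete cilia are replaced by a continuous material envelope covering
the cilia tips. The tip anchored at abscissa $\xi$ follows an elliptic
orbit with metachronal phase:

$$X = \xi - a\cos(\omega t - k\xi), \qquad Y = \beta a \sin(\omega t - k\xi),$$

with $2a$ = CBA, $\omega = 2\pi\,\mathrm{CBF}$, $k = 2\pi/\lambda$ and
$\beta$ the ellipse ratio (default 0.14, the observed mean; $\beta > 0$
orbits clockwise). The wave travels towards $+x$ by default and the
direction is configurable; the phase convention itself is a package choice
since only the orbit equation is prescribed by the source model.

The envelope velocity drives an incompressible Stokes flow in the strip
$0 \le y \le h$, x-periodic in $\lambda$, with boundary data linearized
onto the mean line $y = 0$ (the classical swimming-sheet treatment — the
envelope amplitude is not small compared to $\lambda$ for real edges, so
this is a modelling idealization, not an asymptotic guarantee). At $y = h$
the fluid is stagnant: $u = v = 0$ *and* zero shear for the steady part
(no momentum flux into the dead zone). At $y = 0$ a porous-wall condition
applies: Navier slip of length $\phi$ on the tangential component,

$$u - \phi\,\partial_y u = u_w, \qquad v = v_w,$$

with the normal component matched exactly (kinematic condition). The slip
length encodes the partial momentum transfer of a partially covered wall
and is tied to the measured cilia density by
$\phi = \Lambda (1-\rho_c)^2/\rho_c$ with $\Lambda = 750$ um: dense cilia
($\rho_c \to 1$) recover no-slip, sparse cilia slip almost freely. The
source model prints its slip condition in vector form; we prototyped both
and kept the tangential-slip/impermeable form, which is the standard
porous-wall (Beavers–Joseph-type) convention the model invokes by analogy
— the vector form additionally damps the normal boundary motion and, in
the slip-dominated regime covering most observed densities, inverts the
sign of the wavelength sensitivity of the transport, contradicting the
regression signs established from the bead data.

**Numerical scheme.** The boundary data is a single travelling harmonic,
so the oscillatory field is closed-form once four complex coefficients are
solved: the stream function is
$\psi = \mathrm{Re}\,[f(y)\,e^{i(\omega t - kx)}]$ with biharmonic
$f(y) = (A + By)e^{-ky} + (C + Dy)e^{k(y-h)}$ (the second pair scaled by
$e^{-kh}$ so the 4×4 boundary system stays well-conditioned for
$kh \sim 100$). Residuals of the top boundary, the slip condition and the
divergence are checked on a grid and sit at machine precision, far below
the contractual $10^{-6}$.

**Steady transport.** A linear oscillatory field time-averages to zero;
the net transport observed on beads is second order in the envelope
amplitude. Expanding the boundary condition from the moving envelope onto
the mean line yields a steady effective wall velocity
$U_{\mathrm{eff}} = -\langle \Delta x\,\partial_x u_1 + \Delta y\,
\partial_y u_1\rangle|_{y=0}$ (products of harmonics averaged as
$\tfrac12\mathrm{Re}\,P\bar Q$). In the pure-transverse, no-slip,
deep-channel limit this reduces exactly to Taylor's swimming-sheet drift
$\tfrac12 \omega k b^2$, which the tests verify numerically.
$U_{\mathrm{eff}}$ drives the steady strip profile
$U_0 (1-y/h)^2$ — the unique unidirectional Stokes flow with zero
velocity and zero shear at $y=h$ — with $U_0 = U_{\mathrm{eff}}/(1 +
2\phi/h)$ from the slip condition. Its wall shear is exactly
$2\mu U_0/h$: the parabola and the factor 2 in the index are two faces of
the same stagnant-interface assumption (a Couette profile with the same
wall velocity and gap gives half the stress, `couette_stress()`).

**Tracers.** Bead Stokes numbers are $\mathcal{O}(10^{-4})$
(`stokes_number()`, $(2/9) R^2 \rho_b \omega / \mu$), so beads are
advected as massless tracers: $\dot X = u(X, t)$, integrated with LSODA
(relative tolerance $10^{-8}$) with root-stopping at $|x| = L_w$. The
effective velocity is $V_{\mathrm{eff}}(y_0) = L_w/\tau(y_0)$, exactly the
observable measured on real beads. Lagrangian Stokes drift of the
oscillatory part is thereby captured without ever forming a second-order
Eulerian field; it decays like $e^{-2ky}$ and only matters within a few
micrometres of the wall. Tracers that leave the strip or exceed a time
cap are reported as errors ("stalled tracer"), not silently clipped.
Transport direction depends on the slip regime (it reverses around
$\phi \sim 10$ um for typical parameters); profiles are reported as speed
magnitudes with the direction attached as an attribute, matching how bead
speeds are measured.

The simulator is contract-level: the full flow solution of the companion
analytical model is out of scope, and no magnitude agreement with measured
$U_w^*$ values is claimed. What is asserted — and tested — is the
observable structure: machine-precision boundary residuals, effective
velocity non-increasing with altitude, a parabolic fit whose x-intercept
recovers the configured $h$ within 10%, and transport sensitivities
(+CBF, +CBA, +$\rho_c$, −$\lambda$, −$y_0$) matching the signs of the
empirical regression across a factorial sweep of the observed parameter
ranges.

## Profile fit, index and statistics

`fit_parabola()` fits $V(y) = U_w (1 - y/h)^2$ by Levenberg–Marquardt
(`minpack.lm`), started from the exact quadratic regression
reparametrisation, honouring inverse-variance weights when the samples
carry them. An all-zero profile is flagged degenerate ($U_w = 0$, $h$
indeterminate) instead of being fitted. `shear_stress()` then evaluates
$2\mu U_w/h$ in mPa; the chain is scale-covariant (scaling all velocities
by $c$ scales $\tau_w$ by $c$).

Patient-level aggregation uses the arithmetic mean and the *sample*
($n-1$) standard deviation — validated against the reference per-edge
table, where the population-SD alternative fails to reproduce the
reported spread (3.6 vs 4.1 mPa for the first patient). One edge of that
table reports an index inconsistent with its own $(h, U_w^*)$ inputs (an
apparent transcription error); `check_edge_consistency()` flags it and it
is excluded from numeric agreement checks.

The statistical layer mirrors the original analysis: OLS regression of
bead velocity on CBF, $\rho_c$ (as a fraction), CBA, $y_0$ and $\lambda$
with intercept; a Mann–Whitney U comparison of bead velocities split at
the median edge distance (exact null for combined $n \le 20$ without
ties, normal approximation with tie correction above — the exact-test
convention is verified against brute-force enumeration over all rank
assignments); and Bland–Altman agreement (bias ± 1.96 SD limits).
`per_cilium_force()` divides $\tau_w$ by an areal cilia density (about
5/um²) and deliberately returns a caveat flag: spreading a steady wall
stress uniformly over cilia is not comparable to oscillatory
single-cilium force measurements, and the conversion behind published
per-cilium figures is not fully specified.

## The synthetic generator, and what passing tests do not show

`generate_movie()` emulates the reference acquisition (358 fps, 1800
frames, 256×192 px at 0.32 um/px): a cilia band extending one cilium
length (6 um) from the polyline on the bead side, in which an exact
fraction $\rho_c$ of pixels (seeded RNG) oscillates sinusoidally at the
CBF with spatial phase $2\pi s/\lambda$, sitting half a modulation depth
below the background on time average; beads as anti-aliased discs (8×8
sub-pixel area coverage, sub-0.05 px centroid accuracy) advected parallel
to the edge at $U_w(1-y_0/h)^2$; optional i.i.d. Gaussian pixel noise,
clipped and quantised to 8 bits. Movies are bit-identical given the seed.

The generator deliberately renders no individual cilia, no optical PSF,
no mucus, and a geometrically perfect phase gradient. Recovery tests on
its output therefore demonstrate the *correctness of the estimators under
their own assumptions* — that the pipeline inverts the generative model —
not robustness to out-of-focus edges, uneven illumination, bead–bead
interactions or miscoordinated beating, which real recordings exhibit.
The two built-in failure examples (flat spectrum, in-phase segments) probe
the error paths, not that robustness.

Profile-recovery studies use velocity noise proportional to the local
velocity (SD 10% of $V(y)$) with inverse-variance weights. With 10
altitudes, an *absolute* noise floor of 10% of $U_w$ makes the
x-intercept statistically unidentifiable at the 5% level — the Cramér–Rao
bound on $h$ sits near 8% for any altitude grid — which is why the
heteroscedastic model, the one under which per-bead mean velocities are
actually acquired, is the study condition.

## Problem sizes and runtime choices

Unit tests run on reduced movies (typically 400–600 frames of 128×192 px)
where the quantity under test does not depend on the acquisition length;
the end-to-end parameter-recovery test uses the full reference geometry
(1800 frames, 256×192 px). The profile recovery study uses 1000
replicates; the simulator sweep uses a $2^4$ factorial at two altitudes
with a 10–20 um observation window (crossing time, not window length,
sets the integration cost). Tie-breaks, tolerances and thresholds quoted
above are all configurable arguments with the stated defaults.

## Known limitations

* The flow solver is first-order in boundary data plus second-order
  steady streaming; it is not the companion analytical solution, and
  simulated magnitudes should not be compared to measured $U_w^*$.
* Density estimation assumes the background zone is representative;
  passing beads darken it slightly in long movies.
* The kymograph CBF assumes a quasi-stationary beat over the recording.
* No gap closing in tracking: occlusions fragment tracks rather than
  corrupt them.
* The per-cilium force conversion is intentionally naive and flagged.
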