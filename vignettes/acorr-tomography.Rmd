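---
title: "Inherently aligned multi-view tomography by auto-correlation inversion"
author: "AcorrTomo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inherently aligned multi-view tomography by auto-correlation inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AcorrTomo)
```

## The problem

Multi-view light-sheet fluorescence microscopy images a specimen at several
rotation angles to compensate for the anisotropic resolution of a single
acquisition: the point-spread function (PSF) is elongated along the scanning
(z) axis, so each view resolves best in its own lateral plane. Before the
views can be averaged into one volume, each must be registered against a
reference — a step that is error-prone at the voxel level and expensive at
sub-voxel accuracy.

This package implements an alternative fusion route that removes
registration altogether. The auto-correlation of a volume,

$$\mathcal{A}\{v\} = v \star v,\qquad (a \star b)(\xi) = \sum_y a(y)\,b(y+\xi),$$

is invariant to any rigid translation of $v$: all per-view misalignment is
carried by the Fourier phase, which the auto-correlation discards. Averaging
the per-view auto-correlations therefore produces a fused, *inherently
aligned* measurement $\bar\chi_\mu$, and the object is recovered by
inverting it — a problem in the phase-retrieval family, since $\bar\chi_\mu$
fixes the Fourier modulus but not the phase. The solution is defined up to
the ambiguity group of that problem: a global translation and a global
point reflection (flip). All comparison metrics in the package
(`recoveryScore`, `alignToTruth`) score over that group.

## Forward model and fusion

A view at angle $\varphi_i$ is modelled as $o_\mu^{\varphi_i} = o * h^{\varphi_i}$
(noise-free by default; Gaussian/Poisson noise models exist to stress-test).
The PSF $h$ is an anisotropic Gaussian elongated along z with
$\sigma_\text{scan} \ge \sigma_\text{lat}$; rotating the sample is
equivalent, after rotating each stack back to the reference orientation, to
blurring the fixed object with the rotated kernel $h^{\varphi_i}$.
`simulateViews()` offers both forward paths:

* `"rotate_psf"` (default): blur the unrotated phantom with the analytically
  rotated Gaussian. No interpolation touches the object, so algebraic
  invariants (e.g. exact shift invariance of the fused auto-correlation) can
  be tested bit-for-bit.
* `"rotate_object"`: rotate the phantom (cubic-convolution or bilinear
  interpolation), blur with the angle-0 kernel. This is the path real data
  follow, and the two paths are cross-checked against each other in the test
  suite (exactly at 90°, where rotation is a grid permutation; to
  interpolation tolerance elsewhere).

Fusion computes the two competing averages

$$\bar o_\mu = \frac1N \sum_i o_\mu^{\varphi_i} \qquad\text{and}\qquad
  \bar\chi_\mu = \Big|\frac1N \sum_i \mathcal{A}\{o_\mu^{\varphi_i}\}\Big|,$$

the first optionally after cross-correlation-peak registration
(`fuseDirect`, the standard baseline, integer-voxel precision), the second
with no alignment at all (`fuseAcorr`). The absolute value removes the
negative excursions that background subtraction and spectral round-off leave
in the average; direct-space negatives after background subtraction are
deliberately *not* clamped — sanitation happens once, in lag space.

Averaging in $\mathcal{A}$-space has a second benefit. The direct average is
blurred by $\bar h = \frac1N\sum_i h^{\varphi_i}$, whose auto-correlation
contains all second-order cross-terms $h^{\varphi_i} \star h^{\varphi_j}$,
$i \ne j$; the averaged auto-correlation is blurred only by
$\bar{\mathcal{H}} = \frac1N\sum_i \mathcal{A}\{h^{\varphi_i}\}$, which
drops them. Expanding the two-view case makes the difference explicit:
$\mathcal{A}\{\bar h\} - \bar{\mathcal{H}} = -\tfrac14\,\mathcal{A}\{h^{(1)} - h^{(2)}\}$,
which is nonzero whenever the per-view kernels differ. The effective
direct-space kernel implied by $\bar{\mathcal{H}}$
(`effectivePSF`, computed by Schulz–Snyder inversion from a centred
isotropic Gaussian guess) is *sharper* than $\bar h$ along the scan axis for
a well-distributed set of angles — the package demonstrates this for the
12-view, 30°-step configuration (the FWHMs are computed by the acceptance
script). With only two orthogonal views the effect is absent or reversed:
the non-negative I-divergence minimizer for a two-cigar mixture is a
compact blob whose scan-axis width is not below that of $\bar h$, and
during development several unrelated initialisations (isotropic Gaussians
of different widths, the clamped zero-phase spectral solution) reached the
same minimizer. Sparse angular coverage does not sharpen; the effective-PSF
analysis therefore uses the full-turn configuration.

## Inversion

Two fixed-point multiplicative schemes invert $\bar\chi_\mu$, both
minimizing the Csiszár I-divergence
$D(\chi \,\|\, m) = \sum \chi \log(\chi/m) - \chi + m$ between the target
and the model auto-correlation:

* **Schulz–Snyder (SS)** solves $\bar\chi_\mu = o \star o$:
  $$o^{t+1} = \frac{o^t}{2\sqrt{\textstyle\sum\chi}}
    \Big[\widetilde{\Big(\frac{\chi}{o^t \star o^t}\Big)} * o^t
       + \Big(\frac{\chi}{o^t \star o^t}\Big) \star o^t\Big].$$
* **Anchor-Update (AU)** simultaneously deconvolves the known
  $\bar{\mathcal{H}}$, solving $\bar\chi_\mu = (o \star o) * \bar{\mathcal{H}}$:
  $$o^{t+1} = \frac{o^t}{\sqrt{\sum\chi\sum\mathcal{H}}}
    \Big[\Big(\frac{\chi}{o^t * \mathcal{K}^t}\Big) * \widetilde{\mathcal{K}^t}\Big],
    \qquad \mathcal{K}^t = o^t \star \bar{\mathcal{H}}\ \text{re-derived each step}.$$

Three numerical decisions deserve explanation.

**Normalization.** The updates are divided by constants proportional to the
object mass implied by the model, $\sqrt{\sum\chi}$ (linear-padded geometry:
$\sum\chi = (\sum o)^2 \sum\mathcal{H}$). A per-iterate normalizer
$2\sum o^t$ also leaves exact solutions fixed, but it makes the pure scale
direction oscillate with period two ($c \mapsto 1/c$), so the I-divergence
cannot decrease monotonically and the iterate mass never settles. The
constant-mass normalizer corrects any scale error in a single step and
preserves the descent property; the trace of $\sum o^t$ in
`divergenceTrace()` is constant at $\sqrt{\sum\chi}$ after the first
iteration, which doubles as a mass-consistency check
($(\sum o)^2 \approx \sum\chi$ at convergence).

**The SS bracket.** Under the lag convention used throughout,
$\tilde r * o \equiv r \star o$ identically, so the two bracket terms of the
default (`bracket = "classic"`) update coincide and the scheme is the
original monotone Schulz–Snyder iteration: the divergence trace is
non-increasing at every checkpoint on randomized 1D/2D problems to machine
precision. A variant in which the first term is $r * \tilde o$
(`bracket = "printed"`) symmetrizes the update between the object and its
flip; it is provided for comparison but it is *not* monotone (the test suite
pins a random toy whose divergence transiently rises under it) and exact
solutions with
asymmetric support are not fixed points of it. The classic form is the
default for both reasons.

**Ratio guard.** The model in the denominator is floored at
`epsDiv * max(model)` (default $10^{-12}$): multiplicative Bayesian updates
otherwise blow up on empty model voxels. Input volumes that should be
non-negative but carry spectral round-off at the $-10^{-16}$ level are
clamped to zero at the solver boundary only; genuinely negative inputs are
rejected.

**Initialisation and support.** The updates are multiplicative, so any voxel
that starts at zero stays at zero. The default initial guess is the
reference view (the $\varphi = 0$ acquisition), which is strictly positive
over the whole object neighbourhood and already close to the solution; the
unregistered mean is an equally valid choice. Spiky initial guesses with
empty support must be avoided. With a close guess the iterations converge
even on unpadded (circular) grids; the linear-padded mode embeds the problem
on the $2n-1$ lag grid, on which circular arithmetic is exact for
compact-support objects because the zero margin of the embedded initial
guess is preserved by the updates.

**Exact shift invariance.** The discrete FFT of a circularly shifted array
differs from the shifted FFT in its last bits, so a naive spectral
auto-correlation is shift-invariant only to $\sim 10^{-16}$. In circular
mode `autocorrelate()` therefore canonicalizes its input by rolling the
(unique) intensity argmax to the origin first: integer-shifted copies reduce
to the same array bitwise, making `fuseAcorr` *exactly* invariant to
per-view integer shifts. Exact intensity ties would make the canonical
representative ambiguous; they do not occur for blurred continuous-valued
views.

## Synthetic data and what the tests show

The generator reproduces the study conditions: 12 views in 30° steps over a
full turn; an anisotropic Gaussian PSF with
$\sigma_\text{scan}/\sigma_\text{lat} = 3$ (defaults 3 µm / 1 µm at 1 µm
voxel pitch for the recovery experiment, 4.5 µm / 1.5 µm for the PSF
analysis where the half-maximum crossings must be resolved by the grid);
per-view integer shifts uniform in $[-4, 4]$ voxels emulating stage
misalignment, with the reference view pinned at zero; no noise (the
high-SNR regime in which the additive term of the forward model is
neglected). Phantoms are bead fields (point sources of random position and
intensity), branching random-walk vessel trees with hollow lumina emulating
labelled vasculature, and hollow shells; all keep a zero margin of at least
the PSF half-support so blurring and shifts stay inside the grid. Problem
sizes are desk-scale by design: $48^3$ voxels and 5000 iterations for the
recovery experiment, $\le 8^3$ for the brute-force correlation oracles,
1D/2D toys for the solver-property suites.

What passing tests do and do not show: the suite verifies the correlation
algebra against direct-sum brute force, the exact shift invariance of the
fused auto-correlation, the fixed-point/monotonicity/mass properties of the
solvers, the delta-anchor reduction of AU to SS, the recovery advantage of
SS over unregistered direct fusion, AU's bead-level resolution gain over SS
given the true PSF, and the effective-PSF sharpening at 12 views. The
generator does not emulate light-sheet physics (scattering, absorption,
stripes), rotation-stage tilt, sub-pixel interpolation artefacts of real
stacks, or realistic photon statistics — conclusions about real data remain
qualitative.

## A short worked example

```{r example, eval = FALSE}
phantom <- generatePhantom("bead_field", c(48, 48, 48),
                           list(nBeads = 12), seed = 71)
psf <- PSFModel(sigmaLateral = 1, sigmaScan = 3)
views <- simulateViews(phantom, psf, seq(0, 330, by = 30),
                       shiftLaw = list(max = 4), seed = 73)

chi <- fuseAcorr(views, "circular")        # inherently aligned fusion
ss <- solveAcorr(chi, "SS", init = referenceView(views), nIter = 5000)
recoveryScore(ss$recon, phantom)           # > unregistered direct fusion
recoveryScore(fuseDirect(views, registered = FALSE), phantom)
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sigmaScan`, `sigmaLateral`, `sigmaTransverse` | — (µm) | Gaussian PSF widths; scan axis elongated |
| PSF support | 8σ, odd | kernel extent; ≥ 6σ required, 8σ keeps the rendered second moments essentially exact |
| `shiftLaw$max` | 4 voxels | misalignment radius (uniform integer; optional fractional part) |
| `nIter` | 5000 | iteration budget, the only solver parameter that must be chosen |
| `checkpointEvery` | 100 | trace/validity cadence |
| `tol` | off | optional early stop on relative divergence change |
| `epsDiv` | 1e-12 | relative model floor in the ratio |
| `mode` | circular ≤ grids with close guess; linear-padded for cold starts | correlation geometry |

Rotation interpolation is cubic-convolution (Catmull–Rom) at `order = 3`
(bilinear at `order = 1`); a prefiltered B-spline would gain little at the
smoothness of blurred views and would add a dependency. All internal
arithmetic is double precision: the fixed-point solvers run thousands of
iterations and accumulate rounding.

## Known limitations

* De-autocorrelation recovers the object only up to translation and flip;
  downstream comparisons must score over that group.
* Two-view (or otherwise sparse-angle) configurations do not produce a
  sharper effective PSF; dense angular coverage does.
* The registration baseline is integer-voxel by design; sub-voxel upsampled
  registration is out of scope.
* Circular-mode fusion assumes the object's support (after blurring and
  shifting) stays away from wrap-around; phantoms enforce a margin, real
  data should be padded or cropped accordingly.
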