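# AcorrTomo

Inherently aligned multi-view tomography by auto-correlation inversion.

## What it does

In multi-view light-sheet fluorescence microscopy the specimen is imaged at
several rotation angles and the views are fused into one volume. The
standard pipeline registers every view against a reference before
averaging; registration is fragile at the voxel level and expensive below
it. AcorrTomo fuses the views in auto-correlation space instead. The
auto-correlation

    A{v} = v ⋆ v,    (a ⋆ b)(ξ) = Σ_y a(y) b(y + ξ)

is invariant to rigid translations — all misalignment lives in the Fourier
phase, which A discards — so the per-view auto-correlations can be averaged
with no alignment at all:

    χ̄_μ = | (1/N) Σ_i A{o_μ^{φ_i}} |.

The object is then recovered by inverting χ̄_μ (a phase-retrieval problem,
solvable up to a global shift and flip) with one of two fixed-point
multiplicative schemes that minimize the Csiszár I-divergence:

* **Schulz–Snyder (SS)** solves χ̄_μ = o ⋆ o:
  `o ← o · [(χ/(o⋆o))~ * o + (χ/(o⋆o)) ⋆ o] / (2√Σχ)`
* **Anchor-Update (AU)** additionally deconvolves the known
  auto-correlation-space PSF H̄, solving χ̄_μ = (o ⋆ o) * H̄, re-deriving the
  effective kernel K^t = o^t ⋆ H̄ at every step.

Averaging in A-space also drops the second-order cross-terms between the
per-view PSFs, so the effective PSF of the result is sharper than the
direct-space average PSF h̄ when the angles cover the turn densely.

The package ships the full pipeline: synthetic phantoms (bead fields,
branching hollow vessel trees, shells), an anisotropic-Gaussian multi-view
forward model with misalignment and optional noise, pre-processing
(background subtraction, rotation to the reference frame), the
cross-correlation registration baseline, both solvers, PSF analysis
(effective PSF, FWHM, line profiles) and multi-page TIFF I/O with YAML
sidecars. It is intended for method developers and microscopists who want
to study registration-free fusion on controlled synthetic data.

## Worked example

```r
library(AcorrTomo)

phantom <- generatePhantom("bead_field", c(48, 48, 48),
                           list(nBeads = 12), seed = 71)
psf    <- PSFModel(sigmaLateral = 1, sigmaScan = 3)   # 3:1 elongation
views  <- simulateViews(phantom, psf, seq(0, 330, by = 30),
                        shiftLaw = list(max = 4), seed = 73)

chi <- fuseAcorr(views, "circular")     # no registration performed
ss  <- solveAcorr(chi, "SS", init = referenceView(views), nIter = 5000)

recoveryScore(ss$recon, phantom)                          # 0.327
recoveryScore(fuseDirect(views, registered = FALSE), phantom)  # 0.102
```

The recovery score is the maximum normalized cross-correlation with the
ground truth over all global shifts and the flip ambiguity (1 = perfect up
to the ambiguity group). The auto-correlation reconstruction beats the
unregistered average by a wide margin although it never saw the true
shifts; supplying the true PSF to AU sharpens it further
(`recoveryScore ≈ 0.9997`, bead FWHM ≈ 1.0 voxel vs ≈ 2.9 for SS).

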