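# dogcontour

Edge-based active-contour segmentation of single-channel images, driven by a
raw difference-of-Gaussians (DoG) edge response.

## The scientific problem

Two-phase segmentation — outlining a compact object against its background —
breaks down for global intensity methods when the image carries **intensity
inhomogeneity**: a smooth multiplicative field (an MR coil bias, uneven
illumination) that makes "object intensity" a function of position. Edge-based
active contours sidestep this because a smooth bias barely perturbs local
band-pass edge structure. This package implements a level-set active contour
whose edge detector *and* balloon force are one and the same signed DoG
response, so the contour is simultaneously pushed across homogeneous regions
and halted at edges by a single term.

## The model

The contour is the zero level set of a field φ over the pixel grid
(φ < 0 inside). With a grayscale image *I* on the 0–255 scale, the edge
indicator is the raw difference of Gaussians

    Γ(x) = (G_σ1 * I)(x) − (G_σ2 * I)(x),   σ1 < σ2,

positive just inside bright structures, negative just outside, zero on the
edge. The field evolves by explicit Euler steps φ ← φ + τ·ξ(φ) of the
gradient flow

    ξ(φ) = (ν Γ + μ κ) δ_ε(φ) + α (Δφ − κ),

where κ = div(∇φ/|∇φ|) is mean curvature, δ_ε(φ) = ε/(π(φ² + ε²)) is the
arctan-regularized Dirac impulse, ν Γ δ_ε is the balloon force, μ κ δ_ε the
length penalty, and α(Δφ − κ) a distance-regularization term (the descent
direction of ½∫(|∇φ|−1)²) that removes any need for signed-distance
re-initialization. φ starts as a binary step ±ρ over a seed region; because
δ_ε has algebraic tails the balloon force acts on every pixel, which makes the
final contour largely independent of where the seed is placed.

Defaults (clean images): μ = 0.001·255², ν = −40, α = 1, ε = 1, τ = 0.1,
σ1 = 1, σ2 = 2, ρ = 1. A `"noisy"` preset widens the kernels and strengthens
the length penalty: σ1 = 2, σ2 = 10, μ = 0.01·255². The explicit scheme
follows the stability guideline τ·α ≤ 0.2.

## Worked example

Segment a flower-shaped object under a strong intensity bias (the darkest
ladder level of the built-in phantom suite), starting from a square seed:

```r
library(dogcontour)

ph <- paper_suite(1L)$ladder_5      # flower under a strength-0.25 bias ramp
res <- segment(ph$image, region_rect(100, 100, 150, 150), evolution_params())
res
#> <segmentation_result> 250 x 250, 27 iterations (converged), interior 5164 px

print(segmentation_scores(ph$truth, res$mask), digits = 4)
#>       ji accuracy_pct    dsc    mcc hd
#> 1 0.9992        99.92 0.9996 0.9996  1
```

Despite a 4:1 intensity falloff across the frame, the contour recovers the
object to a Jaccard index of 0.9992 in 27 iterations. A seed rectangle placed
entirely off the object converges to the identical mask:

```r
res2 <- segment(ph$image, region_rect(20, 180, 60, 230), evolution_params())
jaccard(res$mask, res2$mask)
#> [1] 1
```

Useful entry points: `dog_indicator()` (edge map), `evolution_params()`,
`segment()`, `extract_contour()` (sub-pixel zero level set),
`two_phase_split()` (tissue separation inside a ROI),
`segmentation_scores()` / `jaccard()` / `dice()` / `mcc()` / `hausdorff()`,
`make_object_phantom()` / `apply_bias()` / `add_noise()` / `paper_suite()`
(deterministic phantoms with ground truth), `load_image()` / `save_mask()` /
`load_config()` (I/O), plus a CLI at `inst/cli/dogcontour.R`.

## Known limitations

Two properties fail honestly at the documented operating points, and their
test blocks are left failing on purpose:

- **Dense noise floods the background.** Because δ_ε never vanishes, the
  balloon force ν Γ δ_ε acts globally; at salt-and-pepper density 0.2 (or
  Gaussian variance 0.2 on the unit scale) the smoothed noise residual still
  overwhelms the curvature restoring force, and roughly the Γ > 0 half of the
  background flips to interior (Jaccard ≈ 0.2 instead of ≥ 0.9). This is
  amplitude-invariant (Γ is linear in the image), so no contrast setting
  avoids it.
- **The field does not stay a signed distance function when over-run.** The
  distance regularization genuinely reshapes the binary step up to
  convergence (deviation 0.88 → 0.81 in the band |φ| < 2), but past
  convergence the never-vanishing balloon force steepens the interface
  (deviation 7.96 after a forced 200 iterations) while the zero level set —
  and hence the mask — stays put.

Both mechanisms are analyzed in the methods vignette
(`vignettes/dog-levelset-methods.Rmd`).
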