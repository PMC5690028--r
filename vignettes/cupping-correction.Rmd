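---
title: "Energy-minimization cupping correction: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-minimization cupping correction: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emmcup)
```

## The model

Cone-beam CT reconstructions are corrupted by scatter and beam hardening,
which show up in a slice as *cupping*: a smooth, slowly varying depression
of intensity toward the object centre. `emmcup` works entirely in the
reconstructed-image domain. Each slice is modelled additively over the
object support $\Omega$:

$$ f(x) = f_p(x) + f_s(x) + f_n(x), $$

where $f_p$ is the piecewise-constant tissue image ($f_p = \sum_{i=1}^N c_i
u_i(x)$ with hard binary memberships $u_i$ and per-tissue constants $c_i$),
$f_s$ is the smooth cupping field, expanded in a basis of $M$ smooth
functions as $f_s = w^\top G(x)$, and $f_n$ is zero-mean noise (never
estimated explicitly; it is the residual). The decomposition minimizes

$$ F(u, c, w) = \sum_{x \in \Omega}\bigl(f(x) - c_{l(x)} - w^\top G(x)\bigr)^2 $$

by alternating exact, closed-form minimizations: the **w-step** solves the
normal equations $A w = v$ with Gram matrix $A = \sum_\Omega G G^\top$; the
**c-step** sets each $c_i$ to the mean of $f - \hat f_s$ over its class;
the **u-step** assigns each pixel to the class with the smallest squared
residual. $F$ is convex in each block, so every step decreases it and the
energy trace is non-increasing (asserted in the tests at $10^{-9}$
relative tolerance). The iteration stops when the Euclidean change of the
tissue-mean vector drops below `eps`.

A notational point: in the source formulation of this scheme the w-step
and u-step residuals are printed with a bare absolute value / without the
square. We implement both as least-squares forms, which is the only
reading under which the closed-form normal-equation and per-class-mean
solutions actually minimize the energy; the implementation is internally
consistent rather than literally faithful to the typography.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `n_tissues` (N) | 3 (1 for uniformity phantoms) | number of tissue classes; the number of plateaus you expect in the histogram. Never published for the reference experiments, so always user-settable. |
| `degree` | 3 | total degree of the bivariate monomial basis; degree 3 gives the complete 10-function family $x^a y^b$, $a+b\le3$. "Ten polynomials" pins down the count but not the family; the complete degree-3 monomial basis is the unique natural 2-D polynomial family with exactly ten members. |
| `eps` | 0.001 | stopping tolerance on $\lVert c^{(n)} - c^{(n-1)}\rVert_2$, measured on the internal $[0,1]$ intensity scale, which makes the tolerance scale-free across modalities. The norm itself is a package choice (unstated in the source). |
| `max_iter` | 50 | safety bound; typical convergence is far faster. |
| `orthonormalize` | off | Cholesky orthonormalization of the basis w.r.t. the masked inner product; a conditioning aid, off by default to keep the default path the plain normal-equation solve. |

Numerical choices worth knowing:

* **Coordinates** are affinely normalized to $[-1,1]$ over the mask
  bounding box before evaluating monomials; with raw pixel indices the
  degree-3 Gram matrix is catastrophically ill-conditioned.
* **Identifiability.** The basis spans constants and $\sum_i u_i = 1$, so a
  constant can be traded freely between $c$ and $w$. We resolve it by
  recentring the fitted field to zero mean over the mask; the corrected
  image `f - bias_field` therefore preserves the slice's mean intensity
  (CT-number calibration is untouched). The removed constant is reported
  as `bias_offset`.
* **Ties** in the u-step go to the smallest class index (determinism).
* **Empty classes** in the c-step keep their previous mean (division
  guard).
* **Masking.** The energy is evaluated over an object-support mask. With
  `--mask auto` (the default in the CLI) the mask is an Otsu threshold
  followed by largest-connected-component selection and hole filling;
  fitting the polynomial across the object/air edge would corrupt the
  field. A user mask always wins.
* **Initialization.** Tissue means start at the $(i-\tfrac12)/N$ quantiles
  of the masked intensities (sorted, deterministic); $w = 0$; memberships
  follow. `init_means` overrides this, and is respected unsorted — which
  is also how the label-permutation invariance of the decomposition is
  tested.
* Intensities are normalized to $[0,1]$ over the mask before solving and
  restored exactly afterwards, so results are exactly equivariant under
  positive rescaling of the input.

## Metrics

* `tau_cup`: $100\,(\bar u_{\mathrm{edge}} - \bar u_{\mathrm{center}}) /
  \bar u_{\mathrm{edge}}$ over a center and an edge ROI; positive for
  classic cupping.
* `rmsc`: the population standard deviation of pixel intensities after the
  whole image is affinely rescaled to $[0,255]$, optionally restricted to
  an ROI; invariant under affine intensity maps of the input.
* `cnr`: **a package convention**, $|\bar I_{\mathrm{center}} -
  \bar I_{\mathrm{background}}| / \sigma_{\mathrm{background}}$ (population
  s.d.). CNR is reported in the CBCT literature without a common
  definition, so values are comparable within this package only.

ROI geometry is never published with coordinates in the reference
experiments; our defaults for synthetic phantoms are a center disk of
radius $0.1R$, an edge annulus at $0.8$–$0.9R$, and a background square in
the air corner, all overridable via a JSON ROI file (0-based pixel
coordinates, half-open rectangles). For the concentric three-tissue
geometry the edge annulus moves to $0.6$–$0.7R$ so that the center and
edge ROIs sample the *same* tissue; at $0.8$–$0.9R$ it would sit in the
bone shell and `tau_cup` would measure tissue contrast rather than the
artifact.

## What the synthetic phantoms do and do not establish

`make_phantom()` generates exactly the world the model assumes:
`image = true_piecewise + true_bias + noise`, bit-reproducible per seed.

* `uniform_disk` — one tissue (0.7) on a centred disk of radius
  `0.45 * min(shape)`; the analogue of a water-uniformity module.
* `concentric_three_tissue` — soft tissue (0.5) inside $0.75R$, a
  bone-like shell (0.95) at $0.75$–$0.9R$, a low-density outer ring (0.15)
  at $0.9R$–$R$; a skull-like idealization.
* `multi_insert` — a disk with four small density inserts at half radius.

The cupping field is either `polynomial` — $a\,(x^2+y^2-1)$ in
bounding-box coordinates, a centre-depressed bowl *inside* the degree-3
span (model-matched) — or `radial_gaussian`, which lies outside the span
and serves as the model-mismatch stress case. When a `tau_target` is
given, the amplitude $a$ is calibrated in closed form from the ROI means
of the unit bowl so the noise-free phantom has exactly that pre-correction
`tau_cup`. Noise is i.i.d. zero-mean Gaussian; the defaults (noise s.d.
0.01 on order-1 tissue values, targets of 20% for the uniformity disk and
16% for the skull-like phantom) mirror the cupping magnitudes reported for
real water and skull phantoms.

A green test on these phantoms establishes that the algorithm recovers the
decomposition *when its model holds*: piecewise-constant tissues, an
additive in-span smooth field, stationary Gaussian noise, crisp tissue
boundaries. Real CBCT violates all four (texture, partial volume, streaks,
non-stationary noise, fields that are only approximately polynomial), so
phantom results bound algorithmic correctness, not clinical performance.
The `radial_gaussian` kind probes the mildest of these violations.

## Convergence behaviour, honestly

On noiseless model-matched phantoms the energy drops to numerical zero and
the field is recovered to RMSE $<10^{-6}$ (normalized units); the uniform
disk converges in a single iteration (with $N=1$ the post-w-step residual
is orthogonal to constants, so the c-step is a fixed point immediately).

The concentric three-tissue phantom is the method's worst case: its class
indicators are purely radial, hence nearly inside the span of the radial
polynomials ($1, r^2$ and odd-power combinations), and the $w \leftrightarrow c$
alternation converges linearly at a rate of about $0.8$ per iteration (the
largest non-constant squared canonical correlation between the two
subspaces). Pushing $\lVert\Delta c\rVert$ from its initial $\sim
3\times10^{-2}$ below $10^{-3}$ then takes exactly 15 iterations — one
more than the "fewer than 15" reported for real scans, which are less
radially symmetric than this idealization. We deliberately keep the
phantom (and the corresponding acceptance test, which is red by that one
iteration) rather than de-symmetrizing the geometry after the fact; treat
it as a documented worst case, not a failure of the updates themselves,
each of which is provably an exact minimizer (and is tested against
brute-force oracles).

## Known limitations

* Additive bias model only; multiplicative shading and beam-hardening
  streaks are out of scope, as is any projection-domain processing or
  reconstruction.
* Volumes are processed strictly slice-by-slice; the field is not coupled
  across slices.
* Hard memberships: partial-volume pixels are forced into one class and
  inflate the residual there.
* I/O is limited to lossless raw-float-with-sidecar and CSV/TSV in this
  build; DICOM/NIfTI/TIFF readers would slot into `read_image()` but are
  not provided.
* `cnr` is a package convention (see above).

## A worked run

```{r}
sp <- phantom_spec(shape = c(96, 96), geometry = "uniform_disk",
                   cupping = list(kind = "polynomial", tau_target = 20),
                   noise_sd = 0.01, seed = 7)
rec <- recovery_experiment(sp, solver_config(n_tissues = 1))
rec
```

The same pipeline is scriptable end-to-end from the command line via
`emm_cli()` (`simulate`, `correct`, `metrics` subcommands); every run
writes a provenance JSON next to its outputs.
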