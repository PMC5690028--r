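# emmcup

Correction of cupping artifacts in reconstructed cone-beam CT (CBCT)
slices by energy minimization.

CBCT systems with large flat-panel detectors admit so much scatter (plus
beam hardening) that reconstructed objects show *cupping*: intensity sags
smoothly toward the object centre, breaking CT-number accuracy,
thresholding and volume rendering. `emmcup` is for physicists and image
analysts who want to flatten that artifact **after** reconstruction — no
scatter measurements, no hardware, a single scan — and to quantify the
improvement.

## The method

A slice is modelled additively over the object support $\Omega$:

$$f(x) = \underbrace{\textstyle\sum_{i=1}^{N} c_i\,u_i(x)}_{\text{piecewise-constant tissues } f_p}
 + \underbrace{w^\top G(x)}_{\text{smooth cupping field } f_s}
 + \underbrace{f_n(x)}_{\text{zero-mean noise}}$$

with hard binary memberships $u_i$, tissue constants $c_i$, and $M = 10$
polynomial basis functions $G$ (complete bivariate monomials of total
degree $\le 3$). The energy

$$F(u,c,w) = \sum_{x\in\Omega}\bigl(f(x) - c_{l(x)} - w^\top G(x)\bigr)^2$$

is convex in each block and is minimized by alternating exact updates:
$w = A^{-1}v$ (normal equations with Gram matrix $A = \sum G G^\top$),
$c_i = \mathrm{mean}_{\,\Omega_i}(f - \hat f_s)$, and per-pixel nearest-mean
relabelling; iteration stops when $\lVert c^{(n)}-c^{(n-1)}\rVert_2 <
\varepsilon$ (default $10^{-3}$ on the internal $[0,1]$ scale). The fitted
field, recentred to zero mean over the mask, is subtracted:
`corrected = f - bias_field`, preserving the slice's mean intensity.

Uniformity metrics: cupping magnitude
$\tau_{\mathrm{cup}} = 100\,(\bar u_{\mathrm{edge}} -
\bar u_{\mathrm{center}})/\bar u_{\mathrm{edge}}$, root-mean-square
contrast (population s.d. after rescaling to $[0,255]$), a CNR convention,
and line profiles. See the methods vignette
(`vignettes/cupping-correction.Rmd`) for assumptions, parameter guidance
and known limitations.

## Worked example

```r
library(emmcup)

# A 229x229 water-uniformity phantom with an in-span cupping bowl
# calibrated to a 20% pre-correction cupping magnitude, 1% noise.
sp <- phantom_spec(shape = c(229, 229), geometry = "uniform_disk",
                   cupping = list(kind = "polynomial", tau_target = 20),
                   noise_sd = 0.01, seed = 7)
make_phantom(sp)
#> <emm_phantom> uniform_disk 229x229, 1 tissue(s), cupping polynomial (a=0.1805), noise sd 0.01, seed 7

recovery_experiment(sp, solver_config(n_tissues = 1))
#> <emm_recovery> bias RMSE 0.000708 (normalized), label accuracy 100.0%
#>   tau_cup 19.93% -> -0.07% (100.3% reduction), 1 iteration(s)
```

Reading: the generated slice cups by 19.93% at the default center/edge
ROIs; after correction the residual magnitude is -0.07% (i.e. flat to
within the noise), the estimated field matches the injected truth to an
RMS error of 7e-4 on the normalized intensity scale, and with one tissue
class the solver converges in a single iteration.

The same run from the shell (CSV and raw-float+JSON-sidecar formats are
supported):

```sh
LAUNCHER=$(Rscript -e 'cat(system.file("cli/emmcup.R", package = "emmcup"))')
Rscript "$LAUNCHER" simulate --geometry uniform_disk --shape 229x229 \
    --tau-target 20 --noise-sd 0.01 --seed 7 --out demo
Rscript "$LAUNCHER" correct demo/image.csv --tissues 1 \
    --out demo/corrected.csv --bias-out demo/bias.csv --metrics-out demo/metrics.csv
cut -d, -f1-2 demo/metrics.csv
#> label,tau_cup
#> slice001_before,19.93444964
#> slice001_after,-0.06694265353
```

Every `correct` run also writes a `*.provenance.json` (package version,
seed, full config echo) next to its outputs.

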