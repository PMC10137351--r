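---
title: "Modelling the air-kerma field of an X-ray tube with GMDH networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the air-kerma field of an X-ray tube with GMDH networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modelling choices behind `kermagmdh`: the
surrogate of the kerma field, the GMDH engine and its two growth schemes,
the evaluation protocol, and the numerical decisions a maintainer would
want written down.

## The physical picture

A diagnostic X-ray tube emits a conical beam whose intensity, measured as
air kerma, varies over the field:

* **Heel effect.** Photons emitted towards the anode (target) side traverse
  more target material and are attenuated; kerma falls monotonically with
  the tangent angle $\varphi$ (0° at the field centre, 20° at the modelled
  cone edge).
* **Inverse square law.** At fixed angles, kerma scales as $1/r^2$ in the
  source–detector distance.
* **Voltage.** Raising the tube potential hardens and intensifies the beam;
  kerma rises monotonically with $V$.
* **Azimuthal symmetry.** Across the polar angle $\theta$ the field is
  treated as uniform.

## The surrogate field

Monte Carlo transport results for a specific tube are not redistributable,
so the package generates training data from an analytic surrogate
$$K(\varphi, \theta, r, V) = K_{\mathrm{ref}}\; h(\varphi)\,
  \left(\frac{r_{\mathrm{ref}}}{r}\right)^2
  \left(\frac{V}{40\,\mathrm{kV}}\right)^{p},$$
anchored to the packaged 324-row reference table of simulated kerma values
(`load_reference_table()`):

* $K_{\mathrm{ref}} = 0.3730 \times 10^{-5}$, the tabulated kerma at the
  anchor point ($\varphi = 0$, $r = 250$ mm, $V = 40$ kV);
* $h(\varphi)$ interpolates piecewise-linearly through the anchor-block
  kerma ratios at $\varphi = 0, 2, \ldots, 18^\circ$ ($h(0) = 1$, strictly
  decreasing). The table has no $\varphi = 20^\circ$ row in the anchor
  block, so that knot is linearly extrapolated from the last two values
  (yielding ≈ 0.0204) and floored at 0.005 to keep kerma positive;
* $p$ is fit once by log–log least squares over the six anchor-point
  voltages (≈ 0.168; it reproduces the tabulated 140 kV value to 0.1 %);
* optional noise multiplies each value by $(1 + \varepsilon)$,
  $\varepsilon \sim N(0, \sigma)$ truncated at $\pm 3\sigma$, with
  $\sigma \le 0.04$ — the statistical-uncertainty cap of the underlying
  tally data. The default is $\sigma = 0.04$.

The default detector grid (`grid_spec()`) is 11 tangent angles × 25 polar
angles (0–360° in 15° steps, 0° and 360° kept as distinct rows) × 5
distances (250–1250 mm) × 6 voltages (40–140 kV): 1375 points per voltage,
8250 samples. The reference table confounds $\theta$ with $r$ (they co-vary
across its blocks), so no $\theta$ effect is identifiable from it; the
surrogate is exactly $\theta$-invariant, consistent with the reported
top-to-bottom uniformity of measured fields.

**What the surrogate does not emulate:** spectral changes with angle
(beam hardening across the heel), scatter from housing and collimators,
off-focal radiation, any $\theta$ structure, and correlated errors between
neighbouring detectors. Tests passing against the surrogate therefore
validate the learning machinery and the field's leading-order structure,
not a specific physical tube.

## The GMDH engine

Training data are min–max normalized per column to $[0, 1]$ (constant
columns map to 0; parameters are stored in the model and inverted on
prediction). The training rows are split once, with a seeded shuffle, into
a 70 % *fit* subset (coefficients) and a 30 % *selection* subset (the
external regularity criterion); each candidate neuron
$$Z = c_1 + c_2 x_i + c_3 x_j + c_4 x_i^2 + c_5 x_j^2 + c_6 x_i x_j$$
is fit on the former by least squares and scored by its RMSE on the latter.
"Dead" neurons (high criterion score) are discarded.

### Compose growth (default)

The classical multilayer scheme: layer 1 pairs the raw inputs
($\binom{4}{2} = 6$ candidates), keeps the best `width_k = 4`; each later
layer pairs the previous survivors' outputs. Growth stops at `max_layers`
(default 2, the architecture that the study protocol prescribes), when a
new layer fails to improve the best criterion score, or when that score
reaches numerical zero ($\le 10^{-12}$), whichever comes first. The best
neuron of the final layer is the output.

### Cascade growth

On this field the compose scheme hits a structural plateau: every neuron is
fit to the *full* target, so survivors become near-duplicates of the best
approximation, and stacking quadratics of near-identical inputs improves
the fit only marginally. Empirically the selection RMSE stalls near 0.5 %
of the normalized range regardless of width (4–40) or depth (2–60), with or
without re-injecting raw inputs.

`growth = "cascade"` removes the bottleneck while keeping every GMDH
ingredient (quadratic pair neurons, least squares, external-criterion
selection, seeded fit/select split, stop-on-non-improvement): each layer
evaluates all pairs over a pool holding the four raw inputs plus the most
recent layer outputs (at most `pool_cap` features), and the single
criterion-winning neuron is fit to the *residual* of the accumulated model.
The model output is the sum of all layer outputs. Because a stage's
criterion score equals the whole model's selection RMSE after that stage,
the layer-monotonicity invariant and the stopping rule carry over
unchanged. The additive update preserves previously captured structure
exactly — the right bias for this field, whose logarithm is additively
separable in $\varphi$, $r$ and $V$.

### Log target transform

The evaluation criterion is a *relative* error, but least squares on raw
kerma minimizes *absolute* error: the field spans 3.5 decades
(≈ $3\times10^{-9}$ to $4.6\times10^{-6}$), so even a fit with excellent
absolute RMSE leaves tens of percent relative error at the field edge.
`target_transform = "log"` fits $\log K$ (then min–max normalizes as
usual): least squares in log space is relative error in linear space, and
the multiplicative field becomes additive. Predictions are exponentiated
back, so they are always positive. The transform requires strictly
positive targets.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `width_k` | 4 | neurons | survivors per compose layer |
| `max_layers` | 2 | layers | compose: depth; cascade: number of stages |
| `inner_split` | 0.7 | — | fit fraction of the training rows |
| `growth` | `"compose"` | — | `"cascade"` for the residual scheme |
| `target_transform` | `"none"` | — | `"log"` for relative-error fitting |
| `pool_cap` | 24 | features | cascade candidate-pool size |
| `split_fraction` | 0.7 | — | outer train/test split (`run_experiment`) |
| `noise_sigma` | 0.04 | — | surrogate noise fraction, at most 0.04 |

The high-accuracy configuration used by `scripts/acceptance.R` is
`gmdh_control(growth = "cascade", target_transform = "log", max_layers =
200, pool_cap = 36)`: 200 stages with a 36-feature pool converge to a
held-out mean relative error around 0.02–0.2 % on the noiseless surrogate
(seed-dependent), an order of magnitude inside the 0.25 % working bound,
in about two minutes on one CPU. Raising `pool_cap` from 24 to 36 is what
unlocks the final order of magnitude: the larger pool keeps enough feature
diversity for late stages to find informative pairs.

## Numerical choices

* **Least squares.** Each neuron solve uses the SVD; singular values below
  $10^{-10} \times$ the largest are zeroed, giving the deterministic
  minimum-norm solution on rank-deficient designs (e.g. a constant
  feature).
* **Tie-breaks.** Candidates with equal criterion score are ordered by
  their input-index pair, so results are reproducible across platforms.
* **Stopping.** A layer that fails to improve the best criterion score is
  discarded and growth stops; growth also stops once the score reaches
  $10^{-12}$ (numerical zero on a $[0,1]$ target — beyond it, ranking
  neurons is meaningless).
* **Split rounding.** The training subset holds
  $\lfloor 0.7 N \rfloor$ rows — exact on the default grid
  ($0.7 \times 8250 = 5775$) and deterministic otherwise.
* **Seeds.** A single master seed derives independent sub-seeds (simple
  integer hash, kept below $2^{31}$) for surrogate noise, the outer split
  and the inner split, so changing one stage never perturbs another's
  draws. Identical seeds give bit-identical models and reports.
* **Serialization.** Model JSON stores coefficients with 17 significant
  digits; a write/read round trip reproduces coefficients and predictions
  bit-for-bit. Dataset CSVs are written the same way.
* **Relative-error denominator.** The MRE divides by the *predicted*
  value, as the error criterion is printed in the source protocol; the
  conventional expected-value denominator is available via
  `denominator = "expected"`.
* **Extrapolation.** Polynomials evaluate everywhere, so queries outside
  the training range are answered, with a warning.

## Problem sizes in the test suite

Unit tests run on small synthetic designs (tens to hundreds of rows) and a
330-row single-polar-angle grid; the end-to-end checks (field invariants,
split protocol, headline error) use the full 8250-sample default grid. The
headline check trains the 200-stage cascade once, taking on the order of
two minutes; everything else completes in seconds.

## Known limitations

* The surrogate's fidelity bounds what the network can learn about a real
  tube; in particular the exact heel profile between the 2° knots is a
  linear interpolation, and the $\varphi = 20°$ knot is an extrapolation.
* The compose scheme with the study's 2×4 architecture reproduces the
  field's absolute shape but not edge-of-field relative accuracy; use the
  cascade/log configuration when relative error matters.
* MRE with the predicted-value denominator is undefined when a prediction
  is exactly zero and misleading if predictions are negative; the log
  transform sidesteps both by construction.
* The cascade's candidate pool is truncated to the most recent
  `pool_cap` outputs; very long cascades therefore cannot revisit early
  intermediate features.
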