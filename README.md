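# selectseg

Selective (interactive) two-phase segmentation of 2-D greyscale images in R.

Given a few user marker points inside a target object, `selectseg` isolates
that object — and only that object — even when other parts of the image have
exactly the same intensity. The intended application is organ contouring in
CT/MRI, where the target is approximately homogeneous but the background is
not.

## The model

The segmentation is the minimiser of the convex relaxed functional

    min_{u in [0,1]}  TV_g(u) + lambda * <F, u>,

where `TV_g(u) = ∫ g(|∇z|) |∇u|` is the edge-weighted total variation
(`g(s) = 1/(1 + beta s²)`), and the sup-normalised data field
`F = (theta * D + f) / ||theta * D + f||_inf` combines

* `D`: a geodesic distance penalty from the marker polygon, the normalised
  solution of the Eikonal problem `|∇D⁰| = eps_D + beta_G |∇z|²` with
  `D⁰ = 0` on the polygon, and
* `f`: a signed intensity fitting function.

The package's own fitting term keeps the Chan–Vese foreground quadratic
`(z - c1)²` (with `c1` fixed at the mean intensity inside the marker
polygon) but replaces the background term `(z - c2)²` with an asymmetric
tent that equals 1 at `z = c1` and decays linearly to 0 at `c1 - gamma1`
and `c1 + gamma2`. This penalises background pixels of *foreground-like*
intensity — the case where a background constant `c2 ≈ c1` makes Chan–Vese
vanish — and the widths `(gamma1, gamma2)` are selected automatically from
a 3-class Otsu partition of the image histogram. Five classical fitting
terms (`cv`, `rsf`, `lcv`, `hyb`, `gav`) are included for comparison. The
box constraint is enforced by a regularised exact penalty and the
functional is minimised with a modified additive operator splitting (AOS)
scheme; the relaxed minimiser is thresholded at 0.5.

Accuracy is measured by the Tanimoto (Jaccard) coefficient
`TC = |A ∩ GT| / |A ∪ GT|`.

## Worked example

```r
library(selectseg)

# a 128 x 128 synthetic benchmark: homogeneous target disc at 0.50, a decoy
# disc at the same intensity, background panels balanced to mean 0.50
fx <- make_equal_mean_fixture(seed = 1)
P  <- default_markers(fx$gt, seed = 1)     # 3-point marker triangle

fit <- selseg(fx$image, P, model = "pm", lambda = 2, theta = 2)
fit
#> Selective segmentation fit (model = pm)
#>   grid 128 x 128, 3 marker points, lambda = 2, theta = 2
#>   converged after 98 iterations (final change 7.58e-05)
#>   foreground: 1201 pixels (7.3%)

tanimoto(predict(fit), fx$gt)
#> [1] 1

# the same image defeats the Chan-Vese term: its optimal constants satisfy
# c1 = c2, the fitting signal vanishes, and the mask collapses
fit_cv <- selseg(fx$image, P, model = "cv", lambda = 5, theta = 5)
tanimoto(predict(fit_cv), fx$gt)
#> [1] 0.08742714
```

`predict(fit)` returns the binary mask (optionally at another threshold),
`fitted(fit)` the relaxed labels, `coef(fit)` the intensity constants and
weights, `plot(fit)` the image with the segmentation boundary and markers,
and `summary(fit)` convergence and parameter details, including the
automatically selected `(gamma1, gamma2)`.

Robustness tools: `parameter_sweep()` records TC over a `(lambda, theta)`
grid; `randomized_marker_study()` re-solves with random 3-point marker
triangles drawn inside the target and summarises the TC sample.

A small command-line front end wrapping these functions is in
`inst/cli/selectseg.R` (subcommands `run`, `sweep`, `random-study`,
`make-fixture`).

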