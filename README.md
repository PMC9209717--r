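# pcseg

Semi-automatic closed-contour segmentation with principal curves and an
evolution-initialized neural network.

## The problem

Delineating a closed organ boundary on a noisy medical image -- the
motivating case is the prostate on transrectal ultrasound, where speckle
and shadow artifacts blur or erase the edge -- is tedious to do fully by
hand and unreliable to do fully automatically.  pcseg implements a
middle road for analysts and method developers: the user clicks a
handful of approximate boundary points (well under 10% of a full manual
delineation), and the package turns them into a smooth, closed,
*interpretable* parametric contour.

Two cascaded stages do the work:

1. **CCPS** -- a constrained closed polygonal principal curve.  The seed
   points are Z-score normalized; a small closed square grows by
   alternating point-to-curve projection, vertex-position optimization,
   insertion of a vertex into the worst-fitting segment, and removal of
   abnormal vertices (outside the data radius, or with fewer than 5
   projected points in their neighborhood), until the segment-count
   bound `is > β n^(1/3) Δn^(-1/2) r` (β = 0.3) or the improvement
   threshold Δs = 0.002 stops it.  The result is an ordered vertex
   sequence `(t_i, x_i, y_i)`, `t_i = (i-1)/m`.
2. **IAMCDE + ABPNN** -- a one-hidden-layer network
   `h_i = sigmoid(t ω_i - T_i)`, `g_k = tanh(Σ h_i a_ik - b_k)` maps the
   curve parameter to the two coordinates.  Its weights are initialized
   by an improved differential-evolution search (two randomized mutation
   operators chosen by a generation-dependent probability, plus a
   keep-best-half restart) and refined by full-batch backpropagation
   whose learning rate multiplies by 1.5 when the error falls and 0.5
   when it rises.  The trained weights define the closed-form contour
   `f(t) = (x(t), y(t))` via the output map `(1+g)/2`.

Masks rasterized from contours are scored with Dice, Jaccard, and pixel
accuracy; the curve-to-data distance Δf (mean squared distance from the
seed points to the fitted curve) measures fitting fidelity.  A synthetic
module generates star-shaped ground-truth contours, masks, and
radiologist-like seed points, so the whole pipeline is testable without
any clinical data.

## Worked example

```r
library(pcseg)

fx  <- make_fixture(shape_spec(), fraction = 0.08, jitter_sigma = 1, seed = 7)
seg <- segment_contour(fx$seeds, seed = 7)
seg
#> <pcseg_segmentation> 11 curve vertices -> 360 contour points; delta_f 1.66 -> 0.01174

glance(seg)
#> # A tibble: 1 × 8
#>   n_points n_vertices stopped_by     q init_error final_error delta_f_init delta_f_final
#>      <int>      <int> <chr>      <int>      <dbl>       <dbl>        <dbl>         <dbl>
#> 1       41         11 converged     10      0.693      0.0223         1.66        0.0117

evaluate_segmentation(seg, fx$mask)
#> # A tibble: 1 × 4
#>     dsc jaccard accuracy delta_f
#>   <dbl>   <dbl>    <dbl>   <dbl>
#> 1 0.935   0.878    0.959  0.0117
```

Reading the numbers: 41 seed points (8% of the dense truth contour,
jittered by 1 px) condense into an 11-vertex principal curve; the
evolution search leaves the network at error 0.693 and backpropagation
brings it to 0.022 (scaled units); the mean squared seed-to-curve
distance Δf falls from 1.66 (against the initial square) to 0.012, and
the final smooth contour overlaps the ground-truth mask with Dice 0.935.
`autoplot(seg, truth = fx$contour)` draws seeds, curve vertices, and the
fitted contour; `expression_text(seg$abpnn_fit)` prints the closed-form
expression, e.g.

```
x_t <- 128.378966... + 59.331659...*(-1.491283... + ((1 + tanh(1.849731...*
       1/(1 + exp(-(4.299698...*t - 7.817742...))) + ...
```

which re-evaluates to the same contour to 1e-9.

A thin command-line interface wraps the same functions:

```sh
exec/pcseg simulate --out sim --seed 7
exec/pcseg segment  --seeds sim/seeds.csv --out seg --seed 7
exec/pcseg evaluate --contour seg/contour.csv --mask sim/truth_mask.png \
                    --seeds sim/seeds.csv --out metrics.json
exec/pcseg express  --model seg/model.json --out expression.txt
```

## Main functions

| Function | Role |
|---|---|
| `make_fixture()`, `shape_spec()` | synthetic truth contours, masks, seed points |
| `fit_ccps()` | stage 1: closed principal curve and vertex sequence |
| `de_minimize()`, `de_config()` | DE / AMCDE / IAMCDE minimizer |
| `train_abpnn()`, `abpnn_config()` | stage 2: network training |
| `contour_function()`, `sample_closed_contour()`, `expression_text()` | closed-form contour |
| `segment_contour()` | the whole pipeline, seeds in, contour out |
| `evaluate_segmentation()`, `mask_metrics()`, `delta_f()` | evaluation |
| `pcseg_cli()` | command-line entry point (`exec/pcseg`) |

All fitted objects have `tidy()`, `glance()`, and `autoplot()` methods.
See `vignette("contour-fitting")` for the models, the numerical
decisions behind them, and known limitations.
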