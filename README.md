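# corticat

`corticat` is a simulator for a recurrent three-layer cortical-column
network that learns visual categories — and refines them into
subcategories — without any supervision. It is aimed at computational
neuroscientists studying the functional role of cortical feedback:
biased competition, predictive-coding residuals, and the
stability–plasticity dilemma in online category learning.

## The model in brief

Images drive a 100×100 input layer whose activities `s` are copied
one-to-one into layer 2 and divisively normalized (shunting inhibition,
solved at steady state):

    u_j = beta_u * s_j * (1 + lambda * res_j) / (alpha_u + q_j),
    q_j = sum_k Lambda_jk * g_u(u_k),          g_u(u) = max(u, 0)

Layer 3 holds M category cells with feedforward (fan-in) weights `w_in`
and feedback (fan-out) weights `w_out`:

    v_i = beta_v * sum_j g_u(u_j) * w_in[j,i] / (alpha_v + q_i),
    g_v(v) = 1 / (1 + exp(kappa_log * (mu_log - v)))

A winner-take-all picks the most active cell `k`. Its projective field
predicts the expected input, and the rectified prediction error

    res_j = [ g_u(u_j) - w_out[k,j] ]+

re-enters layer 2 as a multiplicative gain (the `1 + lambda * res_j`
term above): feedback can only amplify existing activity, never create
it. Per presentation the network runs one feedforward and one feedback
sweep; after each sweep only the winner learns:

* instar (Oja-type): `dw_in = eta_in * g_v * (g_u - g_v * w_in)` —
  energy-bounded prototype receptive fields;
* outstar: `dw_out = eta_out * g_v * (g_u - w_out)` — the expected
  average input, i.e. the prediction.

While a category's average sharpens, the residual concentrates on what a
particular exemplar adds to it; the amplified difference eventually
recruits an unused cell as that variant's subcategory cell, leaving the
established representation intact.

## Worked example

Train on the four barred squares, presented in blocks, with six category
cells (protocol 1), then read out what each cell has become:

```r
library(corticat)

fit <- run_experiment(preset(1, seed = 1))
glance(fit)
#> # A tibble: 1 × 8
#>   n_steps n_cells n_recruited n_unused n_overall n_subcategory n_ambiguous
#>     <int>   <int>       <int>    <int>     <int>         <int>       <int>
#> 1     800       6           5        1         1             4           0
#> # ℹ 1 more variable: mean_res_mass_tail <dbl>

classify_cells(fit)
#> # A tibble: 6 × 4
#>    cell role        category variation
#>   <int> <chr>       <chr>        <int>
#> 1     1 unused      <NA>            NA
#> 2     2 overall     B               NA
#> 3     3 subcategory B                3
#> 4     4 subcategory B                4
#> 5     5 subcategory B                2
#> 6     6 subcategory B                1
```

One cell (here cell 2) wins the feedforward sweep for *every* square —
it encodes the overall category (the shared outline). Four further cells
each win the feedback sweep for exactly one variant — they encode the
subcategories (the individual bars), and one cell was never recruited:
spare capacity for future categories. `probe_variants(fit)` shows the
winners per clean variant, `autoplot(fit)` the recruitment history, and
`plot_weights(fit, "w_in")` the learned receptive fields.

The feedback ablation (protocol 3, `lambda = 0`) collapses this
structure: the same run recruits exactly one cell and no subcategories.

A command-line interface wraps the same functions:

```sh
corticat run --experiment 1 --seed 1 --out runs/exp1
corticat render-stimuli --out stimuli --format png
```

(after installation, `exec/corticat` inside the installed package; each
run writes a `manifest.json` from which `run_from_manifest()` reproduces
the trace bit-identically.)

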