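# mlpard

Pixel-level mapping of invasive weed patches (milk thistle, *Silybum
marianum*, against mostly graminaceous vegetation) from three-band
multispectral imagery — green, red, near-infrared — fused with a 7×7
local-variance texture layer, using a multilayer perceptron regularised by
automatic relevance determination (MLP-ARD).

The package is aimed at remote-sensing / precision-agriculture analysts
who have gridded multispectral reflectance and polygon ground truth and
want a classifier that (a) fuses spectral and structural information and
(b) reports which inputs actually mattered. Because green and red
reflectance of the target weed and of drying grasses overlap almost
completely, the useful signal sits in the NIR band and in canopy texture;
ARD discovers that from the data instead of requiring manual feature
selection.

## The model

For labelled pixels $D = \{x_i, t_i\}$, $x_i \in \mathbb{R}^n$
(green, red, NIR, texture), $t_i \in \{0,1\}$:

$$y(x) = f_2(\upsilon\, f_1(u\,x)), \qquad
  f_1 = \tanh,\; f_2 = \text{logistic},$$

trained by minimising the penalised cross-entropy

$$F(\omega) = -\sum_i [t_i \ln y_i + (1-t_i)\ln(1-y_i)]
  + \sum_{k=1}^{n+3} \alpha_k E_w(k), \qquad
  E_w(k) = \tfrac12\sum_{j \in W(k)} \omega_j^2,$$

where the weight groups $W(k)$ are: one group per input feature (its
connections to all hidden units), the hidden biases, the hidden-to-output
weights, and the output bias ($n+3$ groups). The decay constants
$\alpha_k$ are re-estimated during training with MacKay's evidence
framework ($\gamma_k = |W(k)| - \alpha_k\,\mathrm{tr}_k(A^{-1})$,
$\alpha_k \leftarrow \gamma_k / 2E_w(k)$, $A$ the Hessian of $F$):
irrelevant features end with large $\alpha$ and crushed weights — a soft
feature selection. Inner optimization is a scaled-conjugate-gradient batch
minimiser; everything is deterministic under one master seed.

A seeded synthetic-scene generator (patchy two-class ground truth,
NIR-bright and high-texture target patches, nearly uninformative green/red
bands, pure-class survey polygons) stands in for UAV imagery so the whole
pipeline is testable without downloads.

## Worked example

```r
library(mlpard)
res <- run_pipeline(default_config(seed = 1))
res$confusion
#> Confusion matrix (rows = actual, columns = predicted; percentages on actual-class sums)
#>                        target              other
#>   target        136 ( 99.27%)        1 (  0.73%)
#>   other           0 (  0.00%)      143 (100.00%)
#>   overall accuracy: 99.64% (279/280 = 99.642857%)
res$relevance
#>   feature      alpha weight_norm rank
#> 1 texture 0.07318198   1.3222433    3
#> 2     nir 0.00001000   3.3105035    1
#> 3     red 0.22666910   0.1690806    4
#> 4   green 0.07120694   1.0621070    2
res$agreement_percent
#> [1] 98.54584
```

Reading the output: the pipeline simulated a 256×256 scene, sampled 1080
pixels from 17 + 13 pure-class polygons, balanced them to 936, split
70/30, trained MLP-ARD and deployed it on all 65,536 pixels. The held-out
confusion matrix shows one missed target pixel out of 280 (99.64%
overall); the relevance report shows NIR with the smallest hyperparameter
and the largest group weight norm (rank 1) and red with the largest
hyperparameter and a tiny norm (rank 4) — the inverse α–norm relation; the
whole-scene map agrees with the simulated ground truth on 98.5% of pixels
(disagreements cluster in the one-window-wide halo at patch boundaries,
where a 7×7 variance is intrinsically ambiguous).

`hinton_export()`/`hinton_text()` give the signed first-layer weight table
for reading feature–neuron synergy, and `save_mlp_ard()` /
`load_mlp_ard()` round-trip models bit-identically through a plain-text
format.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/mlpard run --seed 1 --out out_dir
Rscript inst/cli/mlpard simulate --seed 1 --out sim_dir
Rscript inst/cli/mlpard map --model out_dir/model.txt --scene sim_dir/scene.txt --out map_dir
```

## Package layout

- `R/` — generator, features, MLP-ARD core (SCG optimizer + evidence
  updates), evaluation, mapping pipeline, plain-text I/O.
- `tests/testthat/` — module tests, property tests (gradient vs finite
  differences, texture vs loop oracle, partition/decomposition laws,
  determinism) and end-to-end acceptance tests.
- `vignettes/mlp-ard-weed-mapping.Rmd` — the methods account: model,
  numerical choices, what the synthetic scenes do and do not emulate,
  limitations.
- `inst/cli/mlpard` — command-line wrapper.
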