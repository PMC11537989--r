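# flyhue

Chromatic tuning analysis for neurons of the *Drosophila* visual system:
a tetrachromatic color space built from opsin photon captures, response
indices and encoding models for calcium-imaging amplitudes, and a
twelve-neuron connectome-constrained recurrent circuit model with
perturbation experiments. A synthetic-data generator emulates the gamut
and contrast stimulus designs and dF/F traces, so the entire pipeline
runs end-to-end without any imaging data.

## Who this is for

Systems-neuroscience groups analysing color responses in the fly optic
lobe (photoreceptor terminals, Dm8/Dm9 interneurons, Tm projection
neurons), and modelers who want a compact, testable implementation of
hue-selectivity statistics and a fixed-point recurrent rate model
constrained by synaptic counts.

## The models at the core

**Color space.** A stimulus is its relative photon-capture vector
`q = (q_Rh3, ..., q_Rh6)` (background = 1), log-transformed as
`X = log((q + 0.001)/1.001)` and split into luminance
`l = X . u` (white axis `u = (1,1,1,1)/2`) and a chromatic 3-vector `x`
in a frozen tetrahedron basis; saturation `s = |x|`, hue its direction,
and `p . x = s cos(theta)` for a preferred direction `p`.

**Encoding models.** Linear `y = a_L p.x + b l`; linear-nonlinear with an
asymmetric saturating tanh; and the nonlinear hue-selectivity law

    y_i = (a_NL s_i^alpha / kappa) (exp(kappa cos(theta_i)) - 1) + b l_i

fitted over a log grid of `kappa` (hue sharpness, 20 steps in [0.01, 10])
and `alpha` (saturation exponent, 13 steps in [0.1, 10]), with
observation-count weights and a noise-corrected R².

**Indices.** Sparsity `1 - mean(|v|/max|v|)`, luminance invariance
(chromatic-vs-luminance regression R² ratio), and the hue sensitivity
index — the norm of the response-weighted vector sum of unit opponent
directions — with ROI bootstrap confidence intervals.

**Circuit model.** Twelve neurons (pR7, yR7, pR8, yR8, Dm9, pDm8, yDm8,
Tm5a, Tm5b, Tm5c, pTm20, yTm20) with dynamics
`tau dy/dt = -y + f(g (W y + j X + p x0))`, synaptic-count weights
row-normalized so `sum|w| + sum j = 1`, solved at steady state by
Anderson acceleration and fitted in three stages (29 free parameters) by
Adam with implicit differentiation through the fixed point. Perturbation
operators reproduce the model experiments: TeNT-style output silencing,
Tm-Tm recurrence ablation, sign search over free-sign edges, and a
random-weight null distribution.

## Worked example

Simulate the packaged example circuit (a synthetic, clearly-labelled
illustration of the medulla wiring motifs) on an isoluminant gamut and
quantify the hue tuning of the Tm5a analog:

```r
library(flyhue)

stim <- sampleGamut(150, iso_total = 5,
                    m = sessionObservationCounts(150, seed = 1), seed = 1)
spec <- exampleCircuitSpec()
resp <- simulateResponses(stim, spec, sigma = 0.1, n_roi = 4, seed = 1)

amp   <- SummarizedExperiment::assay(resp, "amplitude")
units <- SummarizedExperiment::rowData(resp)$unit
v     <- colMeans(amp[units == "Tm5a", ])

sparsityIndex(v)
#> [1] 0.6696685
fitSelectivity(stim, v, sigma2 = 0.01)
#> TuningFit <selectivity>  gain=0.003633  b=0.224  kappa=6.952  alpha=1.468
#>   p = (0.079, 0.989, -0.129)  R2 = 0.5650
fitLinear(stim, v, sigma2 = 0.01)@r2
#> [1] 0.3784948
```

The Tm5a analog responds sparsely (sparsity 0.67 versus 0.33 for the pR7
photoreceptor) and is far better described by the selectivity model
(kappa ≈ 7) than by the linear model, whereas the photoreceptor fit
lands at kappa ≈ 0.5 — the broad, quasi-linear regime. Zeroing the Tm-Tm
recurrence (`ablateRecurrence(spec)`) or silencing Tm5a's own output
(`simulateTent(spec, "Tm5a")`) and re-simulating collapses its fitted
kappa several grid steps toward the linear corner: in this model, hue
selectivity is created by recurrence, not inherited from the
feedforward drive.

The full desk-scale pipeline — stimuli, responses, indices, model fits,
report files — runs with `runPipeline(pipelineConfig(seed = 1))`.

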