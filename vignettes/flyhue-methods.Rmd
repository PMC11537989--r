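---
title: "Hue selectivity in the fly medulla: models and methods"
author: "flyhue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hue selectivity in the fly medulla: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyhue)
```

## The color space

Fruit flies sample the spectrum with four chromatic opsins (Rh3, Rh4, Rh5,
Rh6) expressed in the R7 and R8 photoreceptors of pale and yellow
ommatidia, plus the broadband Rh1 of R1-6. `flyhue` represents a stimulus
by its vector of relative photon captures $q_\mu$ (the adapting background
maps to $q = 1$), log-transformed as

$$X_\mu = \log\left(\frac{q_\mu + 0.001}{1.001}\right),$$

so the background sits exactly at the origin. The 4D vector $X$ is split
into a luminance component $l = X \cdot \hat u$ along the unit white axis
$\hat u = (1,1,1,1)/2$ and a 3D chromatic vector $\vec x = B(X - l\hat u)$,
where $B$ is a fixed orthonormal basis of the orthogonal complement
(frozen in `tetrahedronBasis()`); under $B$ the four opsin axes map to the
vertices of a regular tetrahedron. Saturation is $s = |\vec x|$ and hue is
the direction of $\vec x$; for a neuron with preferred unit direction
$\hat p$, $\hat p \cdot \vec x = s\cos\theta$. A 2D color-opponent
projection, $(\mathrm{Rh5{+}Rh6}) - (\mathrm{Rh3{+}Rh4})$ against
$(\mathrm{Rh4{+}Rh5}) - (\mathrm{Rh3{+}Rh6})$, is used for plotting and
for the hue sensitivity index.

Two conventions were genuinely open and are configuration rather than
assumptions baked in:

* **Opponent axes from $X$ or from $q$.** Both are linear difference
  formulas; `opponentProjection` takes whichever matrix you pass and the
  package default is $X$ (log captures), which keeps the white point at
  the origin.
* **The isoluminant constant.** Isoluminance is implemented as
  $\sum_\mu q_\mu = C$ with $C$ configurable; the default $C = 5$ matches
  a gamut centered on a total relative capture of five.

Opsin sensitivity curves come from a standard A1 visual-pigment nomogram
parameterized by $\lambda_{\max}$. The peak wavelengths shipped in
`defaultOpsinPeaks()` are deliberately documented as approximate fixtures:
they place the four opsins in the right spectral order for synthetic work
and should be replaced with calibrated values for real analyses.

## Synthetic data: what it emulates and what it does not

The generator reproduces the *design* of the imaging experiments:

* gamut stimuli drawn uniformly on the isoluminant simplex (symmetric
  Dirichlet scaled to $C$), with optional half-space clipping for hardware
  gamuts;
* session-style observation counts (`sessionObservationCounts`): each
  session covers about 20% of the stimuli with three repeats, so $m_i$
  varies across stimuli as in the real data;
* the greedy max-distance subsampling used to spread a session across
  color space (random first pick, then uniform choice among the ten
  farthest not-yet-chosen stimuli);
* a six-LED system with the published background (0.01, 0.06, 0.1, 0.25,
  0.33, 0.25 uE) and maximum (6, 7, 11, 18, 25, 160 uE) intensities but
  *synthetic Gaussian spectra* -- only the induced captures matter
  downstream;
* the contrast set: each LED or printed mixture stepped at 0.1, 0.3, 0.5,
  0.75, 1 and 3 uE on top of the background;
* response amplitudes equal to a ground-truth model's mean plus Gaussian
  noise of standard deviation $\sigma/\sqrt{m_i}$, and dF/F traces built
  as 0.5 s steps with slow drift and white noise.

It does **not** emulate calcium-indicator kinetics, photoreceptor
adaptation dynamics, movie-level artifacts (motion, bleed-through,
segmentation), or non-Gaussian noise. Passing tests therefore demonstrate
the correctness of the analysis chain and the qualitative circuit
mechanisms, not performance on raw imaging movies.

Stimuli sampled directly in capture space carry no spectrum, so the
achromatic (R1-6) input $x_0$ has no measured Rh1 capture. The package
uses the mean of the four chromatic captures as the Rh1 proxy -- a
broadband photoreceptor integrating across the spectrum sees roughly the
total photon content -- and takes $x_0$ as its log relative capture. When
stimuli are built from spectra or LED drives the Rh1 capture is computed
properly from its template.

## Signal extraction

`dffBaseline` subtracts the 25th percentile of a rolling 40 s window and
smooths with a third-order Savitzky-Golay filter of 0.5 s. Response
amplitude is the mean dF/F 0.35-0.5 s after stimulus onset minus the mean
0.35-0.1 s before; windows are closed intervals (boundary samples
included), a convention fixed for determinism, and the synthetic step
generator marks its steps closed to match. One caveat stated openly: on
*ideal square* steps a smoothing window as long as the step attenuates the
trailing read-out window, so round-trip tests on square steps disable
smoothing; real calcium transients decay slowly and are much less
affected.

ROIs are kept when $\mathrm{SNR} = \|v_{\mathrm{stim}}\|^2 /
\|v_{\mathrm{baseline}}\|^2 \ge 2$, with baseline amplitudes read from 100
randomly placed 0.15 s windows outside stimulation (the count and seeding
are package choices; the procedure only specifies random placement). The
per-observation noise power $\sigma^2$ is the mean squared baseline
amplitude. Response vectors are normalized as $v' = v / \sqrt{\tfrac{1}{N-1}
\sum_i v_i^2}$, so $\sum_i v_i'^2 = N - 1$.

## Tuning indices

* **Sparsity**: $1 - \tfrac1N \sum_i |v_i| / \max_j |v_j|$; 0 for equal
  responses, $1 - 1/N$ for a single responder, and $\approx 0.5$ for
  uniformly distributed amplitudes.
* **Luminance invariance**: the ratio of the no-intercept uncentered
  $R^2$ of a chromatic-only regression to that of a luminance-only
  regression. The denominator is floored at $10^{-6}$ with an explicit
  cap flag, since a chromatic neuron can leave essentially nothing for
  the luminance fit.
* **Hue sensitivity (HSI)**: opponent-plane stimulus vectors are scaled
  to unit direction; saturations are mapped to $[0,1]$ by the set maximum
  (pass `sat_max` when the stimuli are a subset of a larger design);
  stimuli at or above 0.5 scaled saturation, or at the white point, are
  dropped; then
  $h = \sum_i m_i \hat p_i y_i \big/ \sum_i m_i |y_i|$ and
  $\mathrm{HSI} = \|h\|_2$. A single-direction responder scores 1, a
  rotationally uniform one 0.

The noise-corrected goodness of fit is

$$R^2 = \frac{\left(\sum_i m_i y_i v_i\right)^2 -
  \frac{\sigma^2}{\bar m}\sum_i m_i y_i^2}
  {\sum_i m_i y_i^2 \sum_i m_i v_i^2 -
  \frac{\sigma^2(\hat m - 1)}{\bar m}\sum_i m_i y_i^2},$$

with $\bar m$ the mean and $\hat m$ the total observation count. The
typeset source of this correction can also be read with
$\sum_i m_i (y_i v_i)^2$ in the numerator; that literal reading is kept
behind `numerator = "literal"`, but the default is the form above -- the
only reading that is an $R^2$ (it reduces to the squared $m$-weighted
uncentered correlation at $\sigma^2 = 0$). Bootstrap intervals resample
ROIs with replacement (1,000 draws at full scale) and use percentile
limits.

## Encoding models

Three nested descriptions of a neuron's stimulus-response map:

1. **Linear**: $y_i = a_L\, \hat p \cdot \vec x_i + b\, l_i$.
2. **LNL**: the linear drive passed through a modified tanh
   $f(u) = a_{NL}(1 \pm \gamma)\tanh(u/(1 \pm \gamma))$ (the $+$ branch
   for $u \le 0$), continuous with unit slope at 0; $\gamma \in (-1, 1)$
   sets where each side saturates.
3. **Selectivity**: $y_i = \frac{a_{NL} s_i^\alpha}{\kappa}
   \left(e^{\kappa\cos\theta_i} - 1\right) + b\, l_i$, a von Mises-style
   tuning law where $\kappa$ is hue sharpness and $\alpha$ the saturation
   exponent. As $\kappa \to 0$ with $\alpha = 1$ it converges to the
   linear model; `kappa = 0` evaluates that analytic limit directly.

All fits weight stimuli by $m_i$. The linear fit is closed-form weighted
least squares with the chromatic coefficient norm reported as the gain.
The LNL fit runs quasi-Newton nonlinear least squares from the linear
solution with $\gamma = 0$ (up to 50 jittered restarts if it fails to
converge; $\gamma$ is parameterized through a scaled tanh to stay in its
open interval). The selectivity fit searches the published grid --
$\kappa$ over 20 log steps in $[10^{-2}, 10^{1}]$, $\alpha$ over 13 log
steps in $[10^{-1}, 10^{1}]$, endpoints inclusive -- solving for
$\hat p$ by quasi-Newton with $a_{NL}$ and $b$ profiled out at each grid
point ($b$ is refit per point), warm-starting along ascending $\kappa$,
and breaking ties toward smaller $\kappa$ (the simpler model). $\hat p$
is parameterized as an unconstrained 3-vector whose norm is absorbed by
the gain, avoiding angular degeneracies.

## The circuit model

Twelve neurons -- pR7, yR7, pR8, yR8, Dm9, pDm8, yDm8, Tm5a, Tm5b, Tm5c,
pTm20, yTm20 -- obey

$$\tau_a \dot y_a = -y_a + f\!\left(g_a\Big(\sum_b w_{ab} y_b +
\sum_\mu j_{a\mu} X_\mu + p_a x_0\Big)\right),$$

with $f$ the modified tanh at unit gain and per-neuron asymmetry
$\gamma_a$ (Dm9 fixed at 0). Each row of the weight matrix is normalized
so $\sum_b |w_{ab}| + \sum_\mu j_{a\mu} = 1$; Tm-Tm entries sum direct and
disynaptic synapse counts before normalization. Free weight magnitudes
(the shared opsin input $j$ and the two unreconstructed Dm8-Dm8
connections) are parameterized as fractions of the row budget, with the
count-derived entries rescaled to keep the normalization exact -- the
normalization is stated by the model, the interaction with free weights
is a package decision. The free parameters are 8 gains (photoreceptors
share one, Dm8s share one), 11 asymmetries, 1 opsin-input magnitude, 7
achromatic weights (two Dm8s, positive; five Tms, free sign) and the 2
Dm8-Dm8 weights: 29 in total, audited structurally by
`freeParameterAudit`.

**Steady states.** Measurements are modeled at equilibrium, so the ODE is
solved as a fixed point $y = f(g(Wy + jX + px_0))$ by Anderson
acceleration (memory 5, damping 1, at most 500 iterations, sup-norm
tolerance $10^{-4}$ by default; fitting uses $10^{-7}$). All stimuli are
solved simultaneously -- the stacked problem is block diagonal. When the
accelerated iteration stalls (at intermediate parameter values the map
can be locally expansive while the fixed point still exists), a damped
Newton solve with adaptive continuation in the gains takes over; the
start remains deterministic (zeros at zero gain). Parameter regions where
no steady state can be reached are treated as infeasible during
optimization: the loss is infinite and the batch update is skipped.

**Fitting.** The loss is the negative sum over neurons of the
$m$-weighted uncentered correlation between model and data -- calcium
amplitudes carry no absolute scale, so correlation is the right
objective. Gradients flow through the fixed point by implicit
differentiation: adjoint solves against the analytic Jacobian
$(I - \mathrm{diag}(f'g)W)^\top$, never by unrolling the solver; the
parameter Jacobian of the one-step map is taken by central differences on
that explicit map (cheap, $O(h^2)$, and independent of the solver).
Optimization is Adam with batches of 64 stimuli, learning rate 0.001, at
most 100 epochs, early-stopped on the full-data loss. Fitting proceeds in
three stages -- photoreceptors/Dm9, then Dm8s, then Tms. The staging of
the $\gamma$ parameters is not dictated by the procedure's description,
so each stage carries its own neurons' asymmetries (7 + 7 + 15 = 29).

**Perturbations.** `ablateRecurrence` zeroes the Tm-Tm block without
re-normalizing (the ablated circuit deliberately violates the row
budget); `simulateTent` zeroes one Tm neuron's outgoing weights, and
`refitTent` re-fits only that neuron's gain and asymmetry, as in the
corresponding experiments. `signSearch` enumerates the free-sign
recurrent edges exhaustively when $2^k$ fits the budget (seeded random
sampling otherwise). `randomWeightNull` redraws the Tm input weights from
a standard uniform on the same edges, re-normalizes, refits the Tm stage,
and returns the distribution of mean Tm $R^2$ with its 95th percentile;
the desk-scale default is 200 draws (the full-scale experiment uses
10,000). Null and reference refits both start from the same tame Tm
parameterization (unit gains, symmetric tanh) so the comparison isolates
the weight pattern and every draw is solvable; these short refits use a
larger learning rate (0.03, 25 epochs) so they are informative within the
step budget. Tm20 model responses are compared to data as the pale/yellow
column mixture $y = \tfrac13 y_{pTm20} + \tfrac23 y_{yTm20}$.

**The packaged example circuit** (`exampleCircuitSpec`) is synthetic and
labelled so: its synapse counts are illustrative integers (real counts
load via `circuitCountsFromTable`), but its motifs and sign constraints
follow the biology -- photoreceptors drive Dm9 which inhibits them back;
R7s inhibit their home-column Dm8s, which receive excitatory R1-6 input
and inhibit each other; R7/R8 inhibit Tm5a, Tm5b and the Tm20s while R8
excites Tm5c; pDm8 excites Tm5b, yDm8 inhibits Tm5a. The counts, gains
($g_{Tm} = 3$), Tm asymmetries ($\gamma_{Tm} = -0.7$, compressing
hyperpolarization while leaving depolarization expansive), Tm
self-excitation and tonically active Tm5c inhibition were chosen once so
that the circuit is stable and recurrent interactions sharpen hue tuning
-- the mechanism the model probes. On this circuit the fitted $\kappa$ of
the Tm5a/Tm5b analogs exceeds the photoreceptors' several-fold, and both
recurrence ablation and TeNT-style output silencing broaden them, while
time constants are irrelevant at steady state ($\tau = 0.05$ s is kept
for the integration oracle).

## Interpolation and spectral classification

Tuning surfaces over 4D log-capture space (training on gamut plus
contrast sets, which enlarges the hull) use exact thin-plate-spline
interpolation with the constant term removed -- amplitudes are
baseline-subtracted, so no offset is warranted; the degree-one polynomial
tail is kept. Query points are first projected onto the convex hull of
the training set. Because no installed package provides a no-bias exact
RBF interpolant or 4D hull operations, both are implemented directly: the
kernel system is solved dense (with a relative ridge fallback for nearly
coincident designs), and the nearest-point hull projection is solved as a
simplex-constrained least-squares via nonnegative least squares with a
weighted equality row and tiny Tikhonov rows for conditioning. The frozen
contract is behavioral: exact interpolation at nodes, idempotent
nearest-point projection.

Spectral tuning curves evaluate the interpolant along the locus of 10
nm-wide Gaussian lights with peaks from 320 to 580 nm, normalized to the
isoluminant constant; nonspectral curves follow straight capture-space
segments between the single-wavelength points of maximal excitation of
each nonadjacent opsin pair (Rh3-Rh5, Rh3-Rh6, Rh4-Rh6), renormalized to
isoluminance and parameterized by mixture fraction. A neuron is
nonspectral when its peak response along any mixture line exceeds its
peak along the single-wavelength line.

## Numerical choices and desk-scale sizes

Tolerances: fixed point $10^{-4}$ (reporting) / $10^{-7}$ (fitting) /
$10^{-8}$-$10^{-10}$ (oracle comparisons); round-trip identities asserted
at $10^{-10}$; hull membership at $10^{-4}$. Test and example problem
sizes are deliberately desk-scale -- 80-150 gamut stimuli, 100-200 null
draws, 100 recovery replicates, bootstrap coverage at reduced replicate
counts -- chosen so the whole suite runs comfortably on one CPU while
every scaled-down experiment keeps the full-scale design's structure; the
full-scale values (10,000 null draws, 1,000 bootstrap iterations,
exhaustive sign search) remain available through arguments.

## Known limitations

* The indicator nonlinearity and temporal kinetics are out of scope; the
  Gaussian amplitude-noise model is what justifies the additive noise
  correction.
* The example circuit demonstrates mechanisms; none of its numbers are
  estimates of biological parameters.
* The hull projection returns the nearest point to working precision
  ($\sim 10^{-4}$ relative), which is ample for curve evaluation but not
  a certified geometric kernel.
* With square synthetic steps, Savitzky-Golay smoothing biases the late
  response window (see above).
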