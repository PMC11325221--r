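---
title: "Models and methods behind desstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind desstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desstab)
```

`desstab` implements a screening-to-model workflow for choosing deep
eutectic solvents (DES) that stabilize enzymes: polarity descriptors of the
solvent mixtures, first-order inactivation kinetics of the enzymes stored in
them, and neural-network QSPR models linking the two. This vignette explains
each model, its assumptions, the tunable parameters, and the numerical and
design choices, so that results can be interpreted — and distrusted — for
the right reasons.

## Sigma-profiles and the ten S-descriptors

A sigma-profile is the histogram of a molecule's COSMO screening-charge
density $\sigma$ over its surface: for each $\sigma$ (e/Å²) on a uniform
grid, the surface area (Å²) carrying that polarity. Hydrogen-bond acceptors
show peaks at negative $\sigma$, donors at positive $\sigma$, and nonpolar
surfaces near zero. `desstab` treats profiles strictly as discrete
histograms, the form in which COSMO tools emit them: "area under the curve"
is summation of per-point area weights, which is exact for gridded data and
avoids committing to any quadrature rule.

The descriptor map divides $[-0.025, +0.025]$ e/Å² into ten regions of
width 0.005 and sums the area in each, giving $S^1 \dots S^{10}$. Three
conventions matter and are fixed here:

* a grid point lying exactly (tolerance $10^{-12}$, absolute) on an interior
  boundary contributes half its area to each neighbouring region — the
  discrete operationalization of "evenly split";
* points exactly at $\pm 0.025$ belong wholly to regions 1 and 10;
* mass strictly outside the range accumulates in `truncated_mass`, with a
  warning, and is *not* folded into the edge regions. Ten regions are defined
  over a fixed range; silently reassigning tail mass would bias $S^1$ and
  $S^{10}$. Conservation — $\sum_i S^i + \text{truncated} =$ total area to
  $10^{-9}$ relative — is asserted property-style over seeded random
  profiles.

File ordinates may be areas per grid point or area densities; the two differ
by the grid spacing and cannot be distinguished from the numbers alone, so
`read_sigma_profile()` requires the convention to be declared (`"area"` or
`"density"`) and never guesses.

## From recipes to mixture descriptors

A DES recipe is a set of constituents with molar parts (e.g. ChCl:Gly 1:2)
plus a water content in weight percent. On a basis of the stated parts, with
$w$ the water mass fraction,

$$ n_\mathrm{water} = \frac{w}{1-w}\,
   \frac{\sum_j \mathrm{parts}_j M_j}{M_\mathrm{water}}, \qquad
   X_j = \frac{\mathrm{parts}_j}{\sum_j \mathrm{parts}_j + n_\mathrm{water}}. $$

Molar masses are required; a small table ships for the screening library's
six constituents (betaine, choline chloride as an ion pair, ethylene glycol,
propylene glycol, glycerol, urea) and water, and anything else must be given
explicitly — silent defaults for arbitrary chemicals invite wrong
compositions. Whether the original hydrated compositions were derived by this
conversion or pre-tabulated is not recorded anywhere authoritative, so the
conversion is exposed and overridable rather than buried.

Mixture descriptors follow the linear mixing rule
$S^i_\mathrm{mix} = \sum_{j=1}^{NC} X_j S^i_j$, the sum running over all
constituents including water; ternary mixtures need no special casing.
Linearity in $X$ and the single-constituent identity are asserted exactly.
The mixing rule ignores all excess interactions between constituents — it is
a composition-weighted average of pure-component surfaces, not a model of
the hydrogen-bond network — which is precisely why it is cheap enough for
screening.

`des_library_screening()` encodes the ten-system screening grid (betaine- and
choline-chloride-based, three water levels 10/30/50 wt%, with the
betaine:urea 1:3 system solid below 50 wt%), yielding the 28 liquid
formulations; labels follow the `DES <system>.<level>` convention.

## Inactivation kinetics

Residual activity is a percentage of the activity measured 20 min after
preparing the enzyme stock (time zero, exactly 100 by definition). Decay is
modelled first-order,

$$ A_R(t) = A_{R,0}\, e^{-kt}, \qquad t_{1/2} = \ln 2 / k, $$

fitted by Levenberg–Marquardt nonlinear least squares (`minpack.lm`),
initialized from a log-linear regression on the strictly positive residuals,
with up to five jittered restarts. Control settings: relative convergence
$10^{-10}$ on both parameters and objective, 200 iterations per attempt.
Times are in days; `k` is reported per day and per hour side by side because
rate constants are conventionally quoted per hour while sampling spans
weeks — keeping both units first-class avoids silent 24× errors.

Choices worth knowing:

* **Free intercept.** $A_{R,0}$ is fitted, not pinned at 100;
  `fix_intercept = TRUE` exists for sensitivity checks. With early points
  censored (below), a pinned intercept would force bias into $k$.
* **Censoring.** Early residuals in DES often exceed 100% before decaying
  ("overstabilization"); a first-order model cannot represent that, so
  `censor_series()` drops points above 100% at $t>0$. Note the measured side
  effect: under symmetric multiplicative noise, censoring also removes
  legitimate upward noise near 100% and biases $\hat k$ slightly downward
  (about −2% median at 5% noise in our simulations). The recovery suite
  therefore separates the two concerns: estimator bias is measured on
  uncensored series, and censoring has its own worked-example tests.
* **Resolution ceiling.** A series that is zero from the second point onward
  decays faster than the cadence can resolve; the fit returns the sentinel
  $k = 51\,\mathrm{h}^{-1}$ with flag `faster_than_resolvable` rather than
  failing, mirroring the ceiling values such screens report. Zero residuals
  elsewhere are retained — they are informative about fast decay.
* **Precision limits.** At the screening cadence (five points on day one,
  daily to day 7, then weekly, truncated at the 50% crossing or 28 days)
  with 5% multiplicative noise, the median *absolute* relative error of
  $\hat k$ is about 3.5% — and simulation shows a maximum-likelihood
  log-scale fit does no better, so this is an information limit of the
  design, not of the optimizer. The estimator is, however, nearly unbiased:
  the median *signed* relative deviation is well under 1%, which is what the
  recovery tests assert.

## The QSPR model

The modelling assumption is that the inactivation rate constant is a smooth
function of the ten mixture descriptors,
$k = f(S^1_\mathrm{mix}, \dots, S^{10}_\mathrm{mix})$, approximated by a
single-hidden-layer perceptron.

**Response transform.** Rate constants span roughly $2\times10^{-4}$ to
$51\,\mathrm{h}^{-1}$ — five decades. Raw sum-of-squares training would be
dominated entirely by the fastest decays, so the default training response
is $\log_{10} k$, inverted on prediction; raw-`k` mode is retained for
fidelity experiments.

**Input selection.** Spearman rank correlation of each descriptor with the
(transformed) response, with average ranks for ties; constant columns are
reported as $\rho = 0$ and flagged. Descriptors with $|\rho|$ at or above a
threshold are kept. The threshold default is 0.4 — the selected input sets
of the original screen (8, 6 and 3 descriptors for the three enzymes) are
stated without their cutoff, so the value here is configurable and the
default is simply a moderate-correlation convention.

**Splitting.** Data are divided into a calibration set (count or fraction;
55 of 84 in the screen this package mirrors) and a fully held-out prediction
set, with the calibration set subdivided 70/15/15 into training, test
(early stopping) and validation (model selection) blocks; within-calibration
counts are floor-based with the remainder to training. Every block is a
seed-reproducible, disjoint, exhaustive partition.

**Training.** Plain batch gradient descent by backpropagation on the
sum-of-squares error — deliberately the simplest defensible reading of
"back error propagation" — with early stopping on the test block (the
returned weights are those of the best test-error epoch) and restarts at
half the step on divergence. Momentum exists but is off by default. Inputs
are z-scored on the training block. The response is mapped linearly onto
$[0.2, 0.8]$ of its training range so that saturating output activations
(logistic, tanh) can reach every target and the exponential output cannot
overflow; the map is stored in the model and inverted on prediction (for
identity outputs it is a harmless affine reparameterization). Exponential
activations clip their pre-activation at $\pm 30$. Weights initialize
uniform $\pm 1/\sqrt{\text{fan-in}}$ from the model seed.

**Architecture search.** Candidates are sampled uniformly from the stated
space — hidden width 4–13, hidden and output activations from identity,
logistic, tanh, exponential — trained with early stopping, and ranked by
validation $R^2$. The search, weight draws and splits all flow from explicit
seeds; a repeated search is bitwise identical. The training schedule the
package uses for its own end-to-end recovery runs is 8000 epochs with
patience 400 at step 0.1: plain gradient descent is slow, and shorter
budgets measurably underfit smooth truths on some realizations. The original
screen's schedule is unknown; these defaults are documented as ours, not
claimed as anyone else's.

## Evaluation and classification

On the held-out prediction set, with residuals $e = y - \hat y$:
$\mathrm{RMSEP} = \sqrt{\sum e^2 / n}$; bias $= \bar e$;
$\mathrm{SEP} = \sqrt{\sum (e - \bar e)^2 / (n-1)}$ (bias-corrected
scatter); $\mathrm{RPD} = \mathrm{SD}(y)/\mathrm{SEP}$;
$\mathrm{RER} = \mathrm{range}(y)/\mathrm{SEP}$; and
$R^2_{pred,adj} = 1 - (1 - R^2_{pred})(n-1)/(n-p-1)$ with $p$ the number of
model inputs (undefined and flagged when $n \le p+1$). SEP is the
denominator of RPD and RER by default, the standard chemometric definition;
because published values do not always say which denominator was used, an
RMSEP-denominator variant sits behind a flag for sensitivity analysis.

Classification bands: RPD below 1.4 non-reliable, 1.4–2 (closed on both
ends) fair, above 2 excellent; RER above 4 usable for screening, above 10
for quality control, above 15 for quantification (strict inequalities,
highest band wins); a model is "substantial" when $R^2_{pred} > 0.75$. Note
that an RPD of 1.198 falls below 1.4 and is classified non-reliable — by the
band definition itself — even where such models are elsewhere discussed
among the "fair" ones.

## The synthetic-data generator

Grading one's own pipeline requires inputs with known answers. The generator
emulates the statistical *structure* the analysis assumes, not the chemistry
of named constituents:

* **Profiles** are sums of Gaussians on the descriptor grid (default step
  $5\times10^{-4}$ e/Å², total area uniform in 50–150 Å²): acceptor mass
  centred at negative $\sigma$ (≥ 60% below zero), donor mass mirrored
  positive, water bimodal in both signed tails, peak centres jittered per
  seed. Synthetic molar masses are uniform in 50–200 g/mol.
* **Libraries** mirror the screen's shape (default 10 systems × 3 water
  levels − 2 solid cells = 28 formulations); all descriptors are computed
  through the real integration and mixing code, never re-derived inside the
  generator.
* **Decay series** follow the screening cadence with multiplicative Gaussian
  noise (default 5%) and, with probability 0.3, one to three early points
  inflated to 105–140% to exercise censoring. The generator guarantees at
  least three sub-100% points per series so every series it emits remains
  fittable after censoring. The time-zero point is exactly 100.
* **Ground truths** map descriptors to $\log_{10} k$ either linearly in a
  planted subset or through a shallow tanh network inside the model search
  space, affinely rescaled so rate constants land in a fittable 0.02–4
  day⁻¹ range. For planted-recovery tests, `synth_descriptor_matrix()` draws
  tables whose planted columns share a latent factor (pairwise $r = 0.5$):
  real mixture-descriptor tables are exactly such correlated blocks
  (polarity regions co-vary with composition), and the within-block
  correlation is what makes each member of an informative block individually
  detectable by a marginal rank test. With three *independent* planted
  descriptors the marginal Spearman correlation is bounded near
  $1/\sqrt{3}$, which no threshold near 0.5 can separate reliably at
  $n = 84$.

What passing these tests shows — and what it does not: recovery on synthetic
data demonstrates that the pipeline's estimators and selection behave
correctly when their assumptions hold (exponential decay, multiplicative
noise, smooth descriptor–rate map, linear mixing). It says nothing about
whether real enzyme inactivation is first-order, whether real
"overstabilization" is ignorable, or whether ten integrated polarity regions
suffice to describe a real solvent's interactions with a protein.

## Problem sizes and reproducibility

The package's own recovery runs use 1000 random profiles for conservation,
200 decay series for estimator bias, and an 84-row library (28 systems × 3
water levels) for the end-to-end chain — large enough for stable medians and
an informative validation block, small enough to run in seconds. Every
random draw (profiles, libraries, noise, splits, architectures, weights)
descends from explicit integer seeds; repeated runs are byte-identical, and
the pipeline driver records the configuration hash and seed in its manifest.

## Known limitations

* Single-exponential kinetics only; biphasic inactivation, temperature
  dependence and the mechanism of overstabilization are out of scope.
* The linear mixing rule ignores excess interactions; descriptors of
  strongly non-ideal mixtures will be misestimated in a way no downstream
  model can repair.
* Plain gradient descent is slow by modern standards; it is kept because the
  procedure it mirrors specified backpropagation with a sum-of-squares
  error, and budgets are documented. Swapping the optimizer would change
  none of the interfaces.
* With ~28 rows per enzyme, validation blocks are small and model-selection
  variance is real; the package mitigates with seeded splits and a
  leaderboard rather than pretending the winner is uniquely best.
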