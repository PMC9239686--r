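---
title: "Batch contextual Bayesian optimization of a differentiation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch contextual Bayesian optimization of a differentiation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpeopt)
```

## The problem

Inducing iPSC differentiation into retinal pigment epithelium (RPE) is
controlled by a handful of protocol parameters — reagent concentration and
exposure periods, the mechanics of cell detachment at passage, and medium
taper schedules. The outcome of one choice of parameters is a *pigmentation
score*: the fraction of a culture well's area occupied by pigmented
(melanin-producing) cells about five weeks later, a number in $[0, 1]$.
Each evaluation therefore costs roughly 40 days, runs are performed 48 at a
time (eight 6-well plates), and the discretized parameter space holds about
$2.5 \times 10^8$ combinations. `rpeopt` implements the search engine for
this setting — batch Bayesian optimization with a contextual parameter —
plus the image-based scorer and a synthetic closed loop so the whole system
can be exercised and benchmarked on a desk.

## Search space

The seven protocol parameters and their grids are built by
`default_search_grid()`:

| code | meaning                                   | levels            | unit |
|------|-------------------------------------------|-------------------|------|
| PC   | FGFRi preconditioning concentration       | 0–505, step 5     | nM   |
| PP   | FGFRi preconditioning period              | 1–6               | day  |
| DP   | detachment trypsin period (contextual)    | 5, 8, …, 23       | min  |
| DS   | detachment pipetting strength             | 10–100, step 1    | mm/s |
| DL   | detachment pipetting length               | short / long      | —    |
| KP   | KSR taper period                          | 1–19              | day  |
| 3P   | Y/SB/CKI supplement period                | 3–19              | day  |

The published ranges for PC and DS are continuous; their step sizes are a
package convention chosen so the total cardinality (251,839,224) sits in
the documented "about 200 million" regime, and both are overridable in
code and in config files. Conditions are encoded to the unit cube — each
parameter mapped linearly with min level at 0 and max at 1, the two DL
categories at 0 and 1 — which is the coordinate system used by the kernel,
the penalizer distances, and the Lipschitz estimate. Decoding snaps to the
nearest level and resolves exact ties to the *lower* level so round trips
are reproducible.

The trypsin period DP is *contextual*: within a round the apparatus
realizes it only as an ordered window of six values, 3 minutes apart,
shared across plates (well 1 of every plate gets the first value, and so
on). The window is a first-class object (`context_window()`) whose
invariants — increasing, grid-spaced, on-grid — are enforced everywhere.

## Surrogate model

The surrogate is GP regression with an ARD-RBF kernel on the encoded
conditions,

$$k(x, x') = \sigma_f^2 \exp\!\Big(-\tfrac12 \sum_{j=1}^{7}
  \frac{(x_j - x'_j)^2}{\ell_j^2}\Big),$$

with a *fixed* observation-noise variance of 0.0039 (score units squared) —
the replicate spread measured across baseline plates — at every point of
the space. Only the lengthscales $\ell_j$ and signal variance $\sigma_f^2$
are fitted, by maximizing the log marginal likelihood with multi-restart
L-BFGS-B (5 seeded restarts by default; lengthscales bounded to
$[10^{-2}, 10]$ in unit-cube coordinates, signal variance to
$[10^{-6}, 25]$). The prior mean is a constant equal to the mean observed
score: scores live in $[0, 1]$, so a zero mean would systematically bias
predictions in unexplored regions. Whether the original system centered its
scores is not something the package takes a position on; the constant mean
is our convention and is configurable.

Numerical choices: a jitter of $10^{-8}$ is added to the Gram diagonal;
posterior standard deviations are of the latent (noise-free) response;
negative variances from floating-point cancellation are clamped at zero.
Degenerate inputs: an empty observation set is an error instructing the
caller to use uniform initialization; rows with missing scores (a well that
could not be validated) are dropped with a warning; duplicated conditions
are legal — the fixed noise model absorbs replicates. If every ML-II
restart fails or degrades the marginal likelihood, the starting
hyperparameters are kept, so fitting never silently returns a worse model.

## Acquisition and the batch policy

The acquisition is expected improvement for maximization,
$\mathrm{EI}(x) = (\mu - y^{+})\Phi(z) + \sigma\,\phi(z)$ with
$z = (\mu - y^{+})/\sigma$, degenerating to $\max(\mu - y^{+}, 0)$ at
$\sigma = 0$. The incumbent $y^{+}$ is the maximum *observed* score rather
than the maximum posterior mean — simpler, and robust to the noise level
here.

A round needs 48 simultaneous queries that respect the context structure,
which is the job of the batch contextual local penalization (BCLP) policy
in `generate_batch()`:

1. EI is mapped through a softplus to a strictly positive utility
   $\tilde\alpha_0 = \log(1 + e^{\alpha})$. Softplus is monotone, so the
   argmax is untouched; positivity is what makes multiplicative
   penalization meaningful.
2. Well slots are visited in ascending context order (plates inner). For
   each slot, the condition maximizing the running penalized utility is
   selected with DP pinned to the slot's window value; the running utility
   is then multiplied by a soft local penalizer centered on the selection,
   $\varphi(x) = \Phi\big((\hat L\,\lVert x - x_c\rVert - y^{+} +
   \mu(x_c)) / (\sqrt2\,\sigma(x_c))\big)$, which is smallest at the
   selected point and tends to 1 far away.
3. $\hat L$ is the maximum posterior-mean gradient norm over a seeded
   sample of 2,000 grid points (central finite differences in the unit
   cube), floored at $10^{-4}$ so a flat posterior cannot produce a
   division by zero.

Maximization over the $\sim 3.6 \times 10^7$ free-parameter combinations
per context value is by seeded candidate pools plus one coordinate-wise
hill-climb sweep (each free parameter scanned over its full level list in
turn); full enumeration is available for reduced grids and is used in the
tests to verify that the first selected point equals the brute-force EI
argmax. Already-selected conditions are masked from the pool by default.
The loop order (wells outer, ascending DP) matches the context-ordered
fill of the batch; a plate-outer order is config-selectable and produces
the same set of slots.

After scoring a round, the two plan slots at the (plate, well) positions
of the previous round's two best scores are overwritten with those two
conditions verbatim as positive controls (`inject_controls()`), ties
broken by (plate, well) ascending. A control re-runs the old condition
exactly, so its DP may differ from its well's window value — the context
invariant applies to generated slots only.

## Context-window adjustment

Between rounds the trypsin window may stay or translate by one 3-minute
step (`adjust_context()`). For the current window $c$ and the shifted
candidates $c \pm \Delta c$, the acquisition is integrated over the free
parameters at each context value — approximated by the mean over a shared
set of Monte-Carlo draws (10,000 per context value by default; campaigns
use 500, see below) — giving masses $V$, $V_-$, $V_+$ and ratios
$R_\pm = V_\pm / V$. The rule: stay if $\max(R_-, R_+) < 1.05$; otherwise
shift down if $R_- > R_+$, else shift up (an exact tie shifts up, reading
the $R_- \le R_+$ branch literally). Boundary behavior is a design choice:
a candidate entry outside the DP range contributes zero mass, which keeps
the ratios well-defined and biases the rule against infeasible shifts; in
the rare case an infeasible shift still wins, the decision degrades to
*stay* with a warning so the returned window always satisfies its
invariants. $V = 0$ also degrades to *stay* with a warning. The initial
window defaults to $\{5, 8, 11, 14, 17, 20\}$ minutes; with six wells on
the seven-level DP grid only two window positions exist, so one shift
saturates the range.

## Pigmentation scoring

`score_image()` computes the pigmented-area fraction of a well photograph
in a fixed order: Gaussian blur (sigma 2 px); background estimation by
grayscale morphological closing with a disc structuring element (radius
64 px by default) and subtraction — a rolling-ball-style estimate of the
illumination field across the dark pigment blobs; binarization of the
background-minus-image difference at a constant threshold of 40 grey
levels; crop to the well disc; count. Closing recovers a smooth
illumination field exactly on planar gradients and absorbs constant
offsets, so scores are invariant to illumination shifts of tens of grey
levels. The structuring radius must exceed the largest distance from any
disc pixel to background — for the default 56-px disc, 64 px guarantees
this; rasters smaller than the element fall back to the largest odd
element that fits.

The synthetic generator (`synthesize_well_image()`) renders what the
scorer needs to be tested against: a bright plate (mean 170 grey) with a
±15-grey linear illumination gradient, Gaussian pixel noise (sd 4), and
dark pigment blobs 80 grey levels deep covering an exactly counted
fraction of the disc — blobs are grown by ranking disc pixels on jittered
distance to random seed points and taking exactly the first
$\lceil f \cdot |{\rm disc}| \rceil$, so the truth mask is exact and masks
of increasing fraction are nested for a fixed seed. The 40-grey threshold
sits at half the 80-grey pigment depth, which makes the blur-smeared blob
boundary unbiased; the recovery error across fractions 0.1–0.9 is
MAE $\le$ 0.03 in the tests (typically below 0.01). What the generator
does *not* emulate: real optics (vignetting, specular reflections, menisci),
partially pigmented or out-of-focus cells, and debris; passing the
recovery tests therefore shows the pipeline's constants are coherent, not
that they reproduce the original camera setup, whose constants are
unpublished. Per-cell pigmentation intensity is explicitly out of scope —
the score counts area above threshold, not how dark each cell is.

## The closed loop and the synthetic oracle

`run_campaign()` wires the pieces together: round 1 samples uniformly
(context window applied per well); each later round fits the surrogate on
all data, generates the BCLP batch, injects controls, observes all 48
wells, and decides the next context window. Every source of randomness
derives from the single campaign seed. A failure while planning a round
aborts with the partial history preserved. The history keeps each round's
plan, observations, window, and context decision, plus the best-so-far
trajectory (a running maximum by construction).

The oracle (`toy_response()`) is this package's own documented stand-in
for the unpublished test function used to validate the original
optimizer: a product of per-parameter Gaussian bumps in encoded
coordinates with floor 0.05 and maximum 0.95 at PC = 305 nM, PP = 4 d,
DP = 14 min (echoing the baseline's best trypsin time), DS = 40 mm/s,
DL = long, KP = 10 d, 3P = 11 d. Bump widths (0.5–0.6 per encoded
dimension, 1.4 for the binary DL) were set so that uniformly sampled
conditions score $0.37 \pm 0.13$ — the regime real pre-optimized plates
occupied — while scores above 0.85 are confined to a basin occupying
$\sim 6 \times 10^{-4}$ of the space, mirroring how far the reported round
bests (0.86–0.91) sat above typical wells. Observations add Gaussian noise
of variance 0.0039 and clip to $[0, 1]$.

## Simulation-study scale

The benchmark configuration used by the tests and the acceptance script
runs 20 paired seeds of: a 3-round campaign (48 wells per round, 144
evaluations) against uniform random search at the same total budget.
Within campaigns the policy samples 1,500 candidates per context value
(plus the hill-climb sweep), the surrogate uses 5 ML-II restarts, and the
context decision uses 500 draws per context value. These sizes are the
package's documented simulation scale: they make a 20-campaign benchmark
a few minutes of computing while leaving the benchmark's verdict —
median final best around 0.93 versus 0.80 for random search, with BCLP
winning the large majority of paired seeds — stable across master seeds.
The exported defaults for one-off calls are larger (e.g. a 100,000-point
pool in `policy_config()`), appropriate when a single batch is being
planned for a real round.

## Known limitations

* The optimizer's acceptance is against the synthetic oracle; nothing here
  claims to reproduce wet-lab scores, which require living cells.
* The GP treats the binary DL level as a numeric coordinate on $\{0, 1\}$;
  no categorical kernel is attempted.
* Noise is homoscedastic by design (a single fixed variance everywhere);
  heteroscedastic extensions are out of scope.
* The context machinery is specific to a single contextual parameter with
  an arithmetic grid.
* The scorer's constants are calibrated on the synthetic generator; exact
  numeric reproduction of published photograph scores is not attempted.
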