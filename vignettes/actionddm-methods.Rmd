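---
title: "Modeling the Probabilistic Reward Task with a response-outcome RL drift diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the Probabilistic Reward Task with a response-outcome RL drift diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actionddm)
```

## The task and the model

The Probabilistic Reward Task (PRT) is a signal-detection assay of reward
learning. On each trial the participant sees one of two barely
distinguishable stimuli (conventionally, a cartoon face whose mouth is short
or long) and identifies it with a button press under a 2 s deadline. A
session has two 100-trial blocks; within each block the two stimuli appear
equally often, but correct identifications of one stimulus (the "rich" one)
are rewarded three times as often as correct identifications of the other
(the "lean" one). Participants are not told about the asymmetry. Healthy
participants typically develop a *response bias*: they come to press the
rich button more often — and faster — than the lean one, regardless of which
stimulus was actually shown. A blunted response bias is a widely replicated
behavioral correlate of depression and anhedonia.

This package implements a model of that behavior, the **Action-DDM**, which
couples response-outcome reinforcement learning to a diffusion decision
process. The agent maintains an expected value for each *response* (not each
stimulus): after every trial on which the response `resp` was made and
feedback `r` (1 = rewarded, 0 = not) was delivered,

$$Q_{t+1}(\mathrm{resp}) = Q_t(\mathrm{resp}) + \alpha\,(r - Q_t(\mathrm{resp})),$$

with learning rate $\alpha \in [0,1]$ and both values initialized at 0. The
value difference $\Delta Q_t = Q_t(\mathrm{rich}) - Q_t(\mathrm{lean})$
modulates the decision process in two ways. It shifts the drift rate toward
the higher-valued response,

$$v_t = s \cdot v_{\mathrm{intercept}} + B_v \, \Delta Q_t,
\qquad s = \begin{cases} +1 & \text{rich stimulus} \\ -1 & \text{lean stimulus}, \end{cases}$$

and it biases the starting point of the accumulator through a softmax of the
two values, which reduces to a logistic of the value difference:

$$z_t = \frac{e^{B_z Q_t(\mathrm{rich})}}
            {e^{B_z Q_t(\mathrm{rich})} + e^{B_z Q_t(\mathrm{lean})}}
      = \mathrm{logistic}(B_z \, \Delta Q_t) \in (0, 1).$$

Choices and response times are then generated by a Wiener diffusion between
a lower boundary (lean response) and an upper boundary (rich response) with
separation $a$, relative starting point $z_t$, drift $v_t$ and non-decision
time $t$. At the start of the task $\Delta Q = 0$, so $v_t = \pm
v_{\mathrm{intercept}}$ and $z_t = 0.5$: the model begins as an unbiased
perceptual decision maker and acquires its bias from reinforcement history.
The trial-level likelihood of an observed (response, RT) pair is the Wiener
first-passage-time (WFPT) density at the corresponding boundary.

### The drift sign convention

The drift equation above applies the stimulus sign $s$ to the intercept
only. A growing $\Delta Q$ therefore raises the signed drift on *both*
stimulus types: it speeds and improves rich-stimulus decisions while slowing
and impairing lean-stimulus ones, which is exactly the asymmetric accuracy
pattern the task elicits. The alternative reading — signing the whole sum,
$v_t = s(v_{\mathrm{intercept}} + B_v \Delta Q)$ — would instead make a
positive $\Delta Q$ *help* lean-stimulus accuracy, erasing the signature the
$B_v$ mechanism exists to produce. We adopt the first convention as the
default and expose the second behind the `sign_whole` flag of
`subject_loglik()`, `trial_latents()` and the simulator, so the two
resolutions can be compared on any dataset.

Other likelihood conventions: rewards are coded 0/1 (not in cents); trials
without a response (deadline reached) are retained in the data but excluded
from the likelihood, as are QC-invalid trials; feedback on an invalid trial
that nonetheless produced a response still updates the values by default
(`update_q_invalid = TRUE`), since the participant saw the feedback — the
alternative is one flag away.

## Numerical implementation

**WFPT density.** The density is evaluated in C++ by the standard
series-switching scheme: the standardized density has a small-time and a
large-time expansion, and for each evaluation the representation needing
fewer terms at a truncation error of $10^{-12}$ (standardized scale) is
chosen. The dominant exponential of the small-time series is factored out so
log densities remain finite deep in the tails. Unit tests compare the
implementation against an independent fixed-truncation series written
directly from the textbook formulas, against the closed-form absorption
probability, and against numerical quadrature of total mass; the acceptance
suite additionally compares it to a brute-force simulation of 10^6 diffusion
paths (Kolmogorov–Smirnov distance below 0.01).

**Forward sampling.** First passages are simulated by Euler–Maruyama with
step `dt = 1e-4` s, augmented with a Brownian-bridge probability check for
within-step boundary crossings. The bridge correction removes the leading
discretization bias of the plain scheme (which systematically detects
crossings late); the remaining bias is far below the Monte-Carlo noise of
any sample size used here. Observations whose first passage exceeds the 2 s
deadline are recorded as non-responses.

**Observations with `rt <= t`** have zero likelihood and return `-Inf`,
which the samplers treat as an ordinary rejection; a numerical failure
inside the series would surface as `NaN` and is therefore distinguishable.

## Hierarchical estimation

Subject-level parameters are estimated hierarchically: on an unconstrained
scale (logit for $\alpha$; log for $a$ and $t$, which keeps both positive —
the non-decision time in particular must be; identity for $v_{\mathrm{intercept}}$,
$B_v$, $B_z$), each subject's parameter vector is drawn from a normal
group-level distribution whose means and SDs are estimated jointly. Priors
are weakly informative: normal group-mean priors centered at plausible
diffusion-model values and half-normal group-SD priors (`default_priors()`).

With no Hamiltonian/NUTS infrastructure among this package's dependencies,
sampling uses an adaptive Metropolis-within-Gibbs scheme designed for this
posterior:

* componentwise Gaussian random-walk updates of each subject's six
  unconstrained parameters, with per-subject, per-parameter proposal scales
  adapted during warmup toward a 0.44 acceptance rate;
* a conjugate Gibbs update for each group mean and a log-scale Metropolis
  update for each group SD;
* an *interweaved non-centered move*: holding every subject's standardized
  deviate $(\theta_{sj} - \mu_j)/\sigma_j$ fixed, the pair $(\mu_j, \log
  \sigma_j)$ is proposed jointly and all subject values are translated and
  rescaled together. The centered updates alone mix slowly through the
  funnel-shaped coupling between a group SD and its subject-level values
  (visible as inflated split-chain R-hat for the $\alpha$ and $B_v$
  hierarchies); the interweaved move lets the group scale travel without
  dragging each subject through the likelihood one coordinate at a time.

Two MCMC profiles are provided. The `"paper"` profile mirrors the field's
reporting convention for this task (3 chains, 10,000 iterations, 5,000
burn-in, every fifth retained). The `"fast"` profile (4 chains, 1,500
warmup, 1,500 retained each) is the default for the simulation studies and
tests in this package; at the cohort sizes used here it reaches maximum
split-chain R-hat at or below about 1.03. Convergence is summarized by the
split-chain Gelman–Rubin statistic for every monitored quantity, with the
conventional pass threshold of 1.1; values marginally below 1 arising from
finite-sample noise are floored at 1, chains stuck at distinct constants
report `Inf`.

**Model comparison.** The main lattice contains the full model and five
lesions/reparameterizations: `no_value_drift` ($B_v = 0$), `no_value_start`
($B_z = 0$), `unweighted_drift` ($B_v = 1$), `unweighted_start` ($B_z = 1$)
and `shared_B` ($B_v = B_z$). Variants are compared by WAIC on the elpd
scale — a pointwise estimate of out-of-sample log predictive density with a
standard error — computed over valid trials from a thinned set of posterior
draws. Differences to the best variant carry the SE of the paired pointwise
difference; differences within one SE are reported as ties rather than
broken.

## The synthetic-data generator

No participant data ship with the package; all validation runs on synthetic
cohorts. `default_group_distribution()` defines the generating population on
the unconstrained scale:

```{r}
default_group_distribution()
```

These locations and scales are calibration choices, not estimates: cohorts
drawn from them reproduce the behavior scale conventionally reported for
this task — accuracy near 0.80/0.75 (rich/lean), mean RTs near 530–550 ms
with between-subject SD near 90 ms, discriminability near 0.6 (SD ≈ 0.27),
and a small positive response bias near 0.07–0.09 log units that is larger
on fast than slow trials. Reward delivery defaults to independent Bernoulli
flags (0.60 rich / 0.20 lean on correct responses); the classic queued rule
(exactly 30 + 10 scheduled rewards per block, missed rewards re-queued to
the next correct same-type response, not carried across blocks) is available
via `generate_schedule(delivery_rule = "queued")`.

What the generator deliberately does **not** emulate: perceptual
confusability beyond what drift rate captures, within-subject drift or
learning-rate fluctuation over time, lapses/guessing mixtures, and the
inter-trial variability parameters of the full Ratcliff model (the model
here has none, by design). Passing validation on these cohorts therefore
demonstrates the estimation machinery is faithful to *this* model, not that
the model is true of any real population.

One deliberate deviation in the recovery harness: the original validation
logic samples generating parameters from fitted real-data posteriors, which
are unavailable here; `parameter_recovery()` samples them from the group
distribution above, whose spread is calibrated to give comparable
between-subject variance.

## Problem sizes and seeds

The simulation studies are sized for a single CPU:

* *Convergence study*: 20 subjects × 200 trials, `"fast"` profile.
* *Parameter recovery*: 30 subjects × 200 trials, hierarchical refit. With
  these sizes the truth-estimate correlations reproduce the characteristic
  ordering — near-ceiling for non-decision time, threshold and drift
  intercept (r ≈ 0.99 / 0.99 / 0.93 in our runs), moderate for the learning
  parameters (α ≈ 0.65, B_v ≈ 0.5, B_z ≈ 0.94).
* *Model recovery*: 24 subjects for the full-model dataset and 12 for the
  B_z = 0 dataset. For the full-model half the generating weights are set
  to moderate, heterogeneous values (B_v location 0.5 with SD 0.6, B_z
  location 0.8): weights pinned near a lesion's fixed value (0 or 1) make
  that lesion nearly true, and no criterion can — or should — prefer the
  full model there.
* *Posterior predictive checks*: 20 datasets × 200 trials per subject,
  statistics over 8 × 25-trial bias bins and 4 × 50-trial RT bins, fast/slow
  classes at each subject's own 0.1/0.9 RT quantiles.

Every stochastic component takes an explicit integer seed; per-subject
streams are derived deterministically from one master seed, so cohorts,
fits and reports are bit-reproducible.

## Statistical conventions

* **Logarithm base in the signal-detection measures.** The source formulas
  do not fix a base. Base 10 is the default because it reproduces the
  conventional magnitude range of the measures (discriminability ≈ 0.6 at
  ~80% accuracy); natural logs (which scale every value by ln 10 ≈ 2.30)
  are available via `log_base`.
* **Session-level summary.** "Average" rows pool counts across blocks by
  default; averaging the two block-level statistics instead is available via
  `average = "mean_of_blocks"`, since both conventions are in circulation.
* **Group comparisons** use Welch's t-test (no equal-variance assumption)
  with pooled-SD Cohen's d; correlations are Pearson with two-sided p.
  P-values are reported uncorrected — multiple-comparison adjustment is the
  caller's decision, and `stats::p.adjust` composes directly.
* **ICC** is the two-way random-effects, absolute-agreement, single-measure
  form, the natural choice for block-1/block-2 agreement of one measurement
  per block.
* **Median age split** assigns ties at the median to the younger group.
* **Quality control** defaults (RT window 0.15–2.0 s, subject exclusion
  above 20% invalid trials) follow common practice for this task and are
  fully configurable; the exact historical rules vary between labs.

## Known limitations

* The sampler is random-walk based; posteriors with much larger cohorts or
  far weaker identification than exercised here will mix more slowly than a
  gradient-based sampler would. The interweaved move mitigates, but does not
  eliminate, the group-scale funnel.
* The learning-rate and drift-weight parameters are intrinsically weakly
  identified from 200 trials; their recovery correlations (≈ 0.5–0.65) are a
  property of the design, not a defect of the estimator, and match the
  reference ordering.
* WAIC is the only comparison criterion implemented; with very few subjects
  its SE is optimistic, which is why ties within one SE are surfaced rather
  than ranked away.
* The queued delivery rule re-queues within a block only; a scheduled
  reward missed on the last correct opportunity of a block is dropped, so
  realized counts can fall marginally short of 30:10 for low-accuracy
  responders.
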