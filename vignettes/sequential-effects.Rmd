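---
title: "Modelling sequential effects in binary choice sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sequential effects in binary choice sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqfx)
```

## The problem

When people are asked to produce a long "random" sequence of Heads and
Tails, the result is not random: the current choice depends systematically
on previous choices.  Classic signatures include the alternation bias
(switching more often than a fair coin would), over-balanced local counts of
Heads and Tails, and a suppression of alternation after long runs.  The same
kind of sequential dependence — plus a genuine reward dependence — appears
in operant learning, where people repeatedly choose between two options that
pay off stochastically.

`seqfx` models both settings with one family of lagged logistic choice
models, and provides the surrounding machinery: per-participant and pooled
estimation, population heterogeneity summaries, cross-validated next-symbol
prediction, model-free randomness statistics with Monte-Carlo chance bands,
a discounted-weight stationarity scan, and seedable generators that produce
synthetic populations with exactly the structure the analyses assume.

## The choice model

A choice \(a_t \in \{0, 1\}\) (1 = Heads) is Bernoulli with

\[
\Pr(a_t = 1) = \frac{1}{1 + e^{-\Delta Q_t}}, \qquad
\Delta Q_t = \beta_0 + \sum_{k=1}^{L} \beta_k\, s_{t-k},
\]

where \(s_{t-k} = a_{t-k} - (1 - a_{t-k}) \in \{-1, +1\}\) is the signed
past choice and \(L\) is the model horizon.  The signed coding is fixed
package-wide so that the coefficient signs read naturally: \(\beta_0 > 0\)
is an overall preference for Heads, \(\beta_1 < 0\) a propensity to
alternate (negative recency), \(\beta_1 > 0\) inertia.  All coefficients
zero is a fair coin.

For operant sessions with rewards \(r_{t-k}\) the linear predictor gains a
reward-by-action interaction,

\[
\Delta Q_t = \beta_0 + \sum_{k=1}^{L} s_{t-k}\,(\alpha_k r_{t-k} + \beta_k),
\]

so \(\alpha_k\) plays the role of a learned action value (with
\(\alpha_k = \gamma^k / T\) and \(\beta = 0\) this is temporal-difference
learning with softmax choice at temperature \(T\); see `td_alpha()`), and
\(\beta_k\) is the residual, reward-independent sequential effect.  Both are
estimated jointly in one maximum-likelihood fit (`fit_rl()`): the model is a
single linear predictor, and staged estimation would bias both parts when
the regressors correlate.

The first \(L\) trials of a sequence are dropped from the likelihood rather
than padded: the model conditions on \(L\) real preceding trials, and
padding would fabricate history.  Histories never cross participant or
block boundaries — operant blocks differ in reward schedule, so each block
is a separate history unit, while a participant's blocks are pooled as
stacked design rows in one fit.

## Estimation choices

`fit_logistic_mle()` and `fit_rl()` maximise the (optionally weighted)
Bernoulli log-likelihood with a damped Newton iteration: convergence when
the score norm falls below `1e-8`, at most 100 iterations, with step
halving whenever a step would decrease the penalised log-likelihood.
Standard errors come from the inverse observed information, Wald tests from
the normal approximation, and confidence intervals are reported at a
Bonferroni-corrected level \(1 - \alpha/m\) (`bonferroni_level()`), with
\(m\) defaulting to the number of coefficients.

Two numerical edge cases are handled explicitly rather than fatally:

* **Separation.**  Short or highly regular sequences can separate
  perfectly; coefficients are then capped at \(|\beta| \le 20\) and the fit
  flagged `converged = FALSE`.  Capped fits still predict (a capped
  coefficient saturates the probability), which keeps cross-validation
  usable; flagged participants are excluded from population summaries with
  a warning.
* **Ridge stabiliser.**  A ridge penalty (default `1e-4`) is applied only in
  the discounted fits of the stationarity scan, where strong discounting
  leaves an effective sample too small to identify \(L + 1\) coefficients.
  It is off everywhere else — the models elsewhere are plain maximum
  likelihood.

Hard calls from predicted probabilities break the tie at exactly
\(p = 0.5\) deterministically in favour of 1; under continuous estimates
the tie has probability near zero, and a seedable analysis beats an
unseedable coin flip.

## Predictors and cross-validation

Five next-symbol predictors are compared on equal footing
(`evaluate_heterogeneous()`, `evaluate_homogeneous()`):

* *negative recency* — predict the opposite of the last choice;
* *balance* — predict the minority symbol of the last \(L\) choices (an
  exact tie falls back to negative recency);
* *logistic* — the lagged model above;
* *Hamming NN* and *Levenshtein NN* — store every (length-\(L\) window,
  next symbol) pair from the training trials, find the training windows at
  minimal distance from the current history, and predict the majority next
  symbol (majority ties fall back to negative recency).  The Levenshtein
  variant uses unit-cost edit distance; on equal-length windows it can only
  be at most the Hamming distance.

Two regimes quantify the role of individual differences.  The
*heterogeneous* regime fits each participant separately and estimates the
generalisation error by 10-fold cross-validation; the *homogeneous* regime
fits one parameter set on all other participants
(leave-one-participant-out) and predicts the held-out participant.  Folds
are **contiguous blocks of trials**, not random subsets: the quantity being
modelled is sequential dependence, and randomly interleaved folds would
leak each test trial's immediate history into training.  (Random folds are
available via `fold_type = "random"` for sensitivity analysis.)  Test-trial
histories are always the participant's true preceding choices, never model
rollouts, so every model answers the same question: predict trial \(t\)
from the \(L\) real trials before it.  Parameter-free models are evaluated
on the same test trials for comparability, and errors are averaged across
folds, then across participants.  `select_memory_length()` picks \(L\) by
minimising this cross-validated error, breaking ties toward the smallest
\(L\).

Calibration (`calibration_curve()`) bins predictions into 20 equally
populated bins and compares each bin's mean predicted probability with its
empirical Heads frequency; a well-calibrated logistic fit lies on the
diagonal.  Ties among identical predictions are split arbitrarily across
bins by the quantile rule, which is immaterial for continuous predictors
and handled without error in the degenerate constant case.

## Model-free randomness statistics

`conditional_probabilities()` estimates \(\Pr(a_t = 1 \mid a_{t-k} = 1)\)
per lag (0.5 for a fair coin at every lag), pooled over participants or per
participant — both variants are reported because aggregating before or
after the ratio answers slightly different questions.
`heads_count_distribution()` counts Heads in *disjoint* windows of 10
trials (matching a task format in which rows of a 100 × 10 table are
natural units; sliding windows would double-count and correlate adjacent
windows), against the Binomial(10, 0.5) chance reference.
`alternation_by_run_length()` tallies the probability of switching as a
function of the length of the preceding unbroken run; runs truncated by the
sequence start are right-censored and counted at their observed length.
All three get matched-size Monte-Carlo null bands from `chance_band()`
rather than asymptotic approximations.

## Heterogeneity summaries

Per-participant coefficients (`fit_population()`) are summarised per lag by
the mean \(\mu(\beta_k)\), the quadratic mean
\(\sqrt{\overline{\beta_k^2}}\), the SD \(\sigma(\beta_k)\), and the
signal-to-noise ratio \(\mathrm{SNR} = |\mu|/\sigma\)
(`summarize_population()`).  A large quadratic mean with a near-zero mean
is the signature of strong but heterogeneous effects that cancel in a
pooled analysis — the package deliberately surfaces both the pooled fit and
the per-participant view so this dissociation is visible.  The SD uses the
sample (\(n-1\)) convention, standard for between-participant inference;
under it the identity
\(\mathrm{qmean}^2 = \mu^2 + \sigma^2 (n-1)/n\) holds exactly and is
asserted in the tests.  A zero-SD column reports an infinite SNR marker
rather than failing.  Confidence intervals come from resampling
*participants* (not trials) with replacement, 100 resamples by default,
percentile intervals at a Bonferroni-corrected level; `compare_tasks()`
bootstraps two populations independently to interval their per-lag
differences.

## Stationarity scan

Whether a participant's parameters are stable over the session is measured
by refitting the model with exponentially discounted weights — the trial
\(k\) steps before the test trial receives weight \((1-\eta)\,\eta^k\) —
and asking which discount \(\eta\) best predicts upcoming choices
one-step-ahead from the middle of the sequence onwards
(`scan_discounting()`).  The associated timescale is reported as
\(1/(1-\eta)\): the effective number of trials the weighted likelihood
averages over (the alternative reading \(\eta/(1-\eta)\) is available).

The default grid (`eta_grid_default()`) is zero plus 25 values whose
*complements* \(1-\eta\) are equally spaced on a log scale over
\((10^{-6}, 1)\), covering timescales from under two trials to \(10^6\)
trials.  Spacing \(\eta\) itself logarithmically would concentrate the
entire grid below \(\eta \approx 0.58\) — every candidate would forget all
but the last couple of trials, and the scan could not express the
hundreds-of-trials stability it is designed to detect; spacing the
complement makes timescales uniform on the log scale, which is the natural
resolution for this statistic.

Refitting at every test trial is supported (`stride = 1`), but the default
refits every 10 test trials and predicts the stride with the last fit —
with 26 grid values and ~500 test trials per participant the scan is
otherwise the desk-scale bottleneck, and the stride changes the selected
discount only within neighbouring grid points.  Fits whose effective sample
size \((\sum w)^2 / \sum w^2\) stays below \(L + 2\) (inevitable as
\(\eta \to 0\)) are recorded as missing and excluded from the argmin, with
a warning.  Among discounts with exactly equal error the largest \(\eta\)
is selected: when prediction cannot distinguish timescales, the scan
prefers the more stationary reading.

## Synthetic data: what it does and does not emulate

Because the package is exercised end-to-end on simulation, the generators
are first-class, tested code:

* `simulate_fair_coin()` — the i.i.d. null.
* `simulate_logistic_agent()` — the lagged logistic model run generatively.
  The first \(L\) warm-up choices are fair-coin draws: the model needs a
  history to start from, the choice washes out within a few trials, and any
  fixed warm-up would imprint an arbitrary pattern.
* `simulate_population()` — per-participant coefficients drawn
  componentwise Normal around configurable means/SDs, with the truth table
  returned for recovery checks.  Normality is the default because the
  analyses consume only means and SDs; heavy-tailed alternatives would
  change nothing structural.
* `simulate_operant_session()` / `simulate_operant_population()` — the
  reward-augmented model run generatively against a two-armed bandit with
  Bernoulli payoffs.  Default population shape mirrors sessions of 100-trial
  blocks with per-block arm probabilities drawn uniformly — a stand-in for
  real experiments' reward schedules, whose exact parameter sets are not
  public.  Payoff magnitudes are configurable (e.g. ±1), and that matters
  for one analysis: the reward-shuffle permutation control isolates the
  reward term exactly only when rewards are mean-zero and independent of
  choice (symmetric arms, ±1 payoffs); with asymmetric payoffs the
  sequential coefficient legitimately absorbs \(\alpha_k E[r]\) after
  shuffling.

Passing tests on these populations show that the estimators, the
cross-validation machinery, and the statistics do what they claim *when the
generating process is the model family itself* (plus the analytic Bayes
floor `bayes_error()`, computed exactly from the \(2^L\)-state Markov chain
of histories, which the predictors approach on such data).  They do not
show that human sequences are logistic, stationary, or Normal across
participants — with real data the model is a description whose adequacy the
calibration curve, the randomness statistics and the stationarity scan are
there to check.

## Problem sizes

The test suite and the acceptance script run, by design, at the scale of a
typical sequence-generation study: populations of 30 participants × 1,000
trials for the heterogeneity and regime analyses; 200 simulated agents for
recovery; 6 × 10,000-trial sequences for the near-optimality comparison
against the analytic Bayes error; 20 paired stationary/drifting sequences
for the stationarity scan at stride 10; 10,000-trial operant sessions for
the reward-model checks; and 30-trial instances for the brute-force
grid-search oracle.

## Known limitations

* Strictly binary choices; no more than two alternatives.
* The two-stage fit-then-summarise heterogeneity analysis is not a
  hierarchical (mixed-effects) model; shrinkage is deliberately absent.
* The nearest-neighbour predictors implement plain
  nearest-neighbour-by-distance with majority vote; published
  pattern-matching variants differ in window handling and distance
  weighting.
* The discounted scan searches a fixed grid; it does not optimise \(\eta\)
  continuously.
* Degrees of belief about real behavioural data should rest on the
  model-checking tools, not on the synthetic recovery results.
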