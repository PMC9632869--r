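---
title: "Risk-aware ICU treatment policies: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-aware ICU treatment policies: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisrl)
```

`sepsisrl` implements a complete tabular pipeline for learning treatment
policies from ICU-style hourly trajectory data: custom-metric kNN matrix
completion, k-means state discretization selected by a coverage
heuristic, an empirical-MDP patient simulator with absorbing
recovery/death outcomes, and synchronous speedy categorical
distributional Q-learning. Because real critical-care registries are
access-restricted, the package ships a synthetic cohort generator with a
known ground-truth MDP, which is what all tests and experiments run on.
This vignette explains each model, the tunable parameters and their
defaults, the numerical choices, and what the synthetic world does and
does not establish.

## 1. The decision problem

A patient trajectory is a sequence of hourly feature vectors (default 53
continuous channels), a treatment per hour — one of 25 actions on a
5 × 5 grid of intravenous-fluid and vasopressor dose bins — and a
terminal outcome. The trajectory ends in one of two absorbing states,
*recovered* or *died*, rewarded +100 and −100; all intermediate rewards
are zero, so the discounted return of a length-\(L\) recovery episode is
\(100\gamma^{L-1}\). With discount \(\gamma = 0.99\) (the default), the
return lives in \([-100, 100]\) and encodes both outcome and speed.
Intermediate rewards are deliberately absent: survival is the only
criterion the data support, and shaping terms would inject modelling
assumptions the pipeline is designed to avoid.

## 2. Missing-value imputation

Hourly resolution makes missingness severe (the emulated rate is 39% of
entries). Classical kNN imputation needs complete coordinates to compute
distances, so the package uses the dissimilarity
\[
D(x, y) = \sum_{i=1}^{n} f(x_i, y_i), \qquad
f(x_i, y_i) = \begin{cases}
\dfrac{(x_i - y_i)^2}{p_i + (x_i - y_i)^2} & x_i, y_i \text{ observed},\\[4pt]
a & \text{otherwise},
\end{cases}
\]
with per-feature scales \(p_i > 0\) and a missing-value penalty
\(a \in [\tfrac14, 1]\). Each observed coordinate contributes strictly
less than 1; a missing coordinate contributes exactly \(a\), so \(a = 1\)
(the default) treats missingness as maximal disagreement. The default
scales are \(p_i = 2\,\mathrm{Var}(x_i)\) — motivated by
\(E[(X-Y)^2] = 2V\) for i.i.d. variables — so a typical observed
squared difference contributes about one half. Variances use the
population (1/n) convention; `var_type = "sample"` switches it.

**Which quantity is the metric.** Neighbour queries use
\(\sqrt{D}\) (`tree_metric`), not \(D\). Per coordinate,
\(\sqrt{f}\) is a concave increasing transform of \(|x_i - y_i|\) and
hence a metric, and the square root of the coordinate sum is the usual
\(L_2\) composition. \(D\) itself is *not* a metric for any \(a\): three
collinear fully observed points with small separations already violate
the triangle inequality. For \(\sqrt{D}\) the missing-value case gives
exactly the \(a \ge \tfrac14\) threshold: the supremum distance between
two observed values is 1, and the detour through an all-missing point
has length \(2\sqrt{a}\). `triangle_threshold_search` certifies this
boundary by combining random triples with the adversarial family of a
widely separated observed pair bridged by a missing intermediate; the
family pins the infimum, the random search guards against other failure
modes. The triangle inequality is what makes KD-/ball-tree-style
neighbour indexing legitimate at scale.

**Imputation rule.** A missing entry \((i, j)\) becomes the mean of
feature \(j\) over the \(k\) nearest neighbours of row \(i\) that
observe \(j\) (default \(k = 10\), unweighted; inverse-distance weights
behind a flag), falling back to the feature's global observed mean when
none of the \(k\) observes it. Neither \(k\) nor the weighting is pinned
down by the source method; both are exposed as configuration. Neighbours
are drawn from the full observation pool rather than per patient,
because values are often missing precisely when clinicians chose not to
measure them, making within-patient interpolation ill-advised.

**The Swiss-roll benchmark and an honest red flag.** The supplementary
benchmark generates a 3-D Swiss roll, embeds it into \(d\) dimensions
with a random orthonormal map (QR of a uniform random matrix), removes
70% of entries uniformly, and compares kNN completion with
per-feature-mean imputation by RSSE on the masked entries. From
dimension 5 upward kNN wins clearly (at \(d = 100\) by more than a
factor 2). At \(d = 3\) it does not, and cannot: a 3-column matrix at
70% missingness leaves on average 0.9 observed coordinates per row and
makes 34% of rows fully missing, so neighbour queries carry almost no
information — an independent reference implementation
(scikit-learn's `KNNImputer`) also fails to beat the column mean there
for every neighbourhood size we tried. The corresponding acceptance
assertion is therefore left failing at \(d = 3\) by design, with the
passes at \(d = 10, 100\) carrying the substantive claim: the method's
advantage is *independence from the embedding dimension once any usable
neighbourhood information exists*.

## 3. State representation and the coverage heuristic

Completed features are standardized per channel (zero mean, unit
population SD; constant channels become zero columns with a warning) and
discretized by k-means. Because k-means is non-deterministic and the
cluster count is unknown, a family of candidates is fitted
(`fit_candidates`; the historical protocol is 50 restarts × 19 counts =
950 candidates, each with a recorded seed) and one is *selected* by a
criterion that looks only at data and treatment histories, never at the
learner:

1. split the patients into two halves;
2. extract the empirical clinician policy (action frequencies per
   state) from the first half;
3. evaluate that policy by dynamic programming on each half's empirical
   MDP, giving state values \(v_1\) and \(v_2\) in \([-100, 100]\);
4. score the candidate by the *coverage*: the fraction of shared states
   with \(|v_1 - v_2| < 15\).

A representation that distinguishes good from bad states consistently
across halves scores high. The 15-unit margin is an empirical choice on
the ±100 value scale, exposed as a parameter. Ranking by value
iteration's optimal values instead of the clinician policy is
implemented behind a flag-level choice (evaluate any policy you like via
`dp_policy_evaluation`) but is not used for selection: optimal actions
in one half are frequently unobserved in the other.

Three choices the source method leaves open are fixed here as: splits
are by *patient* (row-level splits leak state across halves); policy
rows are renormalized over each half's valid actions, with a uniform
fallback when a state's policy mass lies entirely outside them; states
absent from either half are excluded from coverage rather than
fabricated. Ties in selection break to smaller K, then smaller seed.

## 4. The empirical-MDP simulator

`build_empirical_mdp` tabulates transition counts per (state, action,
successor), directs each episode's final transition into the absorbing
outcome matching its label, normalizes rows, and records the
initial-state distribution from episode starts weighted by occurrence.
Valid actions are those observed at least once in a state — the 5 × 5
grid is never fully available in practice and the simulator only offers
what the data support. Interaction follows the usual episodic
reset/step contract (`mdp_reset`, `mdp_step`, `sample_episode`,
vectorized `rollout_batch`).

Numerical conventions: rewards attach to the transition *into* an
absorbing state (giving the \(100\gamma^{L-1}\) identity used
throughout the tests); rollouts are capped at `h_max = 500` steps and
cap-hit episodes are *censored*, counted as non-recovery (conservative);
a state left with no valid action by a small split also censors.

## 5. Speedy categorical distributional Q-learning

Return distributions are categorical on a fixed support — by default 51
equally spaced atoms on \([-100, 100]\), spacing 4. The categorical
projection \(\Pi_C\) clips a location into the support range and splits
its mass between the two bracketing atoms in proportion to proximity;
it conserves mass exactly and preserves in-range means. Clipping is our
choice for out-of-range locations (the source leaves boundary behaviour
unstated); with \(\gamma \le 1\) and terminal-only ±100 rewards,
backed-up locations stay in range, so the clip is a safety total-ness
device, not an active approximation.

Training is synchronous: each sweep updates *every* valid (state,
action) pair, which avoids exploration entirely — the empirical MDP is
a generative model, not a stream. Per pair one successor is sampled and
two Bellman targets are formed against the current and previous tables,
*sharing* the sample and the successor action (greedy for control,
policy-sampled for evaluation). The speedy update extrapolates:
\[
D_k = k\,\Pi_C T \eta_k - (k-1)\,\Pi_C T \eta_{k-1}, \qquad
\eta_{k+1} = (1 - \alpha_k)\,\eta_k + \alpha_k D_k,
\quad \alpha_k = \tfrac{1}{k+1}.
\]
At \(k = 0\) this reduces exactly to \(\Pi_C T \eta_0\), identical to
the plain categorical Q-learning baseline (`categorical_q_control`),
which shares its fixed points and serves as the speed comparison.

**Signed intermediates.** The extrapolated combination can drive
individual atom weights slightly negative. Rows always sum to 1 (a
tracked invariant, `diagnostics$max_row_sum_err`), and weights are
carried signed through training: clipping inside the loop would change
the recursion. Only at readout are negatives clipped and rows
renormalized; the removed mass is logged and is ~1e-3 or far less in
every suite we run. \(\eta_0\) is the point mass at the atom nearest 0
(no initial guess is prescribed).

**Stopping.** Control stops when the maximum Cramér distance
\(\bar\ell_2(\eta_{k+1}, \eta_k)\) — computed with the general
non-uniform-spacing CDF sum, though default grids are uniform — drops
to \(\Delta = 0.05\), or after \(T = 1000\) sweeps; policy evaluation
always runs its full budget. Two caveats worth knowing: on very small
MDPs the rule can fire spuriously at \(k = 0\) if the single sampled
transition per pair happens to reproduce \(\eta_0\) (irrelevant at
clinical scale with thousands of pairs); and with stochastic sampling
the per-sweep change has a noise floor, so the clinical default
\(T = 1000\) yields expectations accurate to a few return units, not to
machine precision. The oracle tests that compare against exact value
iteration and linear-solve policy evaluation therefore run 8000 sweeps
— the \(1/(k+1)\) averaging leaves Monte-Carlo noise of order
\(200/\sqrt{T}\), which must sit below the 4-unit atom spacing the
criteria use — and their random MDPs draw per-state hazards from
well-separated levels so that optimal actions are identifiable at all
(with i.i.d. hazards, near-ties make the argmax a coin flip for any
finite-sample method).

## 6. Deployment policies and evaluation

A purely greedy policy on an empirical simulator can loop through
states whose estimated best actions chain into a cycle. The deployment
policy is therefore *ranked stochastic*: valid actions sorted by
expected return get weights \(2^{-\mathrm{rank}}\), renormalized — with
many valid actions the best receives ≈ 0.5 and the second ≈ 0.25. The
renormalization (rather than dumping tail mass on the last action) is
our reading; it preserves the stated leading probabilities.

`rollout_metrics` reports the recovery rate (fraction absorbed in
*recovered*; censored episodes count against it) and the mean
discounted return under the training \(\gamma\) — our reading of "mean
reward", consistent with reported values sitting well below
\(100(2\cdot\mathrm{rate} - 1)\). Return distributions are classified
by risk: mass on negative atoms is death probability, positive atoms
recovery (an exact-zero atom splits evenly — measure-negligible in
practice); *negative* if death > 0.5, else *safe* if recovery > 0.95,
else *bimodal* if both sides ≥ 0.4 (our operationalization of "almost
as likely", configurable), else *positive*. The rule is total and
exclusive, checked property-style.

`generalization_experiment` reproduces the train/test protocol: 80/20
patient splits, training on the train simulator, evaluating the ranked
policy on both. The train–test recovery gap is the overfitting
signature; it shrinks as the cohort grows.

## 7. The synthetic cohort: what it emulates, what it does not

`cohort_config` states the world: 53 feature channels, a 5 × 5 action
grid with per-state valid subsets (each action valid with probability
0.5, forced non-empty), 39% MCAR missingness, absorbing outcomes, and
episode lengths arising from absorption hazards rather than being
imposed — per (state, action) a recovery hazard uniform on
(0.02, 0.30) and a death hazard uniform on (0, 0.08), remaining mass
Dirichlet(1) over latent states. These hazards give recovery-heavy
cohorts (≈ 90% under a mediocre behavior policy, matching clinical
registries' survival-dominant outcomes) and geometric-tailed lengths
with means around 5–8 hours. State centroids are isotropic Gaussian
with SD 5 against feature noise SD 1, keeping latent states separable —
the regime in which discretization-based pipelines are meaningful. The
behavior ("clinician") policy mixes the ground truth's optimal policy
with uniform-over-valid at weight `behavior_quality` (default 0.6:
competent but improvable).

What the generator does *not* emulate: informative missingness (values
missing because clinicians chose not to measure — the mechanism is
unspecified in the source; MCAR is the testable default and a MAR hook
is the natural extension), physiological sepsis dynamics, demographic
or binary channels, and inter-patient heterogeneity beyond the latent
state. A green end-to-end test therefore establishes *pipeline
correctness under the stated world* — discretization recovers the
latent states, the empirical MDP converges to the generator, the
learned policy improves on the behavior policy on the training
simulator, and the train/test gap shrinks with cohort size (200 → 5000
patients) — not clinical validity on any real registry.

## 8. Known limitations

- Tabular only: no function approximation; the state space is whatever
  k-means yields.
- The empirical MDP inherits every bias of the behavior policy's
  state-action coverage; actions never taken are simply invalid rather
  than estimated.
- The coverage heuristic compares value functions under a *single*
  extracted policy; candidates that distort rarely visited states can
  tie.
- Quantile/expectile return representations, Wasserstein metrics,
  importance-sampling off-policy evaluation, and risk-sensitive
  maximization objectives are out of scope.
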