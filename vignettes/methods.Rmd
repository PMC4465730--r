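---
title: "Methods: partial-profile choice designs and MNL preference analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partial-profile choice designs and MNL preference analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A discrete choice experiment presents each respondent with a sequence of
choice sets, here forced pairs of profiles. A profile assigns one of three
outcome levels — `positive`, `no_change`, `negative` — to each of K
attributes (in the study configuration, eleven health-system performance
domains). Under the multinomial logit (MNL) model the probability of
choosing profile j in a pair is

    P(j) = exp(u_j) / (exp(u_1) + exp(u_2)),

with utility `u_j = x_j' beta` the sum of the marginal utilities of the
profile's attribute levels, plus subgroup interaction contributions.

**Effects coding.** Each three-level attribute contributes two columns,
with `positive -> (1, 0)`, `no_change -> (0, 1)`, `negative -> (-1, -1)`.
The three implied level utilities sum to zero within every attribute, so
all three — including the status-quo utility — are first-class reportable
quantities rather than residuals of a dummy coding. Absolute utilities
still have no interpretable scale; reporting happens on the standardized
scale described below, which is invariant to the coding choice.

Because the two alternatives are unlabeled, any respondent-level main
effect cancels out of the utility difference; respondent covariates can
only act through interactions with attribute codes. In a forced pair the
model collapses to a binary logistic regression on the effects-coded
profile *differences*, which is how the likelihood, its gradient and the
information matrix are computed throughout.

## Design generation

**Partial profiles and attribute balance.** To limit cognitive burden, at
most `n_varying_max` (study: 5) attributes vary within a choice set; the
rest are held constant. Which attributes are planned constants in which
set is decided before level optimization by an attribute-balance plan:
with 54 sets and 6 planned constants per set over 11 attributes, each
attribute must be constant in either 29 or 30 sets (54·6/11 = 29.45). The
plan is built by a seeded randomized greedy that fills each set from the
attributes with the largest remaining constancy quota, breaking ties by
the smallest pairwise co-constancy count and then at random; up to 50
internal restarts keep the assignment whose pair counts are most even. On
the study geometry the achieved pair-count spread is at most 4 (typically
3); on small exactly-divisible geometries (4 attributes, 6 sets, 2
constants) the greedy recovers perfect pair balance. Planned constants
are displayed at `no_change` in both profiles — a neutral display choice,
not a statistical requirement, since a constant attribute cancels from
the utility difference regardless of its level.

**The design prior.** The Bayesian D-criterion averages the
log-determinant of the MNL information matrix over a multivariate normal
prior on the coefficients. `build_ordered_prior()` encodes three a-priori
beliefs: within every attribute, positive is preferred to no change,
which is preferred to negative; avoiding a negative outcome weighs more
than attaining a positive one (loss aversion); and lower-ranked
attributes matter geometrically less. For rank r the target level
utilities are `(+g_r, 0, -L·g_r)` with `g_r = base_gap · rank_decay^(r-1)`
and loss-aversion multiplier L; the triple is centered into the
sum-to-zero coding space, which preserves both pairwise gaps. Defaults
(`base_gap = 1`, `loss_aversion = 1.5`, `rank_decay = 0.9`, `sd = 0.5`,
`draws = 512`) reproduce this qualitative structure while keeping design
optimization desk-fast; they are configuration, not canonical values, and
the package makes no claim of regenerating any specific historical design
catalog — only designs with the same stated structural properties. The
covariance defaults to diagonal because no correlation structure is
asserted; draws are fixed-seed so optimization is reproducible.

**Coordinate exchange.** Starting from a random feasible design (planned
constants at `no_change`, varying levels uniform, sets redrawn until they
contain a trade-off), the optimizer sweeps over the design: for each set
and each varying attribute all nine level pairs of the two profiles are
tried; for small sets (at most two varying attributes) all joint level
assignments of the set are tried at once, a wider neighborhood that
escapes local optima unreachable by attribute-wise moves. A move is
accepted only on strict criterion improvement (ties retain the incumbent,
preventing cycling); convergence is a full sweep without an accepted
move, capped at 50 sweeps, and the best of several random restarts is
returned. Candidate moves that would let one profile weakly dominate the
other under the prior-mean level ordering are never accepted, so emitted
designs contain no dominated set. Varying attributes that end with equal
levels in both profiles are recorded as incidental constants, distinct
from the planned ones. Survey blocks are assigned round-robin over the
optimized set order, which partitions the sets into equal groups; no
particular blocking rule is claimed beyond that.

**Numerics.** Candidate moves change one row of the difference matrix, so
the criterion is updated per prior draw by two rank-one
(Sherman–Morrison) steps on the stored inverse information matrix — the
new row is added *before* the old one is removed, keeping the
intermediate matrix positive definite even when the design has only as
many rows as columns. Determinant factors below 1e-12 mark a singular
update and the move is rejected. Accumulated state is refreshed from
scratch after every sweep to curb floating-point drift, and the final
criterion is always re-evaluated directly via Cholesky factorization; a
Cholesky diagonal ratio corresponding to a condition number of about 1e10
is treated as singular and yields the `-Inf` sentinel. A design must have
at least as many choice sets as coefficient columns (2K) to be
identifiable at all; the study's 54 sets comfortably exceed the 22
columns.

## Synthetic respondents and choices

`generate_population()` draws each characteristic independently at the
study margins: overlapping stakeholder roles (physician 67%, policy maker
22%, executive 34%, researcher 30%) as independent Bernoulli indicators;
one of five areas (US 37%, Western Europe 25%, Oceania 18%, Canada 10%,
Eastern Europe 9%, renormalized from their printed whole percents); sex
(31% female); age and seniority as truncated normals (50 ± 11 within
25–80; 23 ± 11 within 0–60, clamped to not exceed age); and seven payment
forms in use as independent indicators. Respondents with no role are
redrawn, and the role sampling probabilities are deflated to the fixed
point `p' = p·(1 - q)`, `q = prod(1 - p')`, so the *post*-rejection role
shares still match the targets. Survey blocks cycle 1, 2, 3 so each block
is answered about equally often.

`simulate_choices()` shows each respondent the 18 sets of their block,
drops each set independently with probability 1 − 0.87 (the aggregate
completion rate; respondent-level dropout is deliberately not modeled,
as only the aggregate rate is asserted), and draws the choice from the
MNL probability under the respondent's coefficient vector (base truth
plus that respondent's interaction offsets).

**The default truth** mirrors the qualitative preference structure the
study reports: a deterioration in effectiveness and patient safety is the
dominant coefficient (utility −1, which doubles as the standardization
reference so standardized outputs read like the raw truth); avoiding a
negative outcome outweighs the matching improvement everywhere except
long-term cost containment and gaming, where improvement dominates;
status-quo utilities are small, mostly positive, slightly negative for
those same two domains. Subgroup offsets carry the reported signs —
physicians weight effectiveness, coordination, provider wellness and
timeliness up and short-term cost containment down; policy makers shift
gaming toward improvement; executives weight provider wellness up;
researchers weight effectiveness and long-term cost containment up; area
offsets make Oceania and the US most, Canada least, sensitive to
effectiveness, with Canada and Eastern Europe favoring improvement over
avoidance there. Magnitudes are chosen once so that, at the study's
sample size, every domain's likelihood-ratio test lands far below the
p < 0.0001 the study reports — they are study conditions, not tuning
knobs.

**What the simulator does not emulate.** Characteristics are sampled
independently (only margins, not joint structure, are known); there is no
taste heterogeneity beyond the specified subgroup offsets (no mixed
logit), no straight-lining or other response pathologies, no recruitment
or self-selection process, and missingness is completely at random.
Passing parameter-recovery and calibration tests therefore demonstrates
the correctness of the estimation machinery under the stated model, not
robustness to real-world violations of it.

## Estimation

`fit_mnl()` maximizes the forced-pair log-likelihood
`sum_s [u_chosen - log(exp(u_1) + exp(u_2))]` (computed overflow-safely
on the log-odds scale) by BFGS from a zero start, followed by Newton
steps with backtracking until the gradient max-norm is below 1e-6; the
coefficient covariance is the inverse observed information at the
optimum, with an eigenvalue pseudo-inverse fallback (and warning) if the
information is singular. Columns with no variation in any choice set are
an identifiability error naming the offending coefficients. The fit is
deterministic given the data; it agrees with an independent conditional
logistic regression to near machine precision in the test suite.

**Covariate centering.** Interaction covariates are centered at their
respondent-table mean before multiplying the attribute codes (continuous
covariates are also scaled to SD 1). Centering makes the main-effect
columns estimate *population-average* marginal utilities — the natural
"pooled" reporting context — and renders the interaction columns nearly
orthogonal to them, so the per-attribute likelihood-ratio tests (which
remove an attribute's main-effect columns while keeping all interactions)
measure the pooled effect rather than a baseline-category effect diluted
by collinearity. Subgroup utilities are reconstructed from raw covariate
values via the stored centering constants.

**LR tests and importance.** Each attribute's overall significance is a
likelihood-ratio test with 2 degrees of freedom (its two main-effect
columns removed, interactions retained — an interpretive choice that
keeps "overall significance after adjustment" as the estimand). Relative
importance is −log p rescaled so the smallest p scores exactly 100; the
ratio of logarithms cancels the logarithm base (raw importance is
reported in −log10 units). P-values are carried in log space
(`pchisq(..., log.p = TRUE)`), so attributes whose p-values underflow the
double range keep their exact ordering; plain p-values below 1e-300 are
clamped and flagged.

**Standardization.** Every reported level utility is divided by the
absolute value of the pooled main-effect utility of the reference pair
(deterioration in effectiveness and patient safety), mapping the
reference to exactly −1. The same pooled denominator is used when
standardizing subgroup-specific utilities — otherwise cross-subgroup
comparisons and ratio statements (such as `1.13 / 0.87 - 1 = 0.30`) would
be meaningless. Standardization refuses a reference within 1e-8 of zero.

## Scenario utilities

A scenario assigns an outcome level to every attribute; its total utility
for a subgroup context is the sum of the context's standardized marginal
utilities at those levels. The status-quo scenario sets every attribute
to `no_change`; the default reform scenario improves effectiveness and
patient safety, long-term cost containment, best practice service use,
coordination and innovation, deteriorates provider wellness, patient
centeredness, timeliness, gaming and short-term cost containment, and
keeps care equity unchanged. Area × role cells combine main effects with
the cell's area offset and the focal role's offset (other, overlapping
roles stay at their population mean); no area-by-role interaction terms
are used, since role and area effects are reported separately. The
relative difference `(U_after - U_before)/U_before` is displayed rounded
half-up to two decimals. Rows with a negative status-quo baseline carry a
flag instead of an interpretation: for such rows the ratio's sign
convention is ambiguous, and published examples of that situation are
mutually inconsistent under any single convention, so the package reports
the plain formula plus the flag and treats those cells as
non-reproducible.

## Test design and problem sizes

The test suite builds everything it needs in code. Sizes were chosen to
keep a full run desk-scale while leaving the statistical checks sharp:

* the study design is optimized once per run at 54 sets, 4 restarts, 256
  prior draws, and shared across structure, optimality, simulation and
  recovery tests;
* design optimality is checked two ways: the optimized criterion must
  beat the best of 100 random feasible designs sharing its balance plan,
  and on a two-attribute toy (four sets — the smallest identifiable size
  for four effects-coded columns) coordinate exchange must reach the
  optimum found by exhaustive enumeration over all feasible difference
  multisets;
* likelihood and information-matrix code must match independent
  brute-force oracles to 1e-10, and `LL(0) = n log(1/2)` to 1e-12;
* parameter recovery runs 20 replicates of the full 547-respondent
  simulation: nominal 95% Wald intervals must cover each true coefficient
  with at least 90% average coverage and at least 15 of 20 per
  coefficient — the binomial-noise rendering, at 20 replicates, of a
  90-of-100 coverage requirement;
* the type-I error of the LR test is calibrated on 200 simulated
  datasets of a deliberately null attribute at a reduced size (3
  attributes, 9 sets, 40 respondents), and must land inside the binomial
  95% band around 0.05;
* standardization and importance must be exactly invariant to rescaling
  all coefficients by any positive constant and to the logarithm base.

## Known limitations

* The MNL assumes IIA and homogeneous preferences within subgroup cells;
  no mixed-logit or latent-class extension is provided.
* The design prior's numeric values are package defaults with the stated
  qualitative structure, not estimates; designs are reproducible given a
  seed but are not claimed to match any externally published 54-set
  catalog row for row.
* Negative-baseline relative differences are flagged, not interpreted.
* The coordinate-exchange search is a local optimizer; global optimality
  is only guaranteed where exhaustive enumeration is feasible (and is
  verified there in the tests).
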