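---
title: "Measuring developing social bonds with multilayer versatility and a multivariate hurdle model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring developing social bonds with multilayer versatility and a multivariate hurdle model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`multiego` analyses how young animals build peer relationships, separating
*connectivity* (does a tie between a focal subject and a partner exist at
all?) from *quality* (how much of the subject's social investment does that
partner receive?). The motivating system is a large captive group of rhesus
macaques in which infants from two birth cohorts were followed for their
first three years with 10-minute focal observations scored at 30-second
interval marks across five behaviours: proximity and contact-sit
(undirected state behaviours) and directed play, grooming and aggression.
This vignette explains the models and algorithms, the tunable parameters,
what the synthetic-data generator does and does not emulate, and the
numerical choices behind the implementation.

## From interval records to temporal multiplex ego networks

Focal records are binned by month of life (bin 1 is the calendar month
containing the subject's birth), one unilayer star network per ego,
behaviour and month: edges run only between the ego and its partners
(alters), weighted by the number of scored intervals, kept separately per
direction for directed behaviours. Partners more than three years older
than the ego's cohort are excluded, so alters are developmental peers
(0-6 years old over the study). Monthly layers are stacked into four
developmental partitions — months 1-6, 7-12, the second year and the third
year — each realising five to six observed monthly bins (observation is
monthly in year one and bimonthly afterwards). Months with observation
effort but no events of a behaviour are retained as empty layers, so layer
counts reflect effort, which matters for the temporal-stability reading of
versatility below.

## Multilayer PageRank versatility

For one ego, behaviour and partition, a random walker moves over
(node, layer) pairs. Within a layer it follows edge weights (respecting
direction for directed behaviours); between layers it steps between
replicas of the same node with coupling weight $\omega$ (default 1), either
between every pair of layers ("categorical", the common multiplex default
and ours) or only between consecutive months ("ordinal"); both are
implemented because the published formulations differ and the original
choice is not recoverable from the text. Rows are normalised to be
stochastic; rows with no outgoing mass redistribute uniformly; the walk is
mixed with uniform teleportation at rate $1-d$ (damping $d = 0.85$, the
standard PageRank default). The stationary distribution is found by power
iteration to an $L_1$ residual below $10^{-10}$ (cap 10 000 iterations,
error on non-convergence), and a node's *versatility* is its stationary
mass summed over layer replicas. Tests verify the power iteration against
a dense eigendecomposition and, for single-layer networks, against an
independent PageRank implementation.

Versatility rewards both within-layer strength and presence across many
layers, which is exactly the connectivity-plus-stability reading we want
for a developing relationship. The ego is removed and alter versatilities
are rescaled to sum to one, making the value a *proportional investment*
that is comparable across egos with different degrees and partitions with
different bin counts. Sum-to-one rescaling (rather than max-scaling) is
used because proportional investment is the quantity the downstream model
treats as quality.

One boundary fact uncovered while testing: in a pure star with the
standard uniform-dangling convention, an alter connected only by
*ego-given* edges receives exactly the same stationary inflow as an alter
with a reciprocated tie of equal weight — alters receive mass through the
ego's out-edges plus symmetric teleport terms, so the return edge changes
the ego's mass, not the alter's. The expected strict ordering
"bidirectional > unidirectional" holds when the unidirectional tie is the
alter's own action toward the ego (received-only), and that is the case
the tests pin down.

Because all animals share one enclosure, a missing dyad is informative
rather than missing data: every (ego, alter) pair realised anywhere gains
explicit zero-versatility rows in all behaviours and partitions where it
is absent (*zero-population*), except partitions entirely before the
alter's birth or after its removal, and partitions in which the ego was
never observed. Zeros are flagged, never overwrite computed values, and
the operation is idempotent.

## Covariates

**Dominance ranks.** Yearly hierarchies among adults (3+ years) are
estimated from decided dyadic bouts with David's score on winning
proportions, z-standardised within year; the estimator is pluggable (any
linear-hierarchy score can substitute) since rank enters the model only as
a standardised covariate. Egos carry their mother's score; alters use
their own score when old enough, otherwise the maternal line is walked
upward and, failing that, the mean score of ranked matriline members is
used — a deterministic reading of "maternal or maternal kin's rank".

**Dyadic covariates.** Absolute rank and age differences are computed at
the partition midpoint (a per-year option exists); kinship is coded
unrelated / co-matrilineal / sibling from the matriline and mother fields
(paternal kinship is unknowable in this data model), with treatment coding
against "unrelated". A born flag marks alters born during the previous
partition (the first partition for which they have a lag); a removed flag
marks removal during the focal partition, and later partitions drop the
dyad entirely. Ego age is carried by the partition index as a linear term.

**Lags and responses.** Each behaviour's versatility at partition $t-1$
becomes a lag predictor at $t$, so lags keep both connectivity and quality
information. Responses exist for partitions 2-4 only. Grooming, aggression
and play versatilities are binarised (non-zero becomes 1) because almost
no mass falls strictly between 0 and 1 for those sparse directed
behaviours; contact and proximity keep their continuous values. All
continuous predictors are centred and scaled by two standard deviations so
their coefficients are comparable with binary predictors.

## The five-response model

Contact and proximity versatility follow a hurdle-lognormal family: a
logit hurdle for the probability of zero (connectivity, reverse-coded for
reporting) and a lognormal for positive investment (quality). Aggression,
grooming and play are Bernoulli. All seven linear components (3 Bernoulli,
2 hurdles, 2 lognormal locations) share the same predictor set — including
both hurdle parts, since connectivity and quality effects are reported
separately per predictor (an intercept-only hurdle variant is available) —
and receive ego and alter random intercepts drawn from 7-dimensional
multivariate normals. The ego and alter 7x7 cross-correlation matrices are
the quantity of scientific interest: they say whether individuals that are
unusually connected in one behaviour are unusually connected (or
invested) in another.

**Priors.** Fixed effects are Normal(0, 1). The random-effect precision
matrices carry Wishart(V = 10 I, df = 8) priors: df = dim + 1 implies
uniform marginal priors on each correlation, and the scale was calibrated
on simulated recovery fixtures — with V = I the prior visibly shrank RE
variances and cross-correlations at realistic group counts (40-49 egos),
attenuating a planted correlation of 0.7 to about 0.45, while V = 10 I
recovers it within the posterior's own uncertainty. Residual scales have
half-Normal(0, 1) priors.

**Sampler.** The model is fitted by an exact blocked Gibbs sampler with
Pólya-Gamma augmentation, implemented in C++. Every Bernoulli/hurdle
component becomes conditionally Gaussian given its PG latent variables
(drawn by an exact Devroye-type sampler, validated against closed-form
moments), so fixed effects, random effects and the Wishart precisions
update in closed form; residual scales use slice updates. Two further
engineering points matter for mixing: (1) the likelihood contribution to
each animal's 7-dimensional random effect is diagonal, so the conditional
is a cheap 7x7 solve; (2) for every design column constant within a
grouping factor (the intercept and the ego's cohort, sex and maternal
rank), a translation move shifts the coefficient jointly with the
random-effect mean along the likelihood-invariant direction, sampling the
shift from its exact Gaussian conditional. These ancillarity-sufficiency
moves raised worst-case bulk effective sample sizes from tens to hundreds
at identical cost. Chains run sequentially with seeds derived from the
configuration, so fits are exactly reproducible; split R-hat and bulk ESS
are computed for every fixed effect and non-convergence warns, never
passes silently. The study-scale schedule (4 chains, 6000 iterations,
warmup 2000, thin 2) retains 8000 draws; reduced schedules are used in
tests and the acceptance script and are stated there.

**Reporting.** Hurdle coefficients are sign-reversed in the fixed-effect
report and labelled "connectivity" so that positive always means more
connected; lognormal parts are "quality". Bayes $R^2$ is computed per
draw as $\mathrm{var}(\hat y) / (\mathrm{var}(\hat y) +
\overline{\sigma^2_{\text{res}}})$ on the probability scale for Bernoulli
responses and on the zero-inflated-expectation scale
($\hat y = (1-hu)\,e^{\mu + \sigma^2/2}$) for hurdle responses;
conditional includes the random effects, marginal zeroes them. On the
hurdle scale the conditional estimate is *not* guaranteed to exceed the
marginal one: random effects inflate the lognormal variance term
$e^{2\mu+2\sigma^2}$ faster than the fitted-value variance. Our tests
assert the nesting only on the probability scale.

## The synthetic-data generator

Two generation paths serve different purposes. The *mechanistic* path
simulates a ~130-animal mixed-sex group (two-thirds female, matching a
2:1 F:M ratio) with 12 matrilines, 49 egos in two cohorts (25 + 24, each
ego with a distinct mother within a cohort so cross-cohort siblings
arise), non-ego juvenile peers, removal by a yearly hazard (0.03), a
planted matriline-structured hierarchy generating decided bouts, and
focal records drawn per ego-month: event counts are binomial over
session-interval slots with logistic month trends (play declining,
grooming and aggression increasing), and partners are sampled with
probability proportional to
$\exp(\text{kin} + \text{sex} - \text{rank dist} - \text{age dist} +
\text{partner intercept} + \text{coupling})$, where the coupling term
rewards partners the dyad interacted with (per behaviour) in the previous
partition — the same dependence the model estimates. Default per-interval
base rates (0.25 proximity, 0.06 contact, 0.05 play, 0.015 aggression,
0.008 grooming) and a partner-intercept sd of 0.8 were chosen to
reproduce the observed sparsity ordering of the study system, where
proximity is by far the densest layer and grooming the sparsest; at full
scale the generated model table has roughly 65-70% non-zero proximity and
30-35% non-zero contact dyads. Interval events are independent given
rates — real focal data have within-session bouts of the same behaviour,
so generated weights are less clumped than real ones; passing tests
demonstrate pipeline correctness and sign/ordinal recovery, not unbiased
estimation from real observation schedules.

The *likelihood-exact* path draws responses directly from the model's
families given a predictor skeleton and generative truth (including
correlated random effects), which is the right tool for calibration-style
checks: 90% CI coverage across all fixed effects, sign recovery of
planted large effects, and recovery of a planted ego-RE cross-correlation
of 0.7. Mechanistic generation cannot serve that purpose because
versatility is a nonlinear network transform of the planted rates.

## Problem sizes and numerical choices

The test suite and acceptance script run reduced problem sizes chosen as
the smallest that keep the statistical checks well-powered: recovery fits
use 40 egos x 120 alters (~4000 rows) with 2 chains x 1500 iterations;
end-to-end sign recovery runs five full-scale mechanistic replicates
(49 egos, ~8000 rows) with single 800-iteration chains; the reciprocal
play fixture pools about 35 000 directed events so the binomial noise on
the given:total ratio (<0.01) sits well inside the +/-0.02 band being
checked. Power iteration stops at an $L_1$ residual of $10^{-10}$;
supra-matrices are dense, which is appropriate for star multiplexes of at
most a few hundred node-layer pairs; degenerate inputs (constant smoother
input, empty networks, all-zero alters, single-level factors) are handled
explicitly and tested.

## Known limitations

Ranks default to David's score because the original hierarchy method is
not recoverable; any standardised linear ordering can be plugged in.
Rank/age differences use partition midpoints (per-year optional). The
generator does not model within-session behavioural bouts, seasonal
fertility, or enclosure geometry. The exact inter-layer topology and
normalisation of the original versatility computation are not published;
both coupling variants are implemented and the normalisation choice is
documented above. Hurdle-scale Bayes $R^2$ definitions differ across
software; ours is documented and oracle-tested on simulations rather than
claimed identical to any specific implementation.
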