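---
title: "Evaluating usage of fully automated web interventions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating usage of fully automated web interventions: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehusage)
```

## The measurement problem

An unguided, fully automated web intervention has no therapist in the
loop: participants decide for themselves which content to open, when and
how often ("self-tailoring"). The only objective record of exposure is
the server log — one record per user-initiated https request, with a
timestamp at minute resolution. This vignette explains how `ehusage`
turns such logs into the usage statistics a technical evaluation needs,
which modelling decisions were open, and how the synthetic cohort
generator that backs the test suite is built and calibrated.

The running setting is a 16-week self-management intervention organised
in four 4-week phases, with 104 content "ingredients" (26 information
scripts, 48 assignments, 10 assessment tests, 20 video clusters) that
unlock stepwise each Monday and stay accessible afterwards. A weekly
reminder email goes out on the unlock day. 45 assignments/assessments ask
for an optional usefulness rating after use (useful = 1, not useful = 2,
not filled in = 0).

## From requests to sessions

Platforms of this kind log users out automatically after 30 minutes
without a request, so the session is *defined* by the log itself: a
maximal run of one user's events in which no two consecutive requests are
more than `timeout_min` apart.

Numerical choices that had to be pinned down:

* **The boundary gap.** A gap of exactly 30 minutes stays inside the
  session: auto-logout fires only once the idle time strictly exceeds the
  timeout. The boundary must be fixed one way or the other for
  reproducibility; this reading matches "logged out after 30 minutes of
  inactivity".
* **Seconds.** Timestamps are truncated (not rounded) to the minute on
  ingest. Truncation is order-preserving, so it can never reorder events;
  ingest is idempotent.
* **Duration.** Session duration is `end − start` of *observed* requests,
  in whole minutes. The 30 idle minutes before an auto-logout are never
  added — doing so would inflate every session by up to 30 minutes.
* **Logins.** A session counts as a login only when it lasts ≥ 1 minute,
  the finest duration a minute-resolution log can attest. Zero-duration
  sessions still exist (a single isolated request) and their ingredient
  opens *do* count toward activity: logins and opens are tracked
  independently, which is exactly why a participant can have "logged in
  once but opened nothing". Whether sub-minute visits should contribute
  opens is not externally specified; counting them is the package default
  and the sessionizer keeps the two measures separate so either policy
  can be applied downstream.
* **Explicit markers.** A logged `logout` closes its session immediately;
  a `login` always opens a new one, even within the timeout. Ties at the
  same minute keep file order (stable sort) — the log carries no
  sub-minute ordering to recover.
* **Midnight.** Sessions belong to the calendar day and weekday of their
  start.

The sessionizer is verified against an independent brute-force
event-by-event reference on 1000 random streams in the test suite.

## Usage metrics

Per user the package computes frequency, durations, activity (distinct
ingredients opened — platforms typically do not log re-opens, so distinct
counting is the only faithful semantics), the per-kind distribution of
opens, phase/week coverage, the Sunday = 1 … Saturday = 7 weekday login
histogram, engagement markers, and usefulness proportions whose
denominator is the set of *opened prompt-bearing* ingredients (a missing
response equals an explicit blank; zero opened prompts gives an undefined
triple, deliberately distinct from (0, 0, 0)).

Week indexing is half-open: week 1 is `[start_date, start_date + 7d)`,
and phase = `ceiling(week / 4)`. An ingredient is opened **late** when
the phase of its first open is *later* than its planned phase. Earlier
is impossible (stepwise lock) and a later week within the same phase is
on time. A `write_ingredient` with no open anywhere in the user's log is
counted as an open at the write's timestamp, with a warning — dropping it
would silently bias activity. Events before enrollment or after week 16
are rejected by default (`reject`), with `drop` and `clamp` policies
available.

## Adherence and user groups

**Continuous usage** (intervention adherence) is logging in at least once
in each of the four phases; **intermittent usage** (nonusage attrition)
is its failure. The published convention excludes participants who never
logged in from the intermittent percentage even though the literal
definition includes them; since text and arithmetic genuinely conflict,
`adherence_summary()` reports **both** variants, labelled
`intermittent_as_printed` and `intermittent_strict`, each with Wilson
intervals. The phase-coverage category set is completed with
`only_phase_3` / `only_phase_4` (structurally possible, rarely observed)
so the categories always partition any cohort.

User groups compare observed to *intended* usage: tiers
(nonuser 0 logins/0% activity, low 1/1%, intended 10/50%, high 17/75%).
Two decisions were open:

* **Discordant profiles** (say 21 logins but 30% activity) are assigned
  by the *minimum* of the frequency band and the activity band — a tier
  is reached only when both its minima are met. The conjunctive reading
  follows from the thresholds being stated as joint minima; it is
  configurable.
* **Percent-to-count rounding.** Activity thresholds are fractions of the
  catalog; `ceiling(fraction × 104)` converts them to ingredient counts
  (1% → 2, 50% → 52, 75% → 78). Exact-fraction comparison is available.
* **The collapse.** The intended tier is merged into high only when it is
  nonsubstantial (≤ 2 members), mirroring how a two-member tier was
  handled in practice; a substantial intended tier is kept.

## Inference

All proportions are reported with Wilson score intervals — the interval
obtained by inverting the normal score test. With successes `k`, trials
`n`, `p̂ = k/n` and `z` the exact two-sided normal quantile (1.959964 at
95%, not the rounded 1.96; both reproduce every published interval at its
printed rounding):

$$\mathrm{center} = \frac{\hat p + z^2/2n}{1 + z^2/n}, \qquad
\mathrm{halfwidth} = \frac{z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n}.$$

The interval respects [0, 1], collapses to 0 at `k = 0` and 1 at `k = n`,
and its empirical coverage at n = 70 is checked to be near-nominal by
simulation (10,000 binomial draws at p ∈ {0.1, 0.44, 0.9}).

Group comparisons: two-sample t tests accept either raw vectors or
(mean, SD, n) summaries — published tables provide only summaries — in
pooled (Student) and Welch variants. Welch is the default for new
analyses; the pooled variant reproduces classically reported p values,
and which variant produced a published value is usually unstated, so both
are exposed. Pearson chi-square (no continuity correction), Fisher exact
(2×2, two-sided by the point-probability convention, with p = 1 for a
degenerate margin), Pearson correlation (t transform, n − 2 df) and a
7-cell weekday uniformity chi-square complete the toolbox. The
group-characteristics table chooses chi-square unless any expected cell
is below 5 (then Fisher), with per-row overrides for reproducing a
published table whose per-row choices are known. No multiplicity
correction is applied, matching the two-sided α = .05 reporting
convention of the source analyses. Degenerate inputs follow explicit
conventions rather than erroring mid-report: zero variance in both groups
with equal means gives p = 1, a group with fewer than two observations
gives an NA row.

## The synthetic cohort generator

`sample_cohort()` exists so that every pipeline stage is testable without
trial data. It emulates a 70-woman cohort over 16 weeks as a mixture of
three engagement archetypes (13% nonusers, 43% low, 44% high). For each
user:

1. **Sessions.** Week `w` contributes a Poisson number of sessions with
   rate `r · exp(−d (w − 1))`. High users: `r = 1.518, d = 0.02`, so the
   expected total is 21 logins; low users: `r = 0.811, d = 0.25`,
   expected total 3.6 with ~88% of sessions in the first two phases.
   Session starts fall on the reminder Monday with probability 0.28,
   otherwise uniformly on the other six days, at a uniform minute in
   waking hours (08:00–22:00 — the exact window matters to no computed
   metric). Durations are lognormal (sdlog 0.5, meanlog set so the means
   are 32.8 and 23.5 minutes), floored at 1 and capped at 180 minutes.
   A drawn session starting within the timeout of the previous session's
   end is dropped (it would merge on reconstruction).
2. **Opens.** Each session opens a Poisson number of distinct, unlocked,
   not-yet-opened ingredients (high 6.5, low 5.2 per session), working
   oldest-first, drawing from the earlier-phase backlog with probability
   `late_open_prob` (high 0.06, low 0.50). High users additionally skip a
   random 5% of the catalog permanently (`skip_prob`) — self-tailoring:
   not all generic content applies to every user — which is what lets
   them stay on schedule while opening ~90% of ingredients. Prompt-bearing
   opens emit a usefulness response drawn from archetype-specific
   (useful, not useful, blank) probabilities: (0.66, 0.18, 0.16) for
   high, (0.44, 0.20, 0.36) for low.
3. **Markers.** Contract open/sign in the first session (high 1.00/0.84,
   low 0.57/0.53), avatar (0.25/0.14), distress thermometers (Poisson
   means 5 and 1, at most one per calendar day, at most 13), one support
   email with probability 0.10.
4. **Keep-alives.** Real browsing produces a continuous request stream; a
   drawn session whose simulated events would leave an idle stretch
   longer than the timeout is padded with saves (`write_ingredient`) of
   an already-opened ingredient, or truncated when the user has nothing
   open to write to. Consequently re-sessionization recovers the drawn
   sessions *exactly*, which the test suite asserts.
5. **Nonusers.** 7 in 9 emit nothing at all; 2 in 9 emit a single
   1-minute login with no opens.
6. **Covariates** (age ~ N(50.9, 8.31); education on a 1–7 scale with
   mean ≈ 5; marital, children, employment, adjuvant-treatment and
   hormonal-therapy categories at the reference cohort's observed rates;
   baseline distress total ~ round(N(7, 5.8)), giving ≈ 27% at or above
   the elevated-distress cutoff of 11) are drawn **independently of
   archetype**, so any group comparison on them is a true null — the
   basis of the type-I-error property test.

Randomness is organised as one master seed plus per-user substreams
derived by stable hashing of the user id: the same seed reproduces a
cohort byte for byte, and enlarging a cohort never reshuffles existing
users.

**What the generator does and does not emulate.** It reproduces the
first-moment structure the evaluation depends on: archetype mixture,
mean frequencies and session durations, activity levels, Monday login
share, unlock discipline, engagement-marker rates, and the direction of
the late-open contrast (low users leave the planned structure more than
high users; the high-user late fraction runs somewhat above the reference
value, a known approximation). It does **not** attempt to match second
moments of totals (the reference total-duration SD is large relative to
its mean, suggesting heavier tails than a Poisson-lognormal composition
produces), per-user random effects in usefulness reporting (induced
per-ingredient, with per-user effects possible via custom
`archetype_params`), platform downtime, or browser-specific logging
failures. Passing tests therefore certify the *pipeline arithmetic* on
realistic log structure, not distributional fidelity of real cohorts
beyond the calibrated quantities.

```{r, eval = FALSE}
coh <- sample_cohort(cohort_config(n_users = 70, seed = 1))
res <- usage_evaluation(coh$events, coh$roster)
summary(res)
truth_report(coh$truth, res$groups$assignments)
```

## Problem sizes in the test suite

The suite exercises the sessionizer against a brute-force reference on
1000 random streams; the generator bands on 20 seeded 70-user cohorts
(archetype counts against binomial sampling error, group mean
frequencies, Monday share, classifier recovery ≥ 85% — the calibration
statistics are evaluated as study-level means over the 20 cohorts, whose
per-cohort values scatter with their own sampling error); Wilson coverage
on 10,000 binomial draws per true proportion; and the nominal size of the
group-comparison battery on 500 covariate-only cohorts (roster + truth
labels without event streams — the covariate model is identical and
event streams are irrelevant to a covariate null). These sizes were
chosen so each property is tested at meaningful power while the whole
suite stays quick to run routinely.

## Known limitations

* Exposure is request-based: what a participant does while a page is open
  is unobservable, so duration is the least reliable of the three
  singular statistics.
* Re-opens are not modelled (and typically not logged), so activity is a
  first-open measure.
* The per-week placement of ingredients inside phases is a documented
  canonical layout (`default_catalog()`); any true layout can be
  substituted from file, and all downstream code reads placement only
  from the catalog.
* Whether contract signing is a distinct logged request or inferred from
  saved form content varies by platform; it is modelled as a distinct
  `contract_sign` event here.
* No time-to-event modelling of attrition is attempted; adherence is a
  categorical phase-coverage measure.
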