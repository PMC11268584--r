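---
title: "forumdyn: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{forumdyn: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forumdyn)
library(data.table)
```

forumdyn analyses timestamped event logs from content-sharing forums: one
row per view or post, carrying an opaque user id, a content category with a
COPINE severity grade, and a UTC timestamp. This vignette documents the
models behind each stage, the parameters that matter, what the synthetic
generator does and does not emulate, and the choices made where the design
was genuinely open.

## Sessions

A *session* is a maximal run of one user's events in which every
consecutive gap is below an inactivity threshold. The threshold defaults to
60 minutes, the scale at which inter-event time distributions of forum
activity typically show a sharp drop in frequency; it is a parameter
(`gap_threshold`, minutes) everywhere it is used.

Three conventions needed fixing:

* **Boundary.** A gap of *exactly* the threshold starts a new session —
  "inactive for an hour or more" is read as `>=`. The generator places
  inter-session gaps strictly above and within-session gaps strictly below
  the threshold, so the boundary convention never decides a synthetic case.
* **Single-event sessions** have duration 0 and are included in all
  statistics (mean, survival fractions). There is no principled exclusion
  rule, and including them keeps the partition property exact: session
  event counts always sum to the stream length.
* **Event pooling.** Views and posts both constitute activity, so both
  enter segmentation by default; `event_types` exposes a filter.

`session_duration_stats()` reports the mean duration and the survival
fraction at probe durations (default 10 and 60 minutes). Inter-event times
are histogrammed in base-10 logarithmic bins from 1 minute to 60 days;
sub-minute gaps fall in the first bin.

## Periodicity

Activity rhythms are read from the 168-bin hour-of-week profile (UTC,
Monday 00:00 first). Aggregating calendar weeks aligns recurring daily and
sub-daily structure while averaging out one-off bursts. The classifier
takes the discrete Fourier spectrum of the mean-centred profile and
compares power at the three candidate harmonics — 7, 14 and 28 cycles per
week, i.e. periods of 24, 12 and 6 hours. The candidate with maximal power
is accepted only if

* the profile holds at least `min_events = 50` events,
* its power is at least `dominance_ratio = 2` times the runner-up
  candidate's, and
* it carries at least `min_power_fraction = 0.10` of total non-constant
  power.

Otherwise the user is classified `none`. Ties in candidate power break
toward the longer period — the coarser rhythm is the weaker claim.
Constant profiles have zero non-constant power and return `none` without
error. The statistic is invariant to the rhythm's phase and to rescaling
the profile, which the test suite asserts directly.

Counts, not normalised rates, feed the spectrum: normalising a profile
rescales every harmonic equally, so the classification is unchanged and
counts keep the `min_events` gate meaningful.

A practical consequence of the thresholds: confident calls need on the
order of a hundred sessions per user. On desk-scale default synthetic data
most users are censused as `none`; recovery tests therefore use a
high-activity configuration (lognormal activity with `meanlog = 7.3`,
`sdlog = 0.25`, amplitude 0.9), under which at least 95% of rhythmic users
are classified to their planted period.

## Preference clustering and entropy

Users are represented by their *view shares* per category — row-normalised
view counts — rather than raw counts, because shares remove
activity-volume confounding: a heavy and a light user with the same tastes
should cluster together. Users with fewer than `min_views = 100` views are
dropped first; below that, share vectors are mostly sampling noise. The
threshold is exposed because no canonical value exists.

Clustering is k-means with k-means++ seeding, keeping the best of
`restarts = 10` runs by within-cluster sum of squares. k-means++ matters
here: with plain random-row starts, runs regularly land in local optima
that merge one pair of archetypes and split another, which corrupts both
the assignments and the inertia curve that drives model selection.

The cluster count is chosen by the elbow rule: over a consecutive range
(default `k = 2..15`), select the interior `k` maximising the second
difference `I(k-1) - 2 I(k) + I(k+1)` of the inertia curve, ties toward
smaller `k`. A flat or strictly linear curve has no curvature; the smallest
`k` is returned flagged (`flat = TRUE`) with a warning rather than
pretending a structure exists. The maximum-second-difference rule is the
simplest formalisation of "marked decrease in variance gain"; other
curvature readings of the same verbal criterion can disagree on nearly-tied
curves, which is why the flag and the full second-difference vector are
returned for inspection.

Preference breadth is Shannon entropy in bits, `H = -sum(p log2 p)` with
`0 log 0 = 0`, ranging from 0 (single category) to `log2(M)` (uniform over
`M` categories). Base 2 is a convention; all comparisons are
within-pipeline, so the base affects scale only. Input vectors must be
non-negative and sum to 1 within `1e-9`; anything else is an error rather
than a silent renormalisation.

## The category network

Consumption is defined by viewing: a user consumed a category if they
viewed it at least once; posts do not create consumption edges. Prevalence
`P_i` is a *user count*, and `N` counts users with at least one view, so

```
RR_ij = C_ij * N / (P_i * P_j)
```

equals the lift `(C_ij/N) / ((P_i/N)(P_j/N))`: `RR = 1` is exactly
independence. Edges exist for pairs with `C_ij >= 1`; `filter_core()`
removes edges with `RR < rr_min` (default 1, keeping the boundary, since
only sub-independence links are discarded) and then nodes left isolated.
Filtering is idempotent.

The network's "core" is operationalised as the maximum k-core of the
filtered, unweighted graph: the innermost subgraph in which every category
retains at least `k_max` co-consumed neighbours. `core_composition()`
reports the COPINE-segment make-up of that core plus per-node coreness, so
alternative centrality readings remain possible. Two statistical
limitations are deliberate reproductions of the method as specified: RR
values carry no confidence intervals, and the `RR >= 1` cut involves no
multiple-testing correction across the ~2,200 category pairs.

## The synthetic generator

The generator exists so that every stage can be validated against known
ground truth; its defaults are the package's reference conditions, chosen
once and frozen.

**Activity.** Target views per user are lognormal
(`meanlog = 4.2`, `sdlog = 1.1`): a median of ~67 views, a mean of ~120 and
a heavy right tail reaching thousands, giving the familiar
few-heavy-users/many-light-users profile. A fraction
`producer_fraction = 0.2` of users also post, with post counts
`1 + Poisson(9)` (mean 10).

**Preferences.** Categories split into a Sexual segment
(`sexual_fraction = 0.5`, COPINE grades 7–10) and NonSexual blocks, one
block per archetype, of near-equal size. Every user spends a fixed
`core_overlap = 0.3` share of attention on the shared Sexual core, with
near-uniform within-core weights (Dirichlet precision
`core_concentration = 500`), and the rest on their archetype's block, with
within-block weights drawn at the archetype's concentration — 15 for the
three narrow archetypes, 80 for the five broad ones. Two properties follow
by construction: high-severity categories are consumed across all user
groups (producing the dense Sexual k-core), and archetypes are separated by
their blocks (making them recoverable by clustering, with narrow archetypes
showing lower entropy than broad ones). An earlier design that scattered
each user's core mass over few sexual categories (low per-category
Dirichlet α) was rejected: the user-level scatter overwhelmed the block
separation and made both elbow selection and archetype recovery unstable.
In the infinite-concentration limit the within-block weights become uniform
over the block — the Dirichlet limit applies to the archetype's support,
not to all categories, since the core share is fixed.

**Sessions and rhythms.** Events per session are `3 + Geom(0.12)` (mean
~10.3), with within-session gaps lognormal (`meanlog = 1.1`,
`sdlog = 0.9` minutes, mean ~4.5) truncated strictly below the 60-minute
threshold; consecutive sessions are separated by more than 61 minutes by
construction. Truncation on both sides makes the generated session
boundaries an *exact* oracle for the segmentation stage. A minimum of 3
events per session (rather than a plain geometric starting at 1) is what
lets one family satisfy the three reference session statistics
simultaneously — mean duration ≈ 40 min with ~85% of sessions over 10
minutes and ~25% over an hour; a plain geometric puts too much mass on
singleton sessions and caps the 10-minute survival near 78%. The frozen
parameters give mean ≈ 41.7 min, 85% ≥ 10 min and 23% ≥ 60 min in the
design calculation, which the acceptance checks confirm on generated logs.

Session starts follow a renewal process thinned by
`1 + rhythm_amplitude * cos(2*pi*t/P + phase)` for users with a planted
rhythm (`period_mix` default: 50% at 24 h, 20% at 12 h, 10% at 6 h, 20%
none; `rhythm_amplitude = 0.8`). The rhythm is imposed on session starts,
not individual events — the simplest mechanism that yields periodic weekly
profiles, since within-session events stay within the hour scale.
`session_gap_mean_hours` acts as a *floor* on a user's mean inter-session
spacing; pacing otherwise spreads each user's sessions across the window,
because no single population-wide mean gap can both let a
150-session user fit the window and keep a 5-session user sparse. Sessions
that would cross the window end are dropped whole, keeping the session-size
law intact.

**Scale.** Defaults are desk scale: 500 users over 8 weeks (~60,000
events, ~6,000 sessions — enough for survival fractions at sub-percent
standard error), and 1,000 users where clustering structure is the object.
The full test suite runs in well under a minute of simulation time at these
sizes.

**What the generator does not emulate.** No text, replies or user-to-user
social structure; no growth dynamics (the real cumulative view curves are
sigmoidal as a forum takes off, while the generator is stationary within
the window); no seasonal or weekday/weekend structure beyond the planted
harmonics; producers are a configurable subset of consumers because real
producer/consumer overlap statistics are unavailable. Passing recovery
tests on this generator therefore demonstrates the pipeline's correctness
on data with the assumed structure, not robustness to every feature of
real forum logs.

## Numerical and degenerate-input conventions

* Timestamps are UTC throughout; input without an explicit UTC marker is
  rejected rather than guessed. Ties in timestamp keep file order (stable
  sort), so segmentation is deterministic.
* All generator randomness flows from one seed; population and event
  generation use decoupled seeds so the same population can be re-simulated.
* k-means++ seeding samples only points distinct from already-chosen
  centers; when `k` reaches the number of distinct rows the fit is the
  exact zero-inertia assignment.
* Share vectors must sum to 1 within `1e-9`; cumulative series are built on
  complete day grids so days without events carry the previous value.
* Degenerate periodicity inputs (constant or empty-power profiles) return
  `none`; elbow selection on curvature-free curves returns the smallest
  `k`, flagged.
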