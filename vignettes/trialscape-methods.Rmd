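---
title: "Methods: collaboration-network analysis of trial registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collaboration-network analysis of trial registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialscape)
```

This vignette documents the statistical machinery of `trialscape`: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic registry generator does and does not
emulate, and the numerical conventions that make runs reproducible.

## From registry rows to analysable records

A registry extract is a table with one row per registered trial: an opaque
identifier, a start date, a free-text primary sponsor, and a delimited list
of country locations. `read_trials()` reduces the start date to a calendar
year (all analyses here are annual), resolves country names to ISO alpha-2
codes against the bundled reference table plus an extensible alias list,
and classifies the sponsor.

Sponsor classification is keyword-based: corporate suffixes and pharma
vocabulary ("Ltd.", "Inc.", "GmbH", "Pharma", ...) mark industry sponsors;
academic and public-sector vocabulary ("University", "Hospital",
"Ministry", ...) marks non-industry sponsors. Matching is case-insensitive
with word boundaries, so "Inc" does not fire inside "Incidence". Two
conventions are deliberate:

* **Conflicts resolve to `unknown`.** If a name matches both lists
  ("University Hospital Pharma Ltd.") no precedence is imposed; the trial
  is excluded by `filter_period()` alongside unmatched names. This is the
  conservative reading — in comparable registry analyses a few percent of
  trials are dropped for unclear sponsorship rather than guessed.
* **Ambiguous words stay off both lists.** "Foundation" names both
  charities and corporate foundations, so it classifies as `unknown` unless
  a user extends a list. The shipped lists are short; `sponsor_keywords()`
  accepts arbitrary replacements.

Records are kept when the start year lies in 2006–2013 — the window from
the point registration became a publication requirement up to the last
year with complete coverage — and deduplicated on the trial identifier,
keeping the record with the larger country set (registry mirrors tend to
truncate location lists rather than invent locations). Unresolvable
country names drop the location, not the trial, unless no location
remains; every exclusion is recorded in a report rather than silently
discarded. Cross-registry *semantic* duplicates (the same study registered
under different identifiers) are out of scope.

## Mapping metrics

Trial density is trials per million inhabitants, using 2012 populations.
Two reportability guards avoid unstable small-denominator values: density
is only reported for countries above 250,000 inhabitants, and per-country
proportions (industry share, international share) only where the relevant
denominator reaches 50 trials. The threshold is read inclusively (≥ 50).
Group medians treat countries as equal units — they are medians across
countries, not trial-weighted. In every per-country tally an international
trial counts once for each of its countries; annual distributions likewise
count country *locations*, so a trial in two South American countries
contributes two South American locations that year. Scope is
`single_country`, `international_unicontinental` or
`international_intercontinental` using the reference table's single
continent assignment per country (transcontinental countries such as
Russia or Turkey carry one editable assignment).

## The fixed-margin null model

The central inferential question: do countries i and j appear together in
more trials than expected, *given how international each country is and
how many countries trials tend to span*? The conditioning matters — two
very active countries co-occur often by volume alone. The null model
therefore fixes both margins of the binary trials × countries incidence
matrix (only international trials enter it; single-country rows have
nothing to contribute to co-occurrence) and treats all matrices with those
margins — the fill class — as equally likely.

Sampling uses curveball trades: two random rows exchange a random subset
of the columns they do not share. Each trade preserves both margins
exactly, and the resulting Markov chain converges to the uniform
distribution on the fill class. The implementation (in C++) supports two
regimes:

* **`mode = "chain"` (default):** one long chain, burn-in of five trades
  per row, then one sample per full sweep (one trade per row). This is the
  fast path — successive samples share most of their structure, but
  per-pair summaries average over many samples and the thinning keeps
  autocorrelation low.
* **`mode = "independent"`:** every replicate restarts from the observed
  matrix and applies five trades per row. Used for the uniformity tests,
  where independence assumptions of the chi-square test must hold.

The test suite verifies uniformity directly: on a 4×4 fixture whose fill
class is small enough to enumerate exhaustively, 50,000 sampled matrices
are compared to the uniform distribution by chi-square.

Per-pair null distributions are accumulated as bounded integer histograms
— co-occurrence cannot exceed the smaller column margin — so memory is
O(pairs × max margin) regardless of the replicate count, and 90,000
replicates are unproblematic.

### Percentile, flagging, and the degree of overrepresentation

The threshold is the empirical 99.9th percentile, computed as the
`ceiling(0.999 n)`-th order statistic without interpolation, so "the value
below which 99.9% of observations fall" holds exactly on the sample. With
90,000 replicates the binomial half-width of that coverage is
100·sqrt(0.999·0.001/90000) ≈ 0.01 percentage points. Flagging uses strict
inequality (`observed > q999`): ties at the percentile are not flagged,
which is conservative and interacts sensibly with the integer-valued
distributions. Underrepresentation is not tested.

Flagged pairs get a degree of overrepresentation
`D = (observed − null_mean)/(null_q999 − null_mean)`, the distance above
the null mean in units of the mean-to-percentile distance. A flagged pair
whose null distribution is degenerate (percentile equal to the mean)
cannot carry a degree; such pairs are reported separately rather than
assigned an arbitrary value.

Because co-occurrence counts are integers, the realized size of the test
sits at or below the nominal 0.1%: `null_calibration()` estimates it by
comparing held-out null replicates against the estimated thresholds. In
the shipped study conditions it comes out near 0.07% over 1.2·10⁵
pair-tests.

### Trimming

Sparse countries make the null percentiles degenerate, so before testing,
countries are removed one at a time — always the one currently in the
fewest international trials, ties broken alphabetically, margins
re-evaluated after each removal — while the retained total pairwise
weight stays at or above the retained fraction (0.95 for the denser
industry network, 0.90 for non-industry). Rows reduced below two countries
are dropped with their country. The trimmed matrix remembers its pre-trim
reference total, which makes trimming idempotent. Descriptive
co-occurrence networks are computed untrimmed; trimming applies to the
null-model stage only.

## Map-equation clustering

The co-occurrence network (flagged pairs, edge weight D) is partitioned by
minimizing the two-level map equation. For an undirected weighted network
the random walk's stationary visit rates are strength-proportional
(`visit_rates()`, no teleportation — appropriate because the network is
undirected and connectivity is handled separately), and for a partition M
into modules m:

$$L(M) = q\,H(Q) + \sum_m p_m^\circ\,H(P_m)$$

where `q` is the total module-exit rate, `H(Q)` the entropy over module
entries, and each module's codebook entropy `H(P_m)` covers its nodes'
visit rates plus its exit rate. With one module the exit terms vanish and
L is the entropy of the visit rates — a useful analytic anchor used in the
tests, alongside an independently written term-by-term oracle and
brute-force enumeration of all 52 partitions of 5-node graphs.

The optimizer is a greedy agglomerative search: starting from singletons,
repeatedly merge the connected pair of clusters whose merge most decreases
L; then sweep single-node moves to neighbouring clusters (or a fresh
singleton) until no move helps; repeat both phases to convergence, over
`n_restarts` seeded random sweep orders, keeping the best partition. Merge
ties break toward the lexicographically smallest cluster pair, so results
are deterministic given the seed. Disconnected components are clustered
independently and never merged. The two-level (flat) variant is
implemented; hierarchical clustering is out of scope, matching the flat
cluster lists this analysis reports. Exact cluster counts on real
registry data are data- and search-dependent and are not treated as a
reproducible invariant.

## The synthetic registry generator

`generate_registry()` draws, per country, a Poisson number of anchored
trials with mean `base_rate[income] × population / 10⁶ × rate_scale`; each
trial gets a sponsor (income-group industry fraction), a uniform year in
2006–2013, and becomes international with the sponsor-specific
probability. International trials draw their country count
`k = 2 + Geometric(p)` and elect `k − 1` partners without replacement with
probability proportional to `sqrt(population in millions)` times the block
affinity when anchor and partner share a planted block.

Defaults are the study conditions:

| parameter | default | rationale |
|---|---|---|
| `base_rate` (per million, 2006–2013) | 116 / 13.8 / 1.8 / 1.1 by income group | typical median densities from high- to low-income |
| `industry_fraction` | 0.516 / 0.660 / 0.654 / 0.093 | industry share of trials by income group |
| `p_international` | 0.303 industry, 0.032 non-industry | observed internationality by sponsor |
| `k_geom_prob` | 0.55 industry, 0.18 non-industry | put the k-medians at 2 and 5 (CDF: P(k ≤ 4) < 0.5 ≤ P(k ≤ 5) requires p ∈ [0.159, 0.206)) |
| partner size weight | sqrt(pop in millions) | see below |
| `rate_scale` | 1 (callers scale down) | problem-size dial that leaves the per-income structure untouched |

Two generator design choices deserve explanation:

* **Square-root size weight.** With weights linear in population, a
  planted block of mid-sized countries controls ~2% of the total election
  weight, and even a five-fold affinity cannot produce co-occurrence
  excess beyond what the margins explain — the generator would be unable
  to plant the very structure the null model exists to find. The square
  root reflects that participation breadth grows subproportionally with
  country size and gives affinity multipliers real leverage.
* **Anchor-based election.** A trial is one anchor country plus elected
  partners. This is simple and sufficient to plant excess, but it is *not*
  exactly the margin-conditioned uniform distribution: at large registry
  sizes a few percent of popular-country pairs deviate detectably from the
  fixed-margin null even without blocks. That is a feature real registries
  share (real data are not the null either), but it means type-I
  calibration must use held-out null replicates (`null_calibration()`),
  not generator output, and the no-block false-positive check runs at a
  scale where the mismatch is below detection.

What the generator does **not** emulate: disease areas and phases,
enrolment sizes, temporal drift in collaboration patterns, continent-aware
partner preferences, registry-specific quirks in sponsor naming. Passing
tests therefore demonstrate the pipeline's statistical correctness under
controlled structure, not fidelity of any particular real-world cluster
map.

## Study sizes and numerical conventions

The shipped tests and the acceptance script use these problem sizes,
chosen so each check has clear statistical power while the whole suite
runs in minutes on one core:

* Main pipeline study: `rate_scale = 0.05` (~7,500 trials), 20,000 null
  replicates per sponsor network.
* Shares/medians measurement: `rate_scale = 0.5` (~75,000 trials), so the
  scarce non-industry international class (~1,000 trials) pins its median
  and percentage stably.
* Type-I calibration: thresholds from 5,000 replicates, ≥ 1.2·10⁵
  held-out pair-tests.
* Planted-block study: two affinity-5 blocks of five large countries each
  (Western Europe: DE FR GB IT ES; Americas: US CA MX BR AR) at
  `rate_scale = 0.4` — roughly 1,300 and 1,800 block trials, comfortably
  beyond the ~200 needed — with 5,000 replicates. At this scale the
  weakest within-block pair sits ≈ 4 null SDs above its flagging
  threshold, so ≥ 90% within-block sensitivity has real margin; smaller
  studies leave the weakest pairs on the detection boundary.

Reproducibility conventions: every stochastic entry point takes a seed;
`run_pipeline()` derives recorded per-stage sub-seeds from one root seed;
the C++ sampler draws from R's RNG so `set.seed()` governs everything.
Degenerate inputs (empty registries, zero international trials, forced
single-member fill classes) short-circuit with valid empty results rather
than errors. Optimizer comparisons use a 10⁻¹² tolerance to keep merge
decisions stable under floating-point noise.

## Known limitations

* Keyword classification inherits the biases of its lists; the shipped
  lists are minimal and meant to be extended per registry.
* The bundled 40-country table is a synthetic-but-realistic stand-in for a
  full World Bank extract; analyses of real extracts should substitute a
  complete table via `country_table(path=)`.
* The chain sampler's effective sample size is below its nominal replicate
  count; the defaults (burn-in 5 trades/row, thinning 1 sweep) were
  adequate in uniformity and oracle tests, but heavily structured matrices
  may warrant the independent mode for verification.
* Cluster counts from greedy map-equation search are not a stable
  statistic across seeds on weakly structured networks; only strongly
  separated structure is reproducibly recovered.
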