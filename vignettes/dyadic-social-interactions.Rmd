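---
title: "Quantifying dyadic social interactions in split arenas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic social interactions in split arenas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysin)
```

## The assay and its statistics

`flysin` analyzes a paired-fly assay in which two flies occupy the two
semicircular compartments of a 30 mm circular arena bisected by a removable
1.5 mm interaction barrier. The barrier comes in four types that gate the
sensory channels between partners: clear acrylic passes visual cues, black
blocks them; "open" barriers have airflow channels that pass olfactory cues,
"solid" barriers do not. Each fly is free to approach its side of the
barrier — and its designated partner — or not, and video tracking yields a
centroid trajectory per fly at 29.9 frames/s.

The central statistic is the **interactivity index** of a dyad: the Pearson
correlation between the two flies' distances to their own barrier faces over
the session,

$$ r = \mathrm{cor}\big(d_A(t),\, d_B(t)\big), $$

where $d_A(t)$ is the Euclidean distance from fly A's centroid to the face
segment of the barrier bounding A's compartment. Either sign of $r$ carries
meaning — coordinated approach versus avoidance — so group comparisons use
the mean *absolute* index. A second statistic, **coincidental approaches**,
counts maximal episodes in which both flies are simultaneously within one
body length (3 mm) of the barrier; an episode counts once regardless of
duration, and a new episode requires at least one fly to leave and re-enter
the zone. Counts are normalized by the dyad's grand mean speed so that fast
dyads are not trivially scored as more social.

Dyad specificity is established against a **shuffled-pair null**: flies
recorded simultaneously in the same session are re-paired across arenas into
fictive dyads (true pairings excluded), and the index is recomputed on the
time-aligned series. Because the index is a temporal correlation, shuffling
across sessions would be meaningless; `shuffled_null()` therefore only
re-pairs within a session, in either a side-preserving or a side-free mode
(the assay description does not say whether the original shuffle preserved
compartment side, so both are exposed; side-free is the default as it is the
larger null universe).

Persistence of dyadic behavior across days is measured by the Pearson
correlation of per-dyad indices between day pairs, tested with the Fisher
transform $z = \operatorname{atanh}(r)\sqrt{n-3}$ against a standard normal
(two-tailed). Signed indices are correlated by default; an absolute-value
mode exists because the choice is not fixed by the assay definition.

A **social interaction network** (SIN) has flies as nodes and an edge for
every measured dyad whose absolute index strictly exceeds a threshold
derived from the population: the mean of the first and third quartiles of
all dyads' absolute indices. Quartiles use linear interpolation between
order statistics (quantile type 7), the dominant convention; the rule text
is recorded on every graph, and the day-1 threshold can be reused for later
days (recorded as such). With continuous indices this threshold lies
between the quartiles, so the edge fraction is bounded between 0.25 and
0.75 — a property the test suite checks on simulated data.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `body_length` | 3 | mm | approach-zone width (boundary inclusive) |
| `speed_threshold` | 0.1 | mm/s | immobility/activity cut on mean speed |
| `fps` | 29.9 | frames/s | video frame rate |
| `n_boot` | 1000 | — | bootstrap resamples for standard errors |
| `alpha` | 0.05 | — | significance level (Bonferroni-adjusted) |
| `max_gap_frames` | 15 | frames | longest interpolated tracking dropout |

The immobility screen discards a dyad when either member's session-mean
speed is at or below `speed_threshold`, because the index is undefined for
a constant distance series (zero variance). The 0.1 mm/s default reuses the
activity threshold of the locomotor control assay — the only printed speed
anchor — and is configurable. `max_gap_frames` of 15 (about 0.5 s) is long
enough to bridge blinks of the tracker and short enough not to fabricate
approaches; interpolated frames can be excluded from all statistics by
setting `use_imputed = FALSE` in `analysis_config()`, since whether the
original analysis scored imputed frames is unknown.

Numerical conventions worth stating: "within one body length" is read as
$d \le 3$ mm (the closed reading; the choice is measure-zero for continuous
data). Invalid frames are deleted pairwise for the index and never fabricate
an exit between approach episodes — an episode ends only at a frame where a
fly is observably outside the zone. Group contrasts use Welch's
unequal-variance t-test (the robust default where the test family is not
otherwise pinned down), and the two-sample KS p-value uses the asymptotic
Kolmogorov distribution with effective size $n_x n_y/(n_x+n_y)$, adequate at
the dyad counts this assay produces (tens and up) and a documented
limitation for tiny samples.

## Pairing schemes and schedules

Three dyad designs are supported: disjoint random pairs (every fly in
exactly one dyad; highest throughput), a k-regular design (every fly in
exactly `k` dyads; any simple k-regular pairing graph is admissible and one
is sampled uniformly), and the saturated design of all $\binom{n}{2}$ pairs.
Saturated designs are scheduled as a round-robin tournament by the classical
circle method: $n-1$ rounds per pass, each round a perfect matching, so
every fly is assayed exactly once per round and every dyad appears exactly
once per pass. Odd cohorts (bye rounds) are not supported.

## What the synthetic generator emulates

`simulate_dyad()` produces centroid tracks with the statistical structure
the analyses assume, not biomechanically realistic fly locomotion. Each fly
performs a reflected Gaussian random walk (step SD 0.35 mm/frame) confined
to its compartment. Along the barrier axis the walk mean-reverts at rate
0.02 per frame toward a target distance that blends the fly's home distance
(4 mm) with the partner's current barrier distance; the blend weight is the
effective coupling

$$ \kappa = \pm\big(w_v \cdot \text{vision open} \cdot \text{masks} +
   w_o \cdot \text{olfaction open} \cdot \text{masks}\big), $$

gated by the barrier type and the two genotypes' channel masks (anosmic
knocks out $w_o$, blind knocks out $w_v$, reduced acuity divides the visual
term). For this mutually tracking linear system the stationary correlation
of the two distance series equals $\kappa$ (the symmetric and antisymmetric
modes relax at rates $\theta(1\mp\kappa)$, giving variances proportional to
$1/(1\mp\kappa)$ and hence correlation $\kappa$), so the interactivity
index is controlled, signed, and monotone in the coupling. An earlier
design — a saturating proximity drive added to a constant barrier-ward
drift — was abandoned because it is not monotone: strong coupling parks
both flies at the barrier, the drive becomes constant, and the index
collapses. A 300-frame burn-in is discarded before recording so that both
flies start from their stationary occupancy; without it the shared
approach-the-barrier transient masquerades as positive correlation.

The channel weights ship calibrated (coarse grid search;
`inst/scripts/calibrate-weights.R`): $w_v = 0.15$, $w_o = 0.30$. The
olfactory channel deliberately carries about two thirds of the open-clear
coupling so that an anosmic genotype retains roughly a third of the
wild-type mean absolute index — mirroring the large olfactory effect
observed in this assay — while a fully occluded (solid-black) barrier sits
at the null level by construction. Sessions default to 10,000 frames
(about 5.6 min at 29.9 fps); full hour-long sessions are a parameter away.
Immobility (probability 0.03 per fly-session, matching the observed ~3%
discard rate) and per-frame tracking dropouts (0.005) are included so the
screening and gap-handling code paths are exercised.

`simulate_experiment()` adds the across-day structure: each fly draws a
latent sociability, evolved across days as an AR(1) process with retention
`persistence_rho` (default 0.8); a dyad's signed coupling on a day is
$\tanh(s_i s_j)$ scaled onto the channel weights. Latents are fly-level so
networks show realistic degree heterogeneity. Day-to-day index correlation
is therefore controlled by `persistence_rho` (the latent product decorrelates
as $\rho^2$ per day), and the test suite verifies it recovers monotonically
over a $\rho$ grid.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: pheromone diffusion and visual-field physics, posture
and orientation, wall-following and thigmotaxis, circadian drift within a
session, or any asymmetry between compartments. Conclusions about real
flies must come from real trajectories; the generator's job is to give the
pipeline inputs with known ground truth.

## Problem sizes

The shipped tests and the reproduction script run at desk scale, chosen as
the smallest sizes at which each property is comfortably resolved: null and
type-I checks use 15–20 dyads at 600–1000 frames; persistence recovery uses
20-dyad cohorts at 1500 frames averaged over replicates; the calibration
check uses 100–200-dyad batches at the full 10,000-frame session. Headline
effect sizes from the original hour-long recordings (where a session has
~107,000 frames and null indices are an order of magnitude tighter) are not
expected to reproduce numerically at these sizes; the qualitative structure
— orderings, signs, monotonicities, null levels — is what is checked.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
ex <- simulate_experiment(
  n_flies = 20, scheme = dyad_scheme("scheme1_disjoint", 20),
  days = 2, params = coupling_params(), n_frames = 3000, seed = 1)
tbl <- dyad_metric_table(ex$dyads)
head(tbl[c("dyad_id", "day", "interactivity_index",
           "coincidental_approaches", "excluded")])

# dyad specificity: observed vs shuffled
day1 <- Filter(function(d) d$day == 1, ex$dyads)
nd <- shuffled_null(day1, n_perm = 200, seed = 2)
ks_two_sample(tbl$interactivity_index[tbl$day == 1 & !tbl$excluded],
              nd$values)

# persistence and the network
day_persistence(tbl, 1, 2)
idx1 <- tbl[tbl$day == 1 & !tbl$excluded, ]
thr <- sin_threshold(idx1$interactivity_index)
g1 <- build_sin(idx1, thr, day = 1)
g1
```

## Known limitations

* The KS p-value is asymptotic; do not trust it below ~10 values per side.
* The round-robin scheduler requires even cohorts.
* The turn classifier for Y-maze handedness reconstructs a standard
  sector/distal-half rule; any consistent convention gives the same bias
  distribution up to a global left/right flip, but absolute "R" labels are
  convention-dependent.
* `shuffled_null()` requires simultaneously recorded dyads and truncates
  all series to the shortest; ragged sessions lose frames.
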