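---
title: "Methods: specimen-database change classification and its conservation-assessment impacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: specimen-database change classification and its conservation-assessment impacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Curated specimen databases change: specialists add specimens, correct
misidentifications, rename species, lump and split taxa, and georeference
old collections. Each of those curatorial acts can move the occurrence
points behind a species' extent of occurrence (EOO) and hence its
preliminary extinction-risk category. `specshift` makes that process
quantitative. Given two snapshots of the same database a decade apart, it

1. classifies every record-level difference into nine change classes,
2. computes EOO-based preliminary IUCN Criterion B categories per species
   per snapshot,
3. compares the two assessment rounds (transition matrix, per-category
   Sorensen turnover, per-species EOO changes, conjugate Bayesian tests),
   and
4. attributes a hypothetical EOO impact to every single specimen change
   with a one-change-at-a-time counterfactual.

A seeded simulator generates snapshot pairs with a ground-truth change
log, so every stage can be validated against truth.

# Data model

A record is an identified, optionally georeferenced specimen: stable
`record_id`, `scientific_name`, `rank` (species or genus — genus-rank
records are specimens not yet fully determined), decimal-degree
coordinates, collection year, databasing year. Coordinates are stored
rounded to 6 decimals; the reader also records the source precision
(minute, second, or decimal) because historic georeferencing to the
nearest latitude–longitude minute sets the natural scale for deciding
when coordinates have "really" changed. A record is georeferenced iff
both latitude and longitude are present; partial coordinates are rejected
as malformed rather than guessed at. Records identified only to genus
carry the bare genus name; rank is always consistent with the presence of
an epithet.

# Change classification

Records are matched across snapshots by `record_id`, partitioning ids
into additions, persisting records, and disappeared records. Disappeared
records and records that *lose* their georeference are reported as
anomalies rather than change classes: a curated database is not expected
to delete records, and surfacing such rows separately keeps the class
table honest.

For each persisting record the differ emits at most one name event and
one geography event:

* **Rank transitions first.** Genus → species is `upgraded_to_species`,
  species → genus is `downgraded_to_genus`, before any other logic —
  including the curation map. A rank transition is observable directly
  from the data and is never ambiguous.
* **Curation map second.** The map is a three-column table (old name, new
  name, action ∈ nomenclatural/lump/split) encoding specialist knowledge
  that is simply not recoverable from coordinates and strings: whether a
  whole-species rename was a pure nomenclatural act or a lump of one
  concept into another.
* **Movement heuristic last.** Without a map entry: a move to a name
  already present in the earlier snapshot is a `correction` (the specimen
  joined an existing concept); a whole species moving to one new name
  while its old name disappears is a `lumped` event, flagged
  low-confidence because mass correction is observationally identical; a
  proper subset moving to a name absent earlier is a `split`; anything
  else falls back to `correction`.

Geography events compare coordinates against a tolerance of 1/120° (half
an arc-minute, i.e. half the minute precision of the source data):
gaining coordinates is `new_coordinates`, a move beyond tolerance on
either axis is `corrected_coordinates`.

# EOO and preliminary categories

EOO is the area of the minimum convex polygon around a species' distinct
georeferenced points. Points are projected with a cylindrical equal-area
projection on an authalic sphere (radius 6371.0072 km), with the standard
parallel and central meridian at the point centroid; the projection is
exactly area-preserving on the sphere, and recentring keeps shape
distortion negligible at range scale (whole-set shifts of 0.1° change
EOO by well under 1%). Inputs spanning 180° of longitude are rejected
with guidance rather than silently wrapped. The hull comes from
`grDevices::chull` and its area from the shoelace formula; tests check
both against an independent gift-wrapping oracle and a geodesic
polygon-area reference.

Categorization follows Criterion B on EOO alone (no subcriteria), with
strict thresholds: EOO < 100 km² → CR, < 5,000 → EN, < 20,000 → VU,
< 30,000 → NT, else LC. Criterion B itself defines no NT bound; 30,000
km² is the convention popularized by the preliminary-assessment tools
used for plants, and it is configurable. Species with fewer than 3
*distinct* points are DD — duplicates at minute precision carry no area
information, so deduplication happens before the rule (documented,
configurable convention; the alternative — counting raw records — can
only move species out of DD). Three or more collinear points give EOO 0
and hence CR, not DD: the polygon is computable, merely degenerate.
Exactly-threshold values take the less-threatened side (20,000 km² is
NT, not VU), matching the strict-inequality phrasing of the criterion.

Gridded summaries count georeferenced specimens and distinct species per
cell of a *fixed* global equal-area grid (standard parallel at the
equator, square cells of 10,000 km² by default), so counts are
comparable across snapshots and their difference table is meaningful.

# Category dynamics

Species are matched across years by name **after harmonization**: the
earlier snapshot's records are rewritten to the names they carry in the
later snapshot (record-level, via the change log), putting both years on
one taxonomy. The transition matrix, turnover and per-species EOO tables
use harmonized names; the raw category-count comparison does not —
counting each year under its own taxonomy is what "number of species
assessed as X in year Y" means.

Turnover per category is Sorensen dissimilarity, (b+c)/(2a+b+c), between
the two years' species sets in that category. Threat ordering for the
per-species table is LC < NT < VU < EN < CR; DD sits outside the
ordering, so transitions into and out of DD are reported as their own
classes (`from_DD`, `to_DD`) and excluded from the less/more-threatened
percentages. "Threatened" means VU ∪ EN ∪ CR, and the threatened
proportion is computed among non-DD species (the paper-style binomial
comparison is about assessable species; including DD in the denominator
would conflate data accrual with status change).

# Conjugate Bayesian comparisons

Count-vector differences use independent conjugate posteriors: Dirichlet
(pseudo-count α = 1, the uniform prior; Jeffreys α = 1/2 available) for
multinomial category or change-type profiles, Beta(1, 1) for the
threatened proportion. 10,000 Monte-Carlo draws from each posterior give
the difference distribution (later minus earlier); a difference is
significant when 0 falls outside the central 95% credible interval. Zero
exactly on an interval endpoint counts as *not* significant — a
probability-zero event under continuous posteriors, fixed by convention.
Monte-Carlo summaries rather than analytic convolutions keep the
procedure transparent and make the seed the only source of randomness in
the entire analysis of a fixed snapshot pair. Calibration is tested: at
null (equal true proportions) the 95% intervals cover 0 at a rate of
0.95 ± 0.02 over 1,000 replicates, and posterior means match the
analytic (count + α)/(total + Kα) form.

# Counterfactual impact attribution

For each specimen change, the affected species' hypothetical EOO is
computed from its 2007 occurrence set with *only that change* applied,
using the 2017 data for the changed specimen; the attribution is
`hypothetical − 2007` EOO. Conventions, where the procedure needs them:

* Purely nomenclatural events are excluded — they move no locality data.
* A record with both a taxonomic and a geographic change contributes its
  taxonomic change only (taxonomic precedence).
* A correction touches two species: `correction_out` removes the
  specimen's 2007 point from the losing species, `correction_in` adds
  its 2017 point to the gaining species.
* Lumps are attributed as additions to the receiving species; splits as
  removals from the source species (the newly recognized species has no
  2007 EOO to perturb). Rank upgrades add, downgrades remove; new
  coordinates add the fresh point; corrected coordinates substitute it.
* When a species' 2007 EOO is the DD signal (fewer than 3 points), the
  default `"zero"` mode treats it as 0 km² in the subtraction and flags
  the row; dropping such rows (`"skip"` mode) is available but would
  bias the `new_coordinates` class, which is precisely the class that
  makes species assessable.

In-tasks can only grow a hull and out-tasks only shrink one, so the sign
constraints (in ≥ 0, out ≤ 0) are structural and tested on all simulated
corrections. Per-type summaries report mean ΔEOO with standard error
(sd/√n); the change-type profiles of category-changing versus stable
species are compared with the multinomial difference posterior above,
restricted to species whose category-change status is defined (present
in the matched species set).

# The simulator

The generator emulates the statistical structure of a decade of
monographic curation, not any real taxon. Defaults, chosen once from the
published regime of such databases and fixed:

| parameter | default | what it encodes |
|---|---|---|
| `n_species` | 700 | large monographed genus |
| `specimens_median`, `specimens_sdlog` | 7, 1.1 | right-skewed specimens per species (~9,000 baseline records) |
| `bbox` | −35..12°, −82..−34° | Neotropical window |
| `range_sd_median`, `range_sd_sdlog` | 0.75°, 0.6 | clustered per-species ranges, log-normal across species |
| `p_ungeoreferenced` | 0.2 | ~80% georeferenced |
| `p_genus_rank` | 0.06 | undetermined specimens available for upgrades |
| `new_specimen` | 0.582 | ~58% record growth over the decade |
| `nomenclatural`, `lumped`, `split` | 0.27, 0.033, 0.033 | species-level events; renames dominate; the split rate is scaled up by the ~1/3 share of records that actually moves in a split |
| `correction`, `downgraded_to_genus` | 0.061, 0.0042 | per eligible (stable, species-rank) record |
| `upgraded_to_species` | 0.72 | per genus-rank record |
| `new_coordinates`, `corrected_coordinates` | 0.116, 0.010 | per un-/georeferenced record respectively |
| `p_collected_before_cutoff` | 0.79 | additions are mostly old specimens databased late |

Rates are per *eligible* record (or per species for the species-level
classes), so the record-level marginals land near the intended decade
profile: additions ≫ nomenclatural ≫ the remodeling, correction, rank
and georeferencing classes.

Mechanics worth knowing: species-level events are mutually exclusive per
species; lump receivers are drawn from untouched species; split subsets
are the smaller k-means (k = 2) cluster of the species' projected points,
so splits are geographically coherent and their ΔEOO is nontrivial
(exactly two distinct localities split one-and-one — the clustering
routine cannot handle that case); corrections move single records to an
existing, name-stable species; every lump/split/nomenclatural pair is
emitted in the curation map; each record gets at most one name and one
geography event; coordinate corrections move points 3–30 arc-minutes
toward the box centre so they always exceed the differ's tolerance and
never leave the box. The master seed drives stage-specific streams
(baseline = seed, curation = seed + 1), so stages are independently
reproducible.

What the simulator does *not* emulate: real nomenclature, collector or
herbarium metadata, spatial sampling bias beyond the bivariate-normal
range model, geographically plausible correction targets (a corrected
specimen may jump across the continent, inflating `correction_in` ΔEOO
relative to curation of sympatric look-alikes), record deletions, or
coordinate loss. Green tests therefore demonstrate algorithmic
correctness and calibration on ground-truthed structure — not that any
particular real database behaves like the defaults.

# Validation strategy and problem sizes

The test suite runs entirely on code-built fixtures: hand-computable toy
sets for every operation's contract, property checks under fixed seeds,
and dual-route oracles (gift-wrapping + shoelace for hulls on 500 random
point sets at 1e-6 relative tolerance; geodesic polygon area for the
projection; `vegan`'s Bray–Curtis on presence/absence for Sorensen; the
simulator truth log for end-to-end class recovery over 20 seeds at ~350
species ≈ 5,000-record scale; 1,000-replicate null calibration for the
credible intervals; 1,000 randomized cases for EOO monotonicity and the
DD rule). The analysis scripts and the acceptance script run the full
~700-species configuration.

# Known limitations

* The lump-versus-mass-correction ambiguity is decidable only with the
  curation map; heuristic lumps are flagged low-confidence and should be
  reviewed.
* EOO ignores Criterion B subcriteria and AOO entirely — by design, these
  are *preliminary* assessments.
* The cylindrical equal-area projection degrades near the poles and the
  antimeridian; the package rejects rather than guesses there.
* The counterfactual is strictly one-change-at-a-time: joint effects of
  several changes to one species do not decompose into the per-change
  attributions.
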