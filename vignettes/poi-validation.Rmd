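---
title: "Validating geocoding-service POIs for obesogenic built-environment assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating geocoding-service POIs for obesogenic built-environment assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obesopoi)
```

## The problem

The obesogenic environment is the sum of built-environment influences that
promote obesity: the density of fast-food outlets, the availability of
sports facilities, green space, transit access, and so on. Online geocoding
services — a commercial place database driven partly by official registries
("google" in this package) and a volunteered-geographic-information map
("osm") — expose these amenities as points of interest (POIs) and are an
attractive, low-cost data source for health surveillance. But a database
hit is not a real amenity: services contain entries with no real-world
counterpart (commission errors) and miss amenities that exist on the
ground (omission errors). Before POI counts can inform epidemiology, the
databases must be validated against field truth.

obesopoi implements that validation pipeline: parse service exports, map
raw service labels onto environmental factors and six broader categories
(food, doctor, sport, education, transport, other), restrict records to
defined search areas, and score audited hits with sensitivity and positive
predictive value (PPV), overall and per category.

## The evidence-ratio rule

Which environmental factors matter, and in which direction, is decided
from literature evidence counts. For a factor with $n_+$ studies reporting
a significant positive correlation with weight status and $n_-$ reporting
a significant negative one (studies with no significant association are
ignored):

* fewer than three significant publications ($n_+ + n_- < 3$): the
  evidence is **insufficient**;
* $n_+ / n_- \ge 2$: overall **positive** correlation (obesogenic);
* $n_- / n_+ \ge 2$: overall **negative** correlation (protective);
* otherwise **none**.

Division by zero counts as infinity, so unanimous evidence always
classifies once three publications exist. The boundary ratio of exactly 2
meets the threshold. A factor with 5 positive and 12 negative studies
classifies negative, since $12/5 \ge 2$:

```{r}
classify_correlation(5, 12)
```

`apply_verdict_directions()` feeds these verdicts into the crosswalk, so
factor directions can be derived from an evidence table rather than typed
by hand.

## The crosswalk and its defaults

`load_crosswalk()` bundles the label set used in the four-area Bavarian
field validation this package is built around: 25 Google place types and
42 OSM amenity tags. Category membership and direction per label are not
part of that published material, so the bundled assignments are this
package's own operationalization: categories follow the plain meaning of
each label, and directions follow the overall literature verdicts where
one exists (fast food, convenience stores and transit obesogenic;
supermarkets, restaurants, fitness facilities, parks, education and
physician supply protective); labels without a clear verdict are left
"unclassified". Users can replace the crosswalk entirely with their own
CSV — for instance to add the wider OSM variable pool beyond the amenity
key, using trailing-asterisk wildcards such as `shop=*`.

When a POI carries labels from several categories, the category priority
decides: the default `doctor > food > sport > education > transport >
other` exists because the category-stratified analysis hinges on
unambiguous membership in the "doctor" stratum, which therefore must
dominate mixed-label records. Ties within a category resolve by crosswalk
row order, which is deterministic.

## Search areas and containment

Query regions are circular (Google-style) or quadratic (OSM-style); the
urban default is a 200 m circle diameter or square edge. Distances are
haversine on a sphere of mean radius 6 371 008.8 m. Squares are
axis-aligned geodesic boxes whose half-spans convert meters to degrees at
111 320 m/degree (east–west scaled by cos of the center latitude); at the
200 m scale this planar approximation errs by about 0.1 m, far below the
25 m positional tolerance used for duplicate merging. Boundary points
count as inside, with a ~10^-7 m floating-point guard so that points
constructed exactly on the boundary never flip outside. Irregular
polygons (e.g. a whole-municipality boundary) are not implemented; such
areas are approximated by a user-chosen circle or square.

## Validation metrics

A **hit** is a POI returned by a service for an area. Field audits mark
each hit confirmed (true positive) or rejected (false positive);
amenities discovered in the field but absent from a service are false
negatives for it. Then

$$\text{sensitivity} = 100\cdot\frac{tp}{tp+fn}, \qquad
  \text{PPV} = 100\cdot\frac{tp}{tp+fp}.$$

Three numerical decisions matter:

* **Rounding** is half-away-from-zero to 2 decimals: a PPV of
  $29/32 = 90.625\%$ reports as 90.63, matching the published tables
  (banker's rounding would print 90.62).
* **Undefined metrics** (zero denominator) are reported as `NA`, never as
  0 or 100, and serialize as the string `"NA"`.
* **Unresolved audit statuses block tallying** rather than defaulting:
  the field protocol resolves uncertain hits with online search engines
  before metrics are computed, and the code enforces that step.

One walk-through audit serves every service: each field observation lists
the sources it was missing from, so the field-truth total $tp + fn$ is
identical across sources by construction.
`cross_source_consistency_check()` verifies that invariant; on the
bundled reference counts it holds for all four areas (totals 32, 59, 207,
33 with all categories; 31, 30, 78, 25 without "doctor").

`exclude_category()` reproduces the stratified re-analysis: subtracting
one category's stratum from the overall counts and recomputing. In the
bundled reference data, excluding "doctor" raises the volunteered
service's sensitivity in the dense urban area from 19.81% to 46.15% —
physician listings dominate that area's omission errors.

## The synthetic generator

No field-audit raw data are deposited with the published tables, so the
generator is the package's test bed: it emulates the validation setting
end to end and is first-class, tested code.

A `poi_scenario()` fixes the area, per-category truth counts, each
service's per-category detection probability, each service's expected
commission count, positional jitter, and a seed. `generate_bundle()` then:

1. places truth POIs uniformly in the area (circles via the
   $r = R\sqrt{u}$ construction, squares uniformly per axis);
2. detects each truth POI independently per service with the detection
   probability, jittering detected positions with isotropic Gaussian
   noise (default sd 5 m, the scale of cross-service positional scatter;
   jittered points leaving the area are clamped radially/axially back to
   the boundary and logged);
3. adds Poisson-distributed spurious entries per service — the simplest
   memoryless count law for commission errors — placed uniformly and
   labeled with crosswalkable labels;
4. derives audits exactly from the construction: detected truth =
   confirmed hit, spurious entry = rejected hit, undetected truth = field
   observation missing from that service.

The exact audit derivation is deliberate: it isolates the metric engine
from name-matching heuristics, so pipeline tests measure the metric
engine, not a matcher. Equal seeds give byte-identical serialized
bundles, and the caller's RNG stream is restored afterwards.

`expected_metrics()` is the closed-form companion: expected sensitivity
is the truth-weighted mean detection probability
$100\sum_c p_c N_c / \sum_c N_c$, and expected PPV is $100 D/(D+C)$ with
$D$ the expected detected count and $C$ the commission mean. The test
suite runs 50 seeded bundles at $p = 0.7$, $N = 200$, $C = 30$ and checks
that mean recovered sensitivity sits within three binomial standard
errors of 70% and mean PPV within Monte-Carlo tolerance of the closed
form — sizes chosen to keep the whole suite fast while leaving the
binomial tolerance bands narrow (about 1.4 percentage points).

What the generator does *not* emulate: spatial clustering of amenities
(placement is uniform; real food outlets cluster along streets),
name-matching ambiguity between database and field, temporal database
drift, and inter-observer variability in audits. Passing synthetic tests
therefore demonstrates that the tallying and metric machinery is correct,
not that any particular real database is accurate.

```{r}
sc <- poi_scenario(
  search_area("circle", 48.137, 11.575, size_m = 100, area_id = "demo"),
  truth_counts = c(food = 40, doctor = 20, sport = 10),
  detection_prob = list(google = 0.8, osm = 0.45),
  commission_mean = list(google = 12, osm = 3),
  jitter_sd_m = 5, seed = 42)
bundle <- generate_bundle(sc)
res <- validate_bundle(bundle)
res$google
res$osm
expected_metrics(sc)
```

## Design choices in brief

* **Exports, not endpoints.** The package reads exported files
  (Places-style JSON, Overpass JSON, GeoJSON), never the network: runs
  are reproducible and offline. One provenance line is kept per record.
* **Duplicate merging** is exact-after-normalization on names
  (case-fold, trim, collapse whitespace) within a 25 m default radius;
  no fuzzy matching, so merging is deterministic and idempotent.
* **"At least three publications"** is read as three *significant*
  publications ($n_+ + n_-$), because null studies are explicitly
  excluded from the ratio; the alternative reading would change
  borderline factors.
* **Untagged OSM elements are dropped** (and counted): a record without
  any tag cannot be crosswalked into a category.
* **Coordinates are (latitude, longitude) internally**; GeoJSON I/O
  converts to and from the standard's (lon, lat) axis order.
* **Plots are basemap-free.** Maps draw markers and the area outline on
  plain coordinate axes, keeping rendering offline and byte-deterministic.

## Limitations

The bundled crosswalk covers the validated label set, not either
service's full vocabulary; real deployments should extend it. Search
areas are circles and squares only. The metric engine treats the audit
files as ground truth — the in-field judgment itself is an input, not a
computation. And all stochastic guarantees are in expectation over seeds;
any single synthetic bundle can and will deviate from the closed forms.
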