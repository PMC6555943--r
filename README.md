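# obesopoi

Validation of geocoding-service points of interest (POIs) for obesogenic
built-environment assessment.

Built-environment factors — fast-food density, sports facilities, green
space, transit — are associated with obesity, and online geocoding
services expose them as cheap, queryable POI databases. But database
entries are not ground truth: services list places that do not exist
(commission errors) and miss places that do (omission errors). obesopoi
is the pipeline for quantifying exactly that, for two service dialects: a
registry-backed place database ("google", Places-style JSON exports) and
a volunteered-geographic-information map ("osm", Overpass JSON or GeoJSON
exports).

The pipeline:

1. **Ingest** — parse exports into a common record form; merge duplicate
   listings (same identifier, or same normalized name within 25 m).
2. **Crosswalk** — map raw service labels (place types, `key=value`
   tags) to environmental factors, one of six categories (food, doctor,
   sport, education, transport, other) and an obesogenic direction.
3. **Spatial filter** — restrict records to circular or quadratic search
   areas (200 m diameter/edge urban default), haversine distances.
4. **Literature scoring** — classify each factor's overall correlation
   with obesity by the evidence-ratio rule: with at least three
   significant studies, a factor is positively correlated when
   `n_pos / n_neg >= 2`, negatively when `n_neg / n_pos >= 2` (division
   by zero counts as infinity), otherwise uncorrelated.
5. **Validation metrics** — tally field-audited hits into true/false
   positives and false negatives, and compute per area and service
   `sensitivity = 100 * tp / (tp + fn)` and
   `PPV = 100 * tp / (tp + fp)`, overall, per category, and with a
   category excluded.
6. **Synthetic data** — a seeded generator that emulates truth sets,
   per-service detection and commission errors and positional jitter,
   with a closed-form companion for expected metrics, so the whole
   pipeline runs and is testable offline.

## Worked example

Parse the bundled Places-style export, merge duplicates, categorize:

```r
library(obesopoi)
g <- read_google_places_json(
  system.file("extdata", "example_google_places.json", package = "obesopoi"))
g <- deduplicate_pois(g)
#> [obesopoi] merged 1 duplicate listing(s)
cat_g <- categorize_pois(g)
cat_g[, c("source_id", "name", "factor_name", "category", "direction")]
#> # A tibble: 4 × 5
#>   source_id name               factor_name category direction
#>   <chr>     <chr>              <chr>       <fct>    <chr>
#> 1 gp001     Backstube am Platz Bakery      food     unclassified
#> 2 gp002     Studio Fit         Gym         sport    protective
#> 3 gp003     Praxis Dr. Huber   Doctor      doctor   protective
#> 4 gp004     Trattoria Nuova    Food        food     obesogenic
```

The export held five entries; the clinic was listed twice under different
place types, so deduplication merged it into one record carrying the
union of its labels. `summarize_hits_by_category(cat_g)` then counts 2
food, 1 doctor and 1 sport hit.

The metric engine, on the bundled reference confusion counts from a
two-service, four-area field validation (area C is a dense urban area):

```r
cc <- field_validation_counts("all")
cbind(cc, compute_metrics(cc$tp, cc$fp, cc$fn))[cc$area == "C", ]
#>   area source  tp fp  fn sensitivity_pct ppv_pct
#> 5    C google 144 57  63           69.57   71.64
#> 6    C    osm  41  6 166           19.81   87.23
```

Read: in area C the registry-backed service found far more of the real
amenities (sensitivity 69.57% vs 19.81%) but a larger share of its hits
were spurious (PPV 71.64% vs 87.23%). `exclude_category(result,
"doctor")` reproduces the stratified re-analysis showing that physician
listings drive most of that gap.

A command-line front end over the same functions is at `exec/obesopoi`
(`ingest`, `categorize`, `score-lit`, `validate`, `simulate`, `report`).

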