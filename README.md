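# dietwebs

Season-wide predator–prey food-web analysis from molecular gut-content
detections.

Diagnostic multiplex PCR on the gut contents of field-captured generalist
predators (carabid and staphylinid beetles, spiders) yields one binary
prey-detection vector per individual. `dietwebs` turns those
individual-level detections, collected on a replicated field design (fields
× fertilization treatments × plots × biweekly sessions), into:

* **Interaction webs** — per sampling unit, the predator-species × prey-target
  matrix of mean detection proportions, after removal of self-detections
  (a positive for the consumer's own taxon assay);
* **Network-level specialization** — the standardized two-dimensional
  Shannon entropy
  `H2' = (H2max − H2) / (H2max − H2min)`, bound between 0 (absolute
  generalization) and 1 (absolute specialization), with the entropy minimum
  computed exactly on small grids (concave minimization over the
  transportation polytope) and by a deterministic greedy heuristic on large
  ones;
* **Standardized effect sizes** — each unit's observed H2' compared against
  a null distribution obtained by randomly recombining the individual diet
  data points (per-prey column permutation by default; cell-pool and
  within-unit variants available), expressed as a Cohen's-d-type SES
  `(observed − null mean) / null SD`, positive = more specialized than
  random;
* **Community diversity** — per-unit Shannon–Weaver diversity of predators
  and prey, with pitfall-trap aphid counts replaced by counts from collected
  barley tillers;
* **A tidy seasonal report** — one row per unit plus session × treatment
  summaries, ready for mixed-model or GAM fitting in any standard package.

A synthetic-data generator emulates the two-year study design (3 fields ×
2 treatments × 4 plots × 7/6 sessions → 168 and 144 units) with a
Dirichlet-concentration dial for seasonal specialization, so the entire
pipeline is testable without field data. It is first-class, tested code.

For whom: ecologists running molecular gut-content studies who need a
reproducible path from detection tables to specialization time series, and
anyone needing a standalone, oracle-tested H2' implementation.

## Worked example

```r
library(dietwebs)

design <- default_design()                 # the two-year barley layout
params <- synthetic_params(design = design, seed = 42)
dataset <- simulate_dataset(params)        # detections + community counts

detections <- remove_self_detections(dataset$detections,
                                     design$self_detection_map)
webs <- build_webs(detections[detections$year == "2020", ], design)
length(webs)
#> [1] 168

h2_prime(webs[["2020:F1:fertilized:P1:1"]])
#>   year field  treatment plot session       H2   H2min    H2max   H2prime valid
#> 1 2020    F1 fertilized   P1       1 2.230545 1.92236 3.844721 0.8396844  TRUE

ses <- run_ses(detections[detections$year == "2020", ], design,
               null_config(n_randomizations = 199, seed = 42))
div <- diversity_table(dataset$community)
div <- div[unit_id(div) %in% unit_id(ses), ]
res <- assemble_timeseries(ses, div, design)
res$summary[res$summary$treatment == "fertilized",
            c("session", "treatment", "ses_mean", "ses_se",
              "prey_H_mean", "n_units")]
#>   session  treatment ses_mean ses_se prey_H_mean n_units
#> 1       1 fertilized    4.425  0.479        1.42      12
#> 2       2 fertilized    3.372  0.496        1.63      12
#> 3       3 fertilized    1.923  0.453        1.60      12
#> 4       4 fertilized    0.671  0.291        1.65      12
#> 5       5 fertilized    2.311  0.417        1.62      12
#> 6       6 fertilized    3.326  0.307        1.49      12
#> 7       7 fertilized    4.369  0.350        1.53      12
```

The SES column reads directly: every session mean is positive, so observed
webs are more specialized than random recombinations of the same diet data;
and the default generator's U-shaped seasonal concentration profile shows up
as the mid-season valley (session 4) flanked by high early- and late-season
values, while prey diversity peaks mid-season. These are the synthetic
counterparts of the seasonal patterns the pipeline is designed to expose in
field data.

Real data enter through CSVs validated against the design
(`read_detections()`, `read_community()`, `read_config()`); a thin
command-line wrapper with `validate` / `simulate` / `ses` subcommands ships
in `inst/scripts/dietwebs-cli.R`.

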