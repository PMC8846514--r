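# geosample

Audits of **where publicly deposited human-microbiome samples come from**.

Public sequence repositories (SRA, ENA, DDBJ) describe each deposited sample
with a BioSample metadata record carrying free-text attributes such as
`geo_loc_name` and `host`. `geosample` turns a dump of such records into
per-country and per-region representation statistics, so that repository
curators, funders, and microbiome researchers can quantify how strongly the
sampled populations are skewed toward particular countries relative to where
people actually live.

The pipeline has five composable stages:

1. **simulate** — `cohort_config()` / `generate_cohort()`: seeded synthetic
   BioSample-style cohorts with exact ground truth, so every later stage is
   testable without touching a live repository.
2. **ingest** — `parse_biosample()`, `link_runs()`, `filter_sequenced()`,
   `filter_release_date()`: parse the BioSample XML dialect and RunInfo-style
   run tables, drop records with no sequencing data or no usable release
   date.
3. **scope** — `scope_records()`: keep human-microbiome samples, i.e. records
   filed under a human-labeled metagenome taxonomy category (e.g. "human gut
   metagenome", taxid 408170) plus records in large *generic* categories
   ("gut metagenome") whose `host_taxid`/`host` value indicates a human.
4. **geolocate** — `attribute_geography()`: resolve free-text locations
   ("USA: Minnesota", "Viet Nam", "Côte d'Ivoire") to ISO-3166 countries,
   UN SDG regions, and least-developed-country status via a packaged
   gazetteer and UN 2020 population table.
5. **stats** — `tabulate_samples()`, `shares()`,
   `representation_proportion()`, `raw_index()`, `scale_indices()`,
   `display_transform()`, `time_series()`.

`run_audit()` chains all stages and writes report CSVs plus a JSON manifest
with per-stage record counts and reference-table checksums.

## The statistics

For a unit *c* (country or region) with `s_c` located samples out of `S`
located samples total, and population `p_c` out of world population `P`:

- **representation proportion**
  `R_c = (s_c / S) / (p_c / P)` — 1 means exactly proportional
  representation; `R_c = 4` means four times more samples than the unit's
  population share would predict.
- **signed raw index** — `R_c` when sample share ≥ population share, and the
  negative reciprocal `−1/R_c` otherwise, so an underrepresented country's
  magnitude is the factor its sample count would have to grow by to reach
  proportionality. Countries with zero samples get a sentinel (`NA`).
- **scaled index** — after excluding countries with 50 or fewer samples,
  positive scores are min-max scaled onto (0, 100] and negative scores
  independently onto [−100, 0); `display_transform()` applies the
  sign-preserving `sign(x)·log10(1 + |x|)` used for choropleth coloring.

## Worked example

A fully synthetic audit, end to end (no network access needed):

```r
library(geosample)

coh <- generate_cohort(cohort_config(20000, seed = 7))
r   <- filter_release_date(filter_sequenced(link_runs(coh$records, coh$runs)))
sc  <- scope_records(r)
geo <- attribute_geography(sc$records)

counts <- tabulate_samples(geo$records, "region")
world  <- load_world_table()
tab <- representation_table(tibble::tibble(
  unit = counts$unit, samples = counts$samples,
  population_thousands = vapply(counts$unit, function(reg) {
    if (reg == "Unknown") NA_real_
    else sum(world$population_thousands[world$sdg_region == reg])
  }, double(1))))
```

which prints (shares as percentages, 1 dp; proportions at 2 dp):

```
                             unit samples share_known pop_share repr_proportion
      Europe and Northern America    9027        68.5      14.3            4.78
                          Unknown    2245          NA        NA              NA
    Eastern and Southeastern Asia    1817        13.8      30.2            0.46
               Sub-Saharan Africa     649         4.9      14.1            0.35
  Latin America and the Caribbean     648         4.9       8.4            0.59
            Australia/New Zealand     453         3.4       0.4            8.82
        Central and Southern Asia     420         3.2      25.9            0.12
 Northern Africa and Western Asia     158         1.2       6.8            0.18
```

Reading the first row: 9,027 of the 13,172 located samples (68.5%) come from
Europe and Northern America, a region holding 14.3% of the world population,
so the region is overrepresented by a factor of 4.78. The `Unknown` row
counts scoped samples whose geography was absent, an explicit null token, or
an unrecognized string; it participates in overall shares but not in
population-normalised statistics. These numbers reflect the generator's
default mixture, which emulates the composition of the public
human-microbiome sample pool (about 86% of samples with known location,
heavily concentrated in North America and Europe).

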