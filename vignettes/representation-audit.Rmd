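---
title: "Auditing geographic representation in public microbiome metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing geographic representation in public microbiome metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geosample)
```

## The problem

Sequencing studies of the human microbiome deposit their raw data in a
handful of large public repositories, and each deposited sample is described
by a BioSample metadata record: an accession, an NCBI taxonomy ID naming the
metagenome category the sample was filed under, a release date, and a bag of
free-text attribute key/value pairs. Nothing in that system enforces where
samples come from, and the sampled populations are known to be heavily
concentrated in a few wealthy countries. `geosample` makes that skew
measurable: it scopes a metadata dump to human-microbiome samples,
attributes each sample to a country and UN SDG region, and computes
population-normalised representation statistics.

Everything operates on metadata only. No sequence data is read, and no
network access is ever required: the live-repository harvest is out of scope
and all reference inputs ship with the package as plain text.

## Pipeline model and assumptions

**Ingest.** `parse_biosample()` reads the `BioSampleSet/BioSample` XML
dialect (or an equivalent JSON dump). Attribute names are lower-cased,
trimmed, harmonized through a shipped alias table (e.g. "geographic
location" → `geo_loc_name`), and deduplicated first-occurrence-wins —
real submissions do repeat attribute names, and the first value is the one
submitters typically intend. A record without a taxonomy ID is kept with a
sentinel (0) so the parse count is conserved; taxonomy scoping removes it
later. Two filters follow: a sample with zero linked sequencing runs has no
public data behind it and is dropped (`filter_sequenced()`), and only
samples released strictly before the cutoff (default 2021-01-01) are kept
(`filter_release_date()`), which freezes the audit window and avoids
counting categories harvested at different times against different
horizons. "Strictly before" is a deliberate reading of a pre-2021 window:
2020-12-31 is in, 2021-01-01 is out. Records with missing or unparseable
dates are removed and counted separately, never silently.

**Scope.** A body-site taxonomy table maps metagenome categories to 19
body-site labels. Each body site has a *human-labeled* category ("human gut
metagenome", taxid 408170) and possibly a *generic* one ("gut metagenome")
that can hold samples from any host species. Human-labeled records are in
scope by definition. Generic categories are only screened when they hold at
least `generic_threshold` (default 1000, inclusive) records — smaller ones
contribute little and are dominated by non-human hosts. Within an admitted
generic category, a record is kept when its *putative host* — the
`host_taxid` attribute, falling back to `host` when that is blank or a null
token — indicates a human. The original curation of such host strings was
manual; this package replaces it with an editable lexicon
(`inst/extdata/host_lexicon.yml`): a value is human when it parses to a
taxid in `human_taxids` (9606 and subspecies), or contains a positive token
("human", "homo sapiens", "patient", "crew member", "infant", "adult",
"child", "volunteer", "subject") *and* no negative override naming another
species — so "humanized mouse" and "human gut microbiota transplanted into
mice" are vetoed. The lexicon aims for the same behavior class as manual
curation, not string-for-string identity with any particular historical
curation, and every distinct host value's verdict is logged in the scoping
report for audit. The body-site-less "human metagenome" category is modeled
as its own body-site label. The packaged body-site table anchors the
well-established taxids and is a reconstruction for the rarer categories;
it is a configuration input meant to be checked against the NCBI Taxonomy
Browser before a live harvest.

**Geolocate.** The geographic attribute is read in priority order
(`geo_loc_name`, then the INSDC long forms), split on the first colon per
the "Country: subdivision" convention, and looked up exactly (after case,
whitespace, and diacritic folding) in a gazetteer built from the packaged
world table plus an alias list. Design choices where the convention is
genuinely open:

- A small vocabulary of null tokens ("missing", "not collected", "not
  applicable", "restricted access", "unknown", and the empty string) counts
  as absent geography; the same vocabulary is used by the attribute-usage
  statistics (configurable, with a `count_null_as_present` policy flag).
- Territories that the UN population framework lists separately (Hong Kong,
  Puerto Rico, Greenland, ...) stay distinct units rather than being folded
  into a parent country.
- Ambiguous historical names ("Korea") are left unrecognized rather than
  guessed; unrecognized and null values both end up in the Unknown row, so
  the four resolution statuses (resolved / null token / unrecognized /
  absent) always partition the cohort.
- Antarctica resolves to a country code (ATA) but belongs to no SDG region,
  so its samples fall under Unknown in all region-level statistics. It is
  not a world-table row (the table requires positive populations); the
  resolver special-cases it.

**Statistics.** For unit $c$ with $s_c$ located samples of $S$ total located
and population $p_c$ of world population $P$, the representation proportion
is $R_c = (s_c/S)\,/\,(p_c/P)$. The signed raw index is $R_c$ on the
positive branch (sample share $\ge$ population share) and $-1/R_c$ on the
negative branch; exact proportionality is assigned to the positive branch
with value 1 (a tie-break; only strict over/under-representation is
otherwise distinguished). Countries with zero samples are a sentinel class,
mapped separately on choropleths.

Two denominator conventions matter and are both supported: region-level
tables use the located-*by-region* total (Antarctica counts as Unknown),
while country-level tables use the located-by-country total; the two Unknown
counts therefore differ slightly, as they do in published audits of this
kind.

## Index scaling and display

`scale_indices()` first excludes units with `min_samples` (default 50,
*inclusive* — "50 or fewer") samples, whose shares are too noisy to rank.
Remaining positive scores are scaled by $x \mapsto 100x/\max(x)$ and
negative scores independently by $x \mapsto -100|x|/\max|x|$: the simplest
maps onto $(0, 100]$ and $[-100, 0)$ that keep 0 anchored at exact
proportionality and preserve sign and within-sign ordering (a min-max map
with a shifted minimum would move the proportionality anchor). For display,
`display_transform()` applies $\mathrm{sign}(x)\log_{10}(1+|x|)$; the $+1$
offset keeps 0 finite and fixed. The transform exists purely to spread
middling scores in a color scale, so any monotone sign-preserving variant
would serve; this one is documented so the mapping is reproducible.

**Rounding.** All printed-style percentages and proportions round half *away
from zero* at the presentation layer (`round_half_up()`), matching how
published tables are typically typeset; internal arithmetic is always full
precision.

## The synthetic-cohort generator

`generate_cohort()` draws records field-by-field in a fixed order from one
seeded generator, so a fixed seed reproduces the cohort byte-for-byte. Its
defaults emulate the composition of the public human-microbiome pool as of
a mid-2021 snapshot:

- `country_weights`: proportional to the published top-20 per-country
  sample counts, with the residual "rest of world" mass split evenly across
  ten countries chosen from the remaining regions (Brazil, South Africa,
  Mexico, Russia, South Korea, Thailand, Pakistan, Nigeria, Peru,
  Tanzania), so every region is populated.
- `body_site_weights`: proportional to the published per-body-site counts
  (gut ≈ half of all samples).
- `p_geo_missing = 0.14`: the located share of real cohorts is about 86%.
- `p_generic_category = 0.29`: the approximate fraction of the harvest pool
  that sits in generic categories before host screening.
- `p_human_host_given_generic = 0.173`: the fraction of screened
  generic-category samples whose host value indicates a human.
- `p_geo_messy = 0.2`: known countries rendered as a bare ISO code, an
  upper-cased name, or a "Country: subdivision" string, exercising the
  gazetteer.
- `p_no_runs = 0.02`: a small class of records without sequencing data, so
  the run filter has work to do.
- `year_weights`: geometric growth at ratio 1.4 over 2010–2020, putting
  about 29% of samples in 2020, close to the observed growth curve.

Ground truth (per-country, per-body-site, per-year marginals and per-stage
survivor counts) is computed directly from the latent draws, never through
the pipeline under test. What the generator does *not* emulate: correlated
missingness (in real data, missing geography clusters by study), longitudinal
resampling of the same host, study-level structure (all draws are
per-record), misfiled samples (human data filed under *Homo sapiens* rather
than a metagenome category), and free-text noise beyond the three messy-geo
styles. Passing tests therefore demonstrate that the pipeline's *rules* are
implemented correctly and recover known compositions; they do not
demonstrate robustness to every pathology of real submissions.

## Statistical formulation of the property tests

The recovery tests treat each country's located count as
$\mathrm{Binomial}(n, p_c)$. For the default 30-country mixture at
$n = 10{,}000$ every expected count is large and a per-country
$3\sigma$ normal bound is used directly. For the population-proportional
check over the full ~205-country world table at $n = 50{,}000$, most
expected counts are tiny and a per-country normal bound is both
ill-calibrated and multiplicity-broken (some country lands outside $3\sigma$
on a large fraction of seeds purely by chance). That check therefore uses
exact binomial intervals at the two-sided $\Phi(\pm 3)$ level per country
and bounds the *number* of interval exceedances by what nominal coverage
predicts (at most 3 of ~205), plus a direct check that every well-sampled
country's representation proportion lies inside the interval image around
1. This keeps the $3\sigma$ substance while being honest about testing 205
hypotheses at once.

Problem sizes in the shipped suite — 10,000 records for frequency recovery,
50,000 for proportional-representation recovery, 1,000 for brute-force
oracle equality, 200 for serialization round-trips, 2,000 for the
end-to-end audit — were chosen as the smallest sizes at which the binomial
bounds above are informative, and are stated here so the suite's evidence
can be judged at face value.

## Degenerate inputs and edge rules

- Empty `BioSampleSet` parses to an empty record set; empty tabulations
  return empty tables; `time_series()` on zero records returns an empty
  grid.
- Duplicate accessions across inputs are an error (never silently merged).
- `shares()` refuses zero totals; `representation_proportion()` refuses
  zero population or zero samples (callers use the sentinel class).
- If every unit is excluded from index scaling, the result carries only
  exclusion notes plus a warning.
- Reference tables are validated at load and again at audit startup
  (`validate_references()`): unique codes, positive populations, exactly 8
  SDG regions, aliases mapping to exactly one code, unique body-site
  taxids including the gut anchor row, disjoint lexicon token sets, and
  gazetteer totality (every canonical name resolves to its own code).

## Known limitations

- Country-level resolution only; coordinates and sub-national geography are
  parsed but not geocoded.
- The host lexicon is substring-based; a sufficiently adversarial host
  string can evade it. Every decision is logged precisely so that a human
  can audit the screen.
- The world table is a curated snapshot of UN 2020 population estimates
  (~200 units) bundled for offline use; regional sums agree with the UN
  regional aggregates to within a few tenths of a percent, which is ample
  for representation ratios but not for demographic work.
- Reproducing a published audit's absolute sample counts requires the
  original repository snapshot; this package reproduces the *arithmetic*
  exactly (see `scripts/acceptance.R`) and the pipeline behavior on
  synthetic cohorts with known truth.
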