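biosample_xml <- function(body) {
  f <- withr::local_tempfile(fileext = ".xml", .local_envir = parent.frame())
  writeLines(paste0("<?xml version=\"1.0\"?>\n<BioSampleSet>", body,
                    "</BioSampleSet>"), f)
  f
}

test_that("parser emits one record per BioSample element", {
  f <- biosample_xml('
    <BioSample accession="SAMN1" publication_date="2019-05-02">
      <Description><Organism taxonomy_id="408170"/></Description>
      <Attributes><Attribute attribute_name="host">human</Attribute></Attributes>
    </BioSample>
    <BioSample accession="SAMN2"><Description><Organism taxonomy_id="749906"/></Description><Attributes/></BioSample>
    <BioSample accession="SAMN3"><Description><Organism taxonomy_id="408170"/></Description><Attributes/></BioSample>')
  recs <- parse_biosample(f)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$taxonomy_id, c(408170L, 749906L, 408170L))
  expect_equal(recs$release_date[1], as.Date("2019-05-02"))
  expect_true(is.na(recs$release_date[2]))
})

test_that("duplicate attribute keeps the first value with a warning", {
  f <- biosample_xml('
    <BioSample accession="SAMN1">
      <Description><Organism taxonomy_id="408170"/></Description>
      <Attributes>
        <Attribute attribute_name="host">human</Attribute>
        <Attribute attribute_name="HOST">mouse</Attribute>
      </Attributes>
    </BioSample>')
  expect_warning(recs <- parse_biosample(f), "host")
  expect_identical(recs$attributes[[1]][["host"]], "human")
})

test_that("attribute names are lower-cased and alias-harmonized", {
  f <- biosample_xml('
    <BioSample accession="SAMN1">
      <Description><Organism taxonomy_id="408170"/></Description>
      <Attributes>
        <Attribute attribute_name="Geographic location (country and/or sea)">Chile</Attribute>
      </Attributes>
    </BioSample>')
  recs <- parse_biosample(f)
  expect_identical(recs$attributes[[1]][["geo_loc_name"]], "Chile")
})

test_that("empty BioSampleSet parses to an empty record set without error", {
  f <- biosample_xml("")
  recs <- parse_biosample(f)
  expect_equal(nrow(recs), 0)
})

test_that("duplicate accessions and malformed XML are errors", {
  f <- biosample_xml('
    <BioSample accession="SAMN1"><Description><Organism taxonomy_id="408170"/></Description><Attributes/></BioSample>
    <BioSample accession="SAMN1"><Description><Organism taxonomy_id="408170"/></Description><Attributes/></BioSample>')
  expect_error(parse_biosample(f), "SAMN1")
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<BioSampleSet><BioSample>", bad)
  expect_error(parse_biosample(bad), class = "geosample_parse_error")
})

test_that("records without a taxonomy ID get sentinel 0 and a warning", {
  f <- biosample_xml('<BioSample accession="SAMN1"><Attributes/></BioSample>')
  expect_warning(recs <- parse_biosample(f), "taxonomy ID")
  expect_equal(recs$taxonomy_id, 0L)
})

test_that("run linkage joins, deduplicates, and warns on orphans", {
  recs <- make_records(c("SAMN1", "SAMN2"))
  runinfo <- tibble::tibble(
    Run = c("SRR1", "SRR2", "SRR3", "SRR3", "SRR9"),
    BioSample = c("SAMN1", "SAMN1", "SAMN1", "SAMN1", "SAMNX"),
    LibraryStrategy = "AMPLICON")
  expect_warning(linked <- link_runs(recs, runinfo), "SAMNX")
  expect_equal(nrow(linked$runs[[1]]), 3)  # SRR3 deduplicated
  expect_equal(nrow(linked$runs[[2]]), 0)
})

test_that("filter_sequenced keeps exactly the records with runs and is idempotent", {
  recs <- make_records(sprintf("SAMN%d", 1:10))
  runinfo <- tibble::tibble(Run = sprintf("SRR%d", 1:8),
                            BioSample = sprintf("SAMN%d", 1:8),
                            LibraryStrategy = "WGS")
  linked <- suppressWarnings(link_runs(recs, runinfo))
  kept <- suppressMessages(filter_sequenced(linked))
  expect_equal(nrow(kept), 8)
  expect_equal(attr(kept, "n_removed"), 2)
  again <- filter_sequenced(kept)
  expect_equal(nrow(again), 8)
  expect_equal(attr(again, "n_removed"), 0)
  # all removed
  none <- suppressMessages(filter_sequenced(
    link_runs(make_records("SAMN99"), runinfo[0, ])))
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "n_removed"), 1)
})

test_that("date filter is strict at the cutoff and drops missing dates", {
  recs <- make_records(c("A", "B", "C"),
                       release_date = as.Date(c("2020-12-31", "2021-01-01",
                                                NA)))
  kept <- suppressMessages(filter_release_date(recs))
  expect_equal(kept$accession, "A")
  expect_equal(attr(kept, "n_removed_undated"), 1)
  expect_equal(attr(kept, "n_removed_late"), 1)
  expect_equal(nrow(filter_release_date(kept)), 1)  # idempotent
})

test_that("date filter matches generator truth on a cohort spanning the cutoff", {
  yw <- c("2019" = 0.3, "2020" = 0.3, "2021" = 0.2, "2022" = 0.2)
  coh <- generate_cohort(cohort_config(1500, year_weights = yw,
                                       p_no_runs = 0, seed = 8))
  kept <- suppressMessages(filter_release_date(coh$records))
  truth_pre <- sum(coh$truth$by_year[c("2019", "2020")])
  expect_equal(nrow(kept), truth_pre)
})

test_that("pipeline conservation: parsed = retained + removed at each filter", {
  coh <- generate_cohort(cohort_config(1200, seed = 31))
  linked <- link_runs(coh$records, coh$runs)
  seq_kept <- suppressMessages(filter_sequenced(linked))
  dated <- suppressMessages(filter_release_date(seq_kept))
  expect_equal(nrow(coh$records),
               nrow(dated) + attr(seq_kept, "n_removed") +
                 attr(dated, "n_removed_undated") +
                 attr(dated, "n_removed_late"))
  expect_equal(nrow(seq_kept), coh$truth$n_with_runs)
  expect_equal(nrow(dated), coh$truth$n_dated_pre_cutoff)
})

test_that("attribute usage counts samples carrying each attribute", {
  recs <- make_records(c("A", "B", "C"), attributes = list(
    c(host = "human"), c(host = "mouse", geo_loc_name = "missing"),
    c(host = "human")))
  usage <- attribute_usage(recs)
  expect_equal(usage$samples[usage$attribute == "host"], 3L)
  # null-token geography does not count as present by default...
  expect_false("geo_loc_name" %in% usage$attribute)
  # ...unless the policy flag says so
  usage2 <- attribute_usage(recs, count_null_as_present = TRUE)
  expect_equal(usage2$samples[usage2$attribute == "geo_loc_name"], 1L)
  expect_false("host_disease" %in% usage$attribute)
})

test_that("attribute usage matches generator truth", {
  coh <- generate_cohort(cohort_config(2000, seed = 14))
  usage <- attribute_usage(coh$records)
  truth <- coh$truth$attribute_usage
  for (i in seq_len(nrow(truth))) {
    expect_equal(usage$samples[usage$attribute == truth$attribute[i]],
                 truth$samples[i],
                 label = truth$attribute[i])
  }
})
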