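test_that("TSV reader parses, normalizes, and handles degenerate rows", {
  path <- write_tsv_fixture(c(
    "study_id\tstart_date\tcountries\tconditions",
    "NCT001\t2009-03\tUnited States|Canada\tDiabetes",
    "NCT002\t2005\tFrance|France\tAsthma|asthma",
    "NCT003\tMarch 2010\tKorea, Republic of|Viet Nam\t",
    "NCT004\t\t\tDiabetes",
    "NCT005\tnot a date\tBrazil\tHIV"))
  reg <- suppressMessages(read_registry(path, quiet = TRUE))
  expect_s3_class(reg, "trial_registry")
  expect_equal(nrow(reg), 5L)
  expect_equal(reg$start_year, c(2009L, 2005L, 2010L, NA, NA))
  expect_setequal(reg$countries[[1]], c("United States", "Canada"))
  expect_equal(reg$countries[[2]], "France")          # set semantics
  expect_setequal(reg$countries[[3]], c("South Korea", "Vietnam"))
  expect_equal(reg$countries[[4]], character(0))      # unlocated, kept
  expect_equal(reg$conditions[[1]], "diabetes")       # case-folded
  expect_equal(reg$conditions[[2]], "asthma")         # deduplicated
})

test_that("empty TSV (header only) yields an empty registry", {
  path <- write_tsv_fixture("study_id\tstart_date\tcountries\tconditions")
  reg <- read_registry(path, quiet = TRUE)
  expect_equal(nrow(reg), 0L)
})

test_that("missing file is fatal; missing ids skip in lenient, stop in strict", {
  expect_error(read_registry(tempfile(), quiet = TRUE), "not found")
  path <- write_tsv_fixture(c(
    "study_id\tstart_date\tcountries\tconditions",
    "\t2009\tFrance\tx",
    "NCT001\t2009\tSpain\tx"))
  expect_warning(reg <- read_registry(path, quiet = TRUE), "without a study id")
  expect_equal(reg$study_id, "NCT001")
  expect_error(suppressWarnings(read_registry(path, strict = TRUE,
                                              quiet = TRUE)),
               "without a study id")
})

test_that("ClinicalTrials.gov XML subset is read", {
  path <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    "<studies>",
    "<clinical_study>",
    "  <id_info><nct_id>NCT100</nct_id></id_info>",
    "  <start_date>June 2008</start_date>",
    "  <condition>Diabetes Mellitus</condition>",
    "  <location_countries>",
    "    <country>United States</country>",
    "    <country>Russian Federation</country>",
    "  </location_countries>",
    "  <other>ignored</other>",
    "</clinical_study>",
    "<clinical_study>",
    "  <id_info><nct_id>NCT101</nct_id></id_info>",
    "  <start_date>2011-02-01</start_date>",
    "  <location_countries><country>Japan</country></location_countries>",
    "</clinical_study>",
    "</studies>"), path)
  reg <- read_registry(path, format = "ctgov_xml", quiet = TRUE)
  expect_equal(reg$study_id, c("NCT100", "NCT101"))
  expect_equal(reg$start_year, c(2008L, 2011L))
  expect_setequal(reg$countries[[1]], c("United States", "Russia"))
  expect_equal(reg$conditions[[1]], "diabetes mellitus")
  expect_equal(reg$conditions[[2]], character(0))
})

test_that("start-year dialects parse and implausible years are dropped", {
  expect_equal(trialnet:::.parse_start_year(
    c("2009", "2009-03", "2009-03-15", "March 2009", "March 3, 2009",
      "garbage", "")),
    c(2009L, 2009L, 2009L, 2009L, 2009L, NA, NA))
  expect_warning(
    reg <- trial_registry("S1", 1850L, list("France"), list("x")),
    "outside")
  expect_true(is.na(reg$start_year))
})

test_that("deduplication merges by union and earliest year", {
  reg <- trial_registry(
    c("NCT001", "NCT001", "NCT002"),
    c(2010L, 2008L, NA),
    countries = list("United States", "Canada", "France"),
    conditions = list("diabetes", "asthma", character(0)))
  expect_warning(deduplicate_studies(reg), "conflicting")
  out <- suppressWarnings(deduplicate_studies(reg))
  expect_equal(nrow(out), 2L)
  expect_equal(out$study_id, c("NCT001", "NCT002"))    # sorted
  expect_setequal(out$countries[[1]], c("United States", "Canada"))
  expect_setequal(out$conditions[[1]], c("diabetes", "asthma"))
  expect_equal(out$start_year[1], 2008L)               # earliest kept
})

test_that("deduplication matches a brute-force grouping oracle and is idempotent", {
  set.seed(401)
  ids <- sample(sprintf("ID%d", 1:4), 10L, replace = TRUE)
  reg <- trial_registry(
    ids, sample(c(2000:2005, NA), 10L, replace = TRUE),
    countries = lapply(1:10, function(i) sample(LETTERS[1:6],
                                                sample(1:3, 1))),
    conditions = rep(list("x"), 10L))
  out <- suppressWarnings(deduplicate_studies(reg))
  expect_equal(nrow(out), length(unique(ids)))
  for (id in unique(ids)) {
    expect_setequal(out$countries[[which(out$study_id == id)]],
                    unique(unlist(reg$countries[reg$study_id == id])))
  }
  again <- suppressWarnings(deduplicate_studies(out))
  expect_equal(again, out)
  # all-unique input is identity up to ordering
  uniq <- trial_registry(c("B", "A"), c(2001L, 2000L),
                         list("France", "Spain"), list("x", "y"))
  expect_equal(deduplicate_studies(uniq)$study_id, c("A", "B"))
})

test_that("scope classification depends only on country-set cardinality", {
  reg <- trial_registry(
    c("S1", "S2", "S3"), rep(2000L, 3),
    countries = list(c("United States", "Canada", "Mexico"), "France",
                     character(0)))
  expect_equal(classify_scope(reg),
               c("multinational", "single_nation", "unlocated"))
  # property: random sets, label determined by cardinality alone
  set.seed(402)
  for (i in 1:20) {
    k <- sample(0:5, 1)
    reg <- trial_registry("S", 2000L,
                          list(sample(LETTERS, k)), list(character(0)))
    expect_equal(classify_scope(reg),
                 c("unlocated", "single_nation",
                   "multinational")[min(k, 2L) + 1L])
  }
  # partition invariant: the three scope counts sum to the study count
  set.seed(403)
  reg <- random_registry(40)
  dd <- deduplicate_studies(reg)
  expect_equal(sum(table(classify_scope(dd))), nrow(dd))
})

test_that("country normalization resolves aliases and passes unknowns through", {
  expect_equal(normalize_country("Korea, Republic of"), "South Korea")
  expect_equal(normalize_country("United States"), "United States")
  expect_equal(normalize_country("  united   kingdom "), "United Kingdom")
  expect_warning(out <- normalize_country("Untied States"), "Untied States")
  expect_equal(out, "Untied States")
  expect_error(normalize_country(""), "empty")
})

test_that("region assignment covers the six regions and handles strict mode", {
  expect_equal(assign_region("Brazil"), "South America")
  expect_equal(assign_region("Solomon Islands"), "Oceania")
  expect_equal(assign_region(c("Russia", "Turkey", "Georgia", "Egypt",
                               "Mexico")),
               c("Europe", "Asia", "Asia", "Africa", "North America"))
  expect_error(assign_region("Atlantis", strict = TRUE), "Atlantis")
  expect_warning(r <- assign_region("Atlantis"), "Unassigned")
  expect_equal(r, "Unassigned")
  rm <- default_region_map()
  expect_setequal(unique(rm), trialnet_regions())
  expect_length(trialnet_regions(), 6L)
})

test_that("region map and alias table readers validate their input", {
  bad <- write_tsv_fixture(c("country\tregion", "Narnia\tMiddle Earth"))
  expect_error(read_region_map(bad), "unknown region")
  dup <- write_tsv_fixture(c("country\tregion", "France\tEurope",
                             "France\tAsia"))
  expect_error(read_region_map(dup), "duplicate")
  ok <- write_tsv_fixture(c("alias\tcanonical", "Gaul\tFrance"))
  expect_equal(read_alias_table(ok), c(Gaul = "France"))
})
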