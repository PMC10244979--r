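test_that("demography loads, resolves mother links, and tolerates extras", {
  path <- write_toy_demography()
  demog <- load_demography(path)
  expect_equal(nrow(demog), 11)
  expect_equal(demog$mother_id[demog$id == "C1"], "MA")
  expect_true(is.na(demog$death_year[demog$id == "MA"]))

  # documented dialect tolerance: unknown column ignored with a warning
  raw <- read.csv(path, colClasses = "character")
  raw$field_notes <- "x"
  path2 <- tempfile(fileext = ".csv")
  write.csv(raw, path2, row.names = FALSE, quote = FALSE)
  expect_warning(demog2 <- load_demography(path2), "unrecognized")
  expect_equal(demog2, demog)
})

test_that("demography invariant violations are rejected with named culprits", {
  df <- toy_demography()
  df$death_year[df$id == "C1"] <- 1980   # precedes birth 1992
  expect_error(validate_demography(df), "C1")

  df <- toy_demography()
  df$mother_id[df$id == "E2"] <- "NOPE"
  expect_error(validate_demography(df), "NOPE")

  df <- toy_demography()
  df$mother_id[df$id == "D1"] <- "C2"    # male mother
  expect_error(validate_demography(df), "non-female")

  df <- toy_demography()
  df$birth_year[df$id == "MA"] <- 1993   # younger than her calf C1
  expect_error(validate_demography(df), "strictly before")

  df <- rbind(toy_demography(), toy_demography()[1, ])
  expect_error(validate_demography(df), "duplicate")
})

test_that("encounters load with set semantics and strict parsing", {
  demog <- toy_demography()
  enc <- make_encounters(c("2006-05-01", "2006-05-02"),
                         list(c("GM", "MA"), c("MB", "D1", "C2")))
  path <- write_enc_csv(enc)
  got <- load_encounters(path, demog)
  expect_equal(nrow(got), 2)
  expect_setequal(got$identified[[2]], c("MB", "D1", "C2"))
  expect_s3_class(got$date, "Date")

  # duplicate id within one encounter deduplicates with a warning
  enc_dup <- make_encounters("2006-05-01", list(c("GM", "MA", "GM")))
  expect_warning(got2 <- validate_encounters(enc_dup), "deduplicating")
  expect_equal(sort(got2$identified[[1]]), c("GM", "MA"))

  # UNRECORDED full-encounter flag is a valid value for early rows
  enc_early <- make_encounters("1999-07-01", list(c("GM", "MA")),
                               full_encounter = "UNRECORDED",
                               min_estimated_count = 2L)
  expect_silent(validate_encounters(enc_early, demog))

  # unparseable date names the row; duplicate encounter ids rejected
  bad <- data.frame(encounter_id = "E1", date = "01/02/2003",
                    source_org = "DFO", full_encounter = "TRUE",
                    min_estimated_count = "", identified_ids = "GM")
  pbad <- tempfile(fileext = ".csv")
  write.csv(bad, pbad, row.names = FALSE, quote = FALSE)
  expect_error(load_encounters(pbad), "row")

  enc3 <- make_encounters(c("2006-05-01", "2006-05-02"),
                          list("GM", "MA"))
  enc3$encounter_id <- c("E1", "E1")
  expect_error(validate_encounters(enc3), "duplicate encounter_id")

  enc4 <- make_encounters("2006-05-01", list(c("GM", "ZZ")))
  expect_error(validate_encounters(enc4, demog), "ZZ")
})

test_that("encounter inclusion filter matches the rule table exactly", {
  mk <- function(date, org, full, min_ct, n_ids) {
    make_encounters(date, list(toy_demography()$id[seq_len(n_ids)]),
                    source_org = org, full_encounter = full,
                    min_estimated_count = min_ct)
  }
  cases <- list(
    # date, org, full, min_ct, n_ids, kept
    list("1998-06-01", "DFO", "UNRECORDED", 5L, 6L, TRUE),   # min <= ids
    list("1998-06-01", "DFO", "UNRECORDED", 6L, 6L, TRUE),   # equality kept
    list("1998-06-01", "DFO", "UNRECORDED", 7L, 6L, FALSE),  # min > ids
    list("1998-06-01", "CWR", "UNRECORDED", 2L, 4L, TRUE),   # CWR same rule
    list("1998-06-01", "OTHER", "UNRECORDED", 2L, 4L, FALSE),# org excluded
    list("1998-06-01", "DFO", "UNRECORDED", NA, 4L, FALSE),  # missing min
    list("1998-06-01", "DFO", "TRUE", NA, 4L, FALSE),        # flag irrelevant early
    list("2010-06-01", "OTHER", "TRUE", NA, 2L, TRUE),       # modern: flag only
    list("2010-06-01", "DFO", "FALSE", 1L, 3L, FALSE),
    list("2010-06-01", "DFO", "UNRECORDED", 1L, 3L, FALSE),
    list("2005-01-01", "DFO", "TRUE", NA, 2L, TRUE),         # cutoff year itself
    list("2004-12-31", "DFO", "UNRECORDED", 1L, 2L, TRUE)
  )
  enc <- do.call(rbind, lapply(cases, function(cs)
    mk(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]])))
  enc$encounter_id <- sprintf("E%03d", seq_len(nrow(enc)))
  kept <- filter_encounters(enc)
  expect_equal(enc$encounter_id %in% kept$encounter_id,
               vapply(cases, `[[`, NA, 6))
  # idempotence and order preservation
  expect_identical(filter_encounters(kept), kept)
  expect_false(is.unsorted(match(kept$encounter_id, enc$encounter_id)))
})

test_that("maternal kinship enumerates the pedigree correctly", {
  demog <- toy_demography()
  expect_equal(classify_dyad_kinship(demog, "MA", "C1"), "MOTHER_OFFSPRING")
  expect_equal(classify_dyad_kinship(demog, "C1", "MA"), "MOTHER_OFFSPRING")
  expect_equal(classify_dyad_kinship(demog, "GM", "C1"),
               "GRANDMOTHER_GRANDOFFSPRING")
  expect_equal(classify_dyad_kinship(demog, "C1", "C2"), "MATERNAL_SIBLING")
  expect_equal(classify_dyad_kinship(demog, "MA", "MB"), "MATERNAL_SIBLING")
  # disjoint two-generation lineages
  expect_equal(classify_dyad_kinship(demog, "C1", "E1"), "KNOWN_UNRELATED")
  # missing maternal links block a known-unrelated call
  expect_equal(classify_dyad_kinship(demog, "MA", "E2"), "UNKNOWN")
  expect_equal(classify_dyad_kinship(demog, "GM", "GX"), "UNKNOWN")
  # aunt-type overlap short of the named categories stays UNKNOWN
  expect_equal(classify_dyad_kinship(demog, "MB", "C1"), "UNKNOWN")
  expect_error(classify_dyad_kinship(demog, "MA", "MA"), "distinct")
  expect_error(classify_dyad_kinship(demog, "MA", "NOPE"), "NOPE")
})

test_that("kinship is symmetric and partitions all pairs", {
  demog <- toy_demography()
  tab <- dyad_kinship_table(demog)
  n <- nrow(demog)
  expect_equal(nrow(tab), n * (n - 1) / 2)
  expect_true(all(table(tab$dyad_type) >= 0))
  flipped <- classify_dyad_kinship(demog, tab$j, tab$i)
  expect_equal(flipped, tab$dyad_type)
})

test_that("life stage applies sex-specific strict adult thresholds", {
  demog <- toy_demography()
  # C1 female born 1992: age 13 in 2005 -> adult (> 12)
  expect_equal(life_stage(demog, "C1", 2005), "ADULT")
  expect_equal(life_stage(demog, "C1", 2004), "JUVENILE")
  # C2 male born 1995: age 14 in 2009 -> still juvenile (> 14 strict)
  expect_equal(life_stage(demog, "C2", 2009), "JUVENILE")
  expect_equal(life_stage(demog, "C2", 2010), "ADULT")
  expect_equal(life_stage(demog, "C1", 1991), "NOT_ALIVE")
  expect_equal(life_stage(demog, "GM", 2016), "NOT_ALIVE")
  expect_equal(life_stage(demog, "GM", 2015), "ADULT")  # death year counts
  # unknown sex: conservative male threshold unless overridden
  expect_equal(life_stage(demog, "E1", 2013), "JUVENILE")  # age 14
  expect_equal(life_stage(demog, "E1", 2013, sex_override = "F"), "ADULT")
})

test_that("reproductive status follows the retrospective last-birth rule", {
  demog <- toy_demography()
  # MA's calves born 1992 and 1995
  expect_equal(reproductive_status(demog, "MA", 1993), "REPRODUCTIVE")
  expect_equal(reproductive_status(demog, "MA", 1995), "REPRODUCTIVE")
  expect_equal(reproductive_status(demog, "MA", 1996), "POST_REPRODUCTIVE")
  # a female with no recorded calves is post-reproductive under this rule
  expect_equal(reproductive_status(demog, "D1", 2010), "POST_REPRODUCTIVE")
  expect_error(reproductive_status(demog, "C2", 2010), "females only")
  expect_error(reproductive_status(demog, "MA", 1960), "not alive")
  # age-threshold alternative
  expect_equal(reproductive_status(demog, "GM", 2005, rule = "age_threshold"),
               "POST_REPRODUCTIVE")
  expect_equal(reproductive_status(demog, "MA", 2005, rule = "age_threshold"),
               "REPRODUCTIVE")
})
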