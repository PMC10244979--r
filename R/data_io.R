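DEMOGRAPHY_COLS <- c("id", "sex", "birth_year", "death_year", "mother_id")
ENCOUNTER_COLS <- c("encounter_id", "date", "source_org", "full_encounter",
                    "min_estimated_count", "identified_ids")

SEX_LEVELS <- c("F", "M", "U")
SOURCE_LEVELS <- c("DFO", "CWR", "OTHER")
FULL_ENC_LEVELS <- c("TRUE", "FALSE", "UNRECORDED")

#' Read and validate a demography table
#'
#' Reads a comma-separated demography file with one row per individual:
#' `id,sex,birth_year,death_year,mother_id`. Sex is coded `F`/`M`/`U`
#' (`U` = sex not determined in the field); empty strings mark missing
#' `death_year` (individual not known dead) and missing `mother_id`
#' (maternal link not resolved). Birth and death years are calendar years;
#' ages are computed as integer year differences throughout the package,
#' matching the annual resolution of the source data.
#'
#' Validation enforces: unique ids; `birth_year <= death_year` where death
#' is recorded; every `mother_id` resolves to a female individual born
#' strictly before her offspring. Unrecognized extra columns are dropped
#' with a warning.
#'
#' @param path Path to a demography CSV file.
#' @return A `data.frame` with columns `id` (character), `sex` (character,
#'   one of `"F"`, `"M"`, `"U"`), `birth_year` (integer), `death_year`
#'   (integer, `NA` if unknown), `mother_id` (character, `NA` if unknown).
#' @export
load_demography <- function(path) {
  if (!file.exists(path)) stop("demography file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character())
  missing_cols <- setdiff(DEMOGRAPHY_COLS, names(raw))
  if (length(missing_cols))
    stop("demography file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(raw), DEMOGRAPHY_COLS)
  if (length(extra)) {
    warning("ignoring unrecognized demography column(s): ",
            paste(extra, collapse = ", "))
    raw <- raw[DEMOGRAPHY_COLS]
  }
  demog <- data.frame(
    id = trimws(raw$id),
    sex = trimws(raw$sex),
    birth_year = .parse_int(raw$birth_year, "birth_year"),
    death_year = .parse_int(raw$death_year, "death_year", allow_missing = TRUE),
    mother_id = .na_if_empty(trimws(raw$mother_id)),
    stringsAsFactors = FALSE
  )
  validate_demography(demog)
}

#' Validate an in-memory demography table
#'
#' Applies the same invariant checks as [load_demography()] to a
#' `data.frame` built in code (e.g. by [simulate_population()]).
#'
#' @param demog A `data.frame` with the demography columns.
#' @return The validated `data.frame`, invisibly unchanged.
#' @export
validate_demography <- function(demog) {
  stopifnot(is.data.frame(demog), all(DEMOGRAPHY_COLS %in% names(demog)))
  demog$birth_year <- as.integer(demog$birth_year)
  demog$death_year <- as.integer(demog$death_year)
  if (any(demog$id == "" | is.na(demog$id))) stop("empty individual id")
  dup <- demog$id[duplicated(demog$id)]
  if (length(dup)) stop("duplicate individual id(s): ",
                        paste(unique(dup), collapse = ", "))
  bad_sex <- setdiff(unique(demog$sex), SEX_LEVELS)
  if (length(bad_sex)) stop("invalid sex code(s): ",
                            paste(bad_sex, collapse = ", "),
                            " (expected F, M or U)")
  rev_life <- !is.na(demog$death_year) & demog$death_year < demog$birth_year
  if (any(rev_life))
    stop("death_year precedes birth_year for: ",
         paste(demog$id[rev_life], collapse = ", "))
  has_mother <- !is.na(demog$mother_id)
  if (any(has_mother)) {
    midx <- match(demog$mother_id[has_mother], demog$id)
    dangling <- demog$mother_id[has_mother][is.na(midx)]
    if (length(dangling))
      stop("mother_id does not resolve for: ",
           paste(unique(dangling), collapse = ", "))
    not_female <- demog$sex[midx] != "F"
    if (any(not_female))
      stop("mother_id refers to a non-female individual for offspring: ",
           paste(demog$id[has_mother][not_female], collapse = ", "))
    not_older <- demog$birth_year[midx] >= demog$birth_year[has_mother]
    if (any(not_older))
      stop("mother not born strictly before offspring: ",
           paste(demog$id[has_mother][not_older], collapse = ", "))
  }
  demog
}

#' Read and validate an encounter table
#'
#' Reads a comma-separated encounter file with one row per photo-identification
#' encounter: `encounter_id,date,source_org,full_encounter,min_estimated_count,identified_ids`.
#' Dates are ISO-8601 (`YYYY-MM-DD`); `identified_ids` is a semicolon-delimited
#' list of individual ids. `full_encounter` is `TRUE`/`FALSE`/`UNRECORDED`
#' (the field was not collected before 2005, so `UNRECORDED` is expected for
#' early rows); `min_estimated_count` is the field estimate of the minimum
#' number of whales present, empty when not recorded.
#'
#' Ids repeated within one encounter are deduplicated with a warning (an
#' encounter's identified set has set semantics); an empty identified set is
#' rejected. When `demography` is supplied every identified id must resolve
#' against it.
#'
#' @param path Path to an encounters CSV file.
#' @param demography Optional validated demography table used to resolve ids.
#' @return A `data.frame` with columns `encounter_id`, `date` (`Date`),
#'   `source_org`, `full_encounter`, `min_estimated_count` (integer, `NA`
#'   when unrecorded) and the list-column `identified` (character vectors).
#' @export
load_encounters <- function(path, demography = NULL) {
  if (!file.exists(path)) stop("encounter file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character())
  missing_cols <- setdiff(ENCOUNTER_COLS, names(raw))
  if (length(missing_cols))
    stop("encounter file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  dates <- as.Date(trimws(raw$date), format = "%Y-%m-%d")
  if (anyNA(dates))
    stop("unparseable date at row(s): ",
         paste(which(is.na(dates)), collapse = ", "))
  enc <- data.frame(
    encounter_id = trimws(raw$encounter_id),
    date = dates,
    source_org = trimws(raw$source_org),
    full_encounter = trimws(raw$full_encounter),
    min_estimated_count = .parse_int(raw$min_estimated_count,
                                     "min_estimated_count",
                                     allow_missing = TRUE),
    stringsAsFactors = FALSE
  )
  enc$identified <- lapply(strsplit(trimws(raw$identified_ids), ";", fixed = TRUE),
                           function(x) trimws(x[nzchar(trimws(x))]))
  validate_encounters(enc, demography)
}

#' Validate an in-memory encounter table
#'
#' @param enc An encounter `data.frame` as produced by [load_encounters()].
#' @param demography Optional demography table; when given, all identified ids
#'   must be present in it.
#' @return The validated encounter `data.frame` (identified sets deduplicated).
#' @export
validate_encounters <- function(enc, demography = NULL) {
  stopifnot(is.data.frame(enc),
            all(setdiff(ENCOUNTER_COLS, "identified_ids") %in% names(enc)),
            "identified" %in% names(enc))
  dup <- enc$encounter_id[duplicated(enc$encounter_id)]
  if (length(dup)) stop("duplicate encounter_id(s): ",
                        paste(unique(dup), collapse = ", "))
  bad_org <- setdiff(unique(enc$source_org), SOURCE_LEVELS)
  if (length(bad_org)) stop("invalid source_org value(s): ",
                            paste(bad_org, collapse = ", "))
  bad_full <- setdiff(unique(enc$full_encounter), FULL_ENC_LEVELS)
  if (length(bad_full)) stop("invalid full_encounter value(s): ",
                             paste(bad_full, collapse = ", "))
  if (any(!is.na(enc$min_estimated_count) & enc$min_estimated_count < 0))
    stop("negative min_estimated_count")
  n_dupes <- vapply(enc$identified, anyDuplicated, 0L)
  if (any(n_dupes > 0)) {
    warning("duplicate ids within encounter(s) ",
            paste(enc$encounter_id[n_dupes > 0], collapse = ", "),
            "; deduplicating")
    enc$identified <- lapply(enc$identified, unique)
  }
  if (any(lengths(enc$identified) == 0))
    stop("empty identified set in encounter(s): ",
         paste(enc$encounter_id[lengths(enc$identified) == 0], collapse = ", "))
  if (!is.null(demography)) {
    ids <- unique(unlist(enc$identified, use.names = FALSE))
    unknown <- setdiff(ids, demography$id)
    if (length(unknown))
      stop("identified id(s) not in demography: ",
           paste(unknown, collapse = ", "))
  }
  enc
}

#' Apply the encounter inclusion filter
#'
#' Keeps only encounters in which all whales present were plausibly
#' identified. From `cutoff_year` on, the database carries an explicit
#' "full encounter" flag and only flagged encounters are retained. Before
#' `cutoff_year` the flag did not exist; an early encounter is retained
#' only if it came from one of the two central repositories (`DFO`, `CWR`)
#' and the field estimate of the minimum number of whales present does not
#' exceed the number actually identified. Early encounters with no recorded
#' minimum estimate are excluded (completeness cannot be verified).
#'
#' @param enc A validated encounter table.
#' @param cutoff_year First year in which the full-encounter flag was
#'   collected (default 2005).
#' @return The retained rows of `enc`, in input order.
#' @export
filter_encounters <- function(enc, cutoff_year = 2005) {
  yr <- encounter_year(enc)
  modern <- yr >= cutoff_year
  keep_modern <- modern & enc$full_encounter == "TRUE"
  keep_early <- !modern &
    enc$source_org %in% c("DFO", "CWR") &
    !is.na(enc$min_estimated_count) &
    enc$min_estimated_count <= lengths(enc$identified)
  out <- enc[keep_modern | keep_early, , drop = FALSE]
  rownames(out) <- NULL
  out
}

encounter_year <- function(enc) as.integer(format(enc$date, "%Y"))

#' Classify the maternal kinship of a dyad
#'
#' Resolves the relationship of unordered pairs through the maternal pedigree
#' only (the data resolve kinship to r > 0.25 through observed mother-calf
#' bonds). Categories, checked in order:
#' `MOTHER_OFFSPRING`, `GRANDMOTHER_GRANDOFFSPRING` (mother's mother),
#' `MATERNAL_SIBLING` (same known mother), `KNOWN_UNRELATED` (both maternal
#' lineages known two generations up — mother and maternal grandmother —
#' and fully disjoint), else `UNKNOWN`. The result is symmetric in the
#' order of `i` and `j`.
#'
#' @param demography A validated demography table.
#' @param i,j Character vectors of individual ids (recycled to equal length).
#' @return Character vector of dyad types.
#' @export
classify_dyad_kinship <- function(demography, i, j) {
  n <- max(length(i), length(j))
  i <- rep_len(as.character(i), n)
  j <- rep_len(as.character(j), n)
  if (any(i == j)) stop("dyad requires two distinct individuals")
  ii <- match(i, demography$id)
  jj <- match(j, demography$id)
  if (anyNA(ii) || anyNA(jj))
    stop("unknown individual id(s): ",
         paste(unique(c(i[is.na(ii)], j[is.na(jj)])), collapse = ", "))
  mo <- demography$mother_id            # mother of each row
  gm <- mo[match(mo, demography$id)]    # maternal grandmother of each row
  m_i <- mo[ii]; m_j <- mo[jj]
  g_i <- gm[ii]; g_j <- gm[jj]

  out <- rep("UNKNOWN", n)
  mo_pair <- (!is.na(m_j) & m_j == i) | (!is.na(m_i) & m_i == j)
  gm_pair <- (!is.na(g_j) & g_j == i) | (!is.na(g_i) & g_i == j)
  sib <- !is.na(m_i) & !is.na(m_j) & m_i == m_j
  lineage_known <- !is.na(m_i) & !is.na(m_j) & !is.na(g_i) & !is.na(g_j)
  disjoint <- lineage_known &
    m_i != m_j & m_i != g_j & g_i != m_j & g_i != g_j &
    m_i != j & g_i != j & m_j != i & g_j != i
  out[disjoint] <- "KNOWN_UNRELATED"
  out[sib] <- "MATERNAL_SIBLING"
  out[gm_pair] <- "GRANDMOTHER_GRANDOFFSPRING"
  out[mo_pair] <- "MOTHER_OFFSPRING"
  out
}

#' Tabulate kinship over all unordered pairs
#'
#' @param demography A validated demography table.
#' @return A `data.frame` with columns `i`, `j` (canonical order `i < j`)
#'   and `dyad_type`, one row per unordered pair.
#' @export
dyad_kinship_table <- function(demography) {
  ids <- sort(demography$id)
  if (length(ids) < 2)
    return(data.frame(i = character(), j = character(),
                      dyad_type = character(), stringsAsFactors = FALSE))
  pr <- utils::combn(ids, 2)
  data.frame(i = pr[1, ], j = pr[2, ],
             dyad_type = classify_dyad_kinship(demography, pr[1, ], pr[2, ]),
             stringsAsFactors = FALSE)
}

#' Life stage of an individual in a calendar year
#'
#' Age is the integer calendar-year difference. Adulthood uses sex-specific
#' thresholds with strict inequality: a female is adult when older than 12
#' years, a male when older than 14. Individuals of unknown sex use the
#' conservative male threshold unless `sex_override` supplies an imputed sex.
#'
#' @param demography A validated demography table.
#' @param id Character vector of ids.
#' @param year Integer calendar year(s).
#' @param sex_override Optional character vector (`"F"`/`"M"`) replacing the
#'   recorded sex (used with imputed sexes); `NA` entries fall back to the
#'   recorded value.
#' @return Character vector in `{"JUVENILE", "ADULT", "NOT_ALIVE"}`.
#' @export
life_stage <- function(demography, id, year, sex_override = NULL) {
  n <- max(length(id), length(year))
  id <- rep_len(as.character(id), n)
  year <- rep_len(as.integer(year), n)
  k <- match(id, demography$id)
  if (anyNA(k)) stop("unknown individual id(s): ",
                     paste(unique(id[is.na(k)]), collapse = ", "))
  sex <- demography$sex[k]
  if (!is.null(sex_override)) {
    sex_override <- rep_len(sex_override, n)
    sex <- ifelse(is.na(sex_override), sex, sex_override)
  }
  birth <- demography$birth_year[k]
  death <- demography$death_year[k]
  alive <- year >= birth & (is.na(death) | year <= death)
  age <- year - birth
  thr <- ifelse(sex == "F", 12L, 14L)   # U falls to the male threshold
  out <- ifelse(!alive, "NOT_ALIVE", ifelse(age > thr, "ADULT", "JUVENILE"))
  out
}

#' Reproductive status of a mother in a calendar year
#'
#' The analysis stratifies mothers as reproductive or post-reproductive.
#' The default retrospective last-birth rule labels a female
#' `POST_REPRODUCTIVE` in a year when she has no recorded offspring born in
#' that year or later; a female with no recorded calves at all is
#' post-reproductive under this rule for every year. The alternative
#' `"age_threshold"` rule uses a fixed age cutoff instead.
#'
#' @param demography A validated demography table.
#' @param id Character vector of female ids.
#' @param year Integer calendar year(s).
#' @param rule `"last_birth"` (default) or `"age_threshold"`.
#' @param age_cutoff Age above which a female is post-reproductive under the
#'   age-threshold rule (default 40).
#' @return Character vector in `{"REPRODUCTIVE", "POST_REPRODUCTIVE"}`.
#' @export
reproductive_status <- function(demography, id, year,
                                rule = c("last_birth", "age_threshold"),
                                age_cutoff = 40L) {
  rule <- match.arg(rule)
  n <- max(length(id), length(year))
  id <- rep_len(as.character(id), n)
  year <- rep_len(as.integer(year), n)
  k <- match(id, demography$id)
  if (anyNA(k)) stop("unknown individual id(s): ",
                     paste(unique(id[is.na(k)]), collapse = ", "))
  if (any(demography$sex[k] != "F"))
    stop("reproductive_status is defined for females only; offending id(s): ",
         paste(unique(id[demography$sex[k] != "F"]), collapse = ", "))
  alive <- year >= demography$birth_year[k] &
    (is.na(demography$death_year[k]) | year <= demography$death_year[k])
  if (any(!alive))
    stop("mother not alive in queried year for id(s): ",
         paste(unique(id[!alive]), collapse = ", "))
  if (rule == "age_threshold") {
    age <- year - demography$birth_year[k]
    return(ifelse(age > age_cutoff, "POST_REPRODUCTIVE", "REPRODUCTIVE"))
  }
  # last-birth rule: reproductive iff some recorded calf is born >= year
  last_birth <- vapply(id, function(m) {
    calves <- demography$birth_year[!is.na(demography$mother_id) &
                                      demography$mother_id == m]
    if (length(calves)) max(as.numeric(calves)) else NA_real_
  }, 0)
  unname(ifelse(!is.na(last_birth) & last_birth >= year,
                "REPRODUCTIVE", "POST_REPRODUCTIVE"))
}

#' Write demography / encounter tables in the package dialect
#'
#' @param demog,enc Tables as returned by the loaders.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_demography <- function(demog, path) {
  out <- demog
  out$death_year <- ifelse(is.na(out$death_year), "", out$death_year)
  out$mother_id <- ifelse(is.na(out$mother_id), "", out$mother_id)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_demography
#' @export
write_encounters <- function(enc, path) {
  out <- data.frame(
    encounter_id = enc$encounter_id,
    date = format(enc$date, "%Y-%m-%d"),
    source_org = enc$source_org,
    full_encounter = enc$full_encounter,
    min_estimated_count = ifelse(is.na(enc$min_estimated_count), "",
                                 enc$min_estimated_count),
    identified_ids = vapply(enc$identified, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.parse_int <- function(x, what, allow_missing = FALSE) {
  x <- trimws(x)
  miss <- !nzchar(x) | is.na(x)
  if (any(miss) && !allow_missing)
    stop("missing ", what, " at row(s): ", paste(which(miss), collapse = ", "))
  out <- suppressWarnings(as.integer(x))
  bad <- !miss & is.na(out)
  if (any(bad))
    stop("non-integer ", what, " at row(s): ", paste(which(bad), collapse = ", "))
  out
}

.na_if_empty <- function(x) {
  x[!nzchar(x)] <- NA_character_
  x
}
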