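# Shared fixtures and independent brute-force oracles.

# Ten-individual maternal pedigree covering every kinship category:
#   GM (founder) -> MA, MB (daughters); MA -> C1 (F), C2 (M); MB -> D1 (F)
#   GX (founder) -> MX (daughter) -> E1; E2 has no known mother;
#   C1 -> F1 (third generation)
toy_demography <- function() {
  data.frame(
    id = c("GM", "MA", "MB", "C1", "C2", "D1", "GX", "MX", "E1", "E2", "F1"),
    sex = c("F", "F", "F", "F", "M", "F", "F", "F", "U", "M", "M"),
    birth_year = c(1960, 1975, 1978, 1992, 1995, 1996, 1962, 1980, 1999,
                   1990, 2010),
    death_year = c(2015, NA, NA, NA, NA, NA, 2010, NA, NA, 2005, NA),
    mother_id = c(NA, "GM", "GM", "MA", "MA", "MB", NA, "GX", "MX", NA, "C1"),
    stringsAsFactors = FALSE
  )
}

write_toy_demography <- function(df = toy_demography(),
                                 path = tempfile(fileext = ".csv")) {
  kindyn::write_demography(df, path)
  path
}

make_encounters <- function(dates, id_sets,
                            source_org = "DFO", full_encounter = "TRUE",
                            min_estimated_count = NA_integer_) {
  n <- length(dates)
  enc <- data.frame(
    encounter_id = sprintf("E%04d", seq_len(n)),
    date = as.Date(dates),
    source_org = rep_len(source_org, n),
    full_encounter = rep_len(full_encounter, n),
    min_estimated_count = rep_len(as.integer(min_estimated_count), n),
    stringsAsFactors = FALSE
  )
  enc$identified <- id_sets
  enc
}

write_enc_csv <- function(enc, path = tempfile(fileext = ".csv")) {
  kindyn::write_encounters(enc, path)
  path
}

# Random encounter data over a small closed population; used by the
# property tests and the oracle-equivalence acceptance check.
random_encounter_data <- function(seed, n_ind = 20, n_days = 120,
                                  years = 2000:2002) {
  set.seed(seed)
  ids <- sprintf("I%02d", seq_len(n_ind))
  demog <- data.frame(
    id = ids, sex = sample(c("F", "M", "U"), n_ind, replace = TRUE),
    birth_year = sample(1970:1995, n_ind, replace = TRUE),
    death_year = NA_integer_, mother_id = NA_character_,
    stringsAsFactors = FALSE
  )
  # some individuals die inside the window to exercise the alive rule
  dies <- sample(n_ind, max(1, n_ind %/% 5))
  demog$death_year[dies] <- sample(years, length(dies), replace = TRUE)
  all_days <- as.Date(sprintf("%d-01-01", years[1])) +
    sort(sample(0:(365 * length(years) - 1), n_days))
  rows_dates <- list(); rows_sets <- list(); r <- 0
  for (d in seq_along(all_days)) {
    for (e in seq_len(sample(1:3, 1))) {
      yr <- as.integer(format(all_days[d], "%Y"))
      alive <- demog$id[demog$birth_year <= yr &
                          (is.na(demog$death_year) | demog$death_year >= yr)]
      if (length(alive) < 1) next
      k <- sample(1:min(5, length(alive)), 1)
      r <- r + 1
      rows_dates[[r]] <- all_days[d]
      rows_sets[[r]] <- sample(alive, k)
    }
  }
  enc <- make_encounters(do.call(c, rows_dates), rows_sets)
  list(demography = demog, encounters = enc)
}

# Brute-force annual SRI oracle: explicit loops over days and pairs.
brute_force_sri <- function(enc, demog, year) {
  in_year <- as.integer(format(enc$date, "%Y")) == year
  enc <- enc[in_year, , drop = FALSE]
  alive <- demog$id[demog$birth_year <= year &
                      (is.na(demog$death_year) | demog$death_year >= year)]
  alive <- sort(alive)
  days <- sort(unique(enc$date))
  res <- list()
  for (a_i in seq_along(alive)) for (b_i in seq_len(a_i - 1L)) {
    i <- alive[b_i]; j <- alive[a_i]
    x <- 0L; d <- 0L
    for (day in as.list(days)) {
      sets <- enc$identified[enc$date == day]
      seen_i <- any(vapply(sets, function(s) i %in% s, NA))
      seen_j <- any(vapply(sets, function(s) j %in% s, NA))
      together <- any(vapply(sets, function(s) i %in% s && j %in% s, NA))
      if (seen_i || seen_j) d <- d + 1L
      if (together) x <- x + 1L
    }
    if (d > 0)
      res[[length(res) + 1]] <- data.frame(i = i, j = j, year = year,
                                           x = x, d = d, sri = x / d,
                                           stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(i = character(), j = character(), year = integer(),
                      x = integer(), d = integer(), sri = numeric()))
  out <- do.call(rbind, res)
  out[order(out$i, out$j), ]
}

# Brute-force lagged association rate: loops over every dyad and ordered
# day pair, mirroring the definition directly.
brute_force_lar <- function(enc, demog, bins, dyad_selector = NULL) {
  days <- sort(unique(enc$date))
  ids <- sort(unique(unlist(enc$identified)))
  seen <- function(id, day) {
    any(vapply(enc$identified[enc$date == day],
               function(s) id %in% s, NA))
  }
  assoc <- function(i, j, day) {
    any(vapply(enc$identified[enc$date == day],
               function(s) i %in% s && j %in% s, NA))
  }
  nb <- nrow(bins)
  num <- den <- numeric(nb)
  for (a_i in seq_along(ids)) for (b_i in seq_len(a_i - 1L)) {
    i <- ids[b_i]; j <- ids[a_i]
    for (t in as.list(days)) {
      if (!assoc(i, j, t)) next
      if (!is.null(dyad_selector) &&
          !isTRUE(dyad_selector(i, j, as.integer(format(t, "%Y"))))) next
      for (tp in as.list(days[days > t])) {
        lag <- as.numeric(tp - t) / 365.25
        bin <- which(bins$lag_lo < lag & lag <= bins$lag_hi)
        if (!length(bin)) next
        if (seen(i, tp) && seen(j, tp)) {
          den[bin] <- den[bin] + 1
          if (assoc(i, j, tp)) num[bin] <- num[bin] + 1
        }
      }
    }
  }
  data.frame(lag_lo = bins$lag_lo, lag_hi = bins$lag_hi,
             g = ifelse(den > 0, num / den, NA_real_), num = num, den = den)
}

# Encounters for a set of disjoint pairs that are both identified on every
# sampled day and associate independently with probability p_assoc.
independent_reassoc_encounters <- function(seed, n_pairs = 40, p_assoc = 0.3,
                                           n_days = 250, span_years = 12) {
  set.seed(seed)
  ids <- sprintf("P%02d_%s", rep(seq_len(n_pairs), each = 2), c("a", "b"))
  days <- as.Date("2000-01-01") +
    sort(sample(0:(365 * span_years - 1), n_days))
  dates <- list(); sets <- list(); r <- 0
  for (d in seq_along(days)) {
    for (p in seq_len(n_pairs)) {
      pair <- ids[c(2 * p - 1, 2 * p)]
      if (runif(1) < p_assoc) {
        r <- r + 1; dates[[r]] <- days[d]; sets[[r]] <- pair
      } else {
        r <- r + 1; dates[[r]] <- days[d]; sets[[r]] <- pair[1]
        r <- r + 1; dates[[r]] <- days[d]; sets[[r]] <- pair[2]
      }
    }
  }
  demog <- data.frame(id = ids, sex = "U", birth_year = 1980,
                      death_year = NA_integer_, mother_id = NA_character_,
                      stringsAsFactors = FALSE)
  list(demography = demog,
       encounters = make_encounters(do.call(c, dates), sets))
}

# Small record-level dataset with sex-only effects, for the
# intercept-only collapse comparison.
sex_only_records <- function(seed, n_dyads = 120, probs_f = c(0.5, 0.3, 0.2),
                             probs_m = c(0.15, 0.25, 0.6)) {
  set.seed(seed)
  recs <- list()
  for (k in seq_len(n_dyads)) {
    sx <- if (k %% 2 == 0) "F" else "M"
    pr <- if (sx == "F") probs_f else probs_m
    n_yr <- sample(3:8, 1)
    ages <- sort(sample(0:35, n_yr))
    recs[[k]] <- data.frame(
      mother_id = sprintf("M%03d", k), offspring_id = sprintf("O%03d", k),
      year = 2000 + ages, age = ages, sex = sx, sex_known = TRUE,
      category = sample.int(3, n_yr, replace = TRUE, prob = pr),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}
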