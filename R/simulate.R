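#' Configuration for the matrilineal population simulator
#'
#' Defaults emulate the statistical structure of a long-term Bigg's killer
#' whale photo-identification study: maternal units as constant companions,
#' female-biased budding dispersal after first reproduction, male philopatry
#' with rare roving, three tiers of dyadic association probability
#' (within-unit ~0.90, allied units ~0.11, background ~0.01) and daily
#' encounters with imperfect identification over 48 years.
#'
#' The observation-process parameters are derived from the tier targets:
#' the per-individual identification probability `p_id` solves
#' `p_id^2 / (2 p_id - p_id^2) = p_within` (the within-unit simple-ratio
#' expectation, exact regardless of encounter frequency), and the joint
#' encounter rates for allied and background unit pairs solve the analogous
#' day-rate equations for `p_allied` and `p_background`.
#'
#' @param n_founder_matrilines Number of founding females, each seeding a
#'   maternal unit.
#' @param n_years Study span in years (48 by default).
#' @param start_year First calendar year.
#' @param birth_prob Annual birth probability per reproductive female.
#' @param repro_age_first,repro_age_last Female reproductive ages (first
#'   birth possible at 12, last at 40, mirroring cessation in the late
#'   30s / early 40s).
#' @param mortality_calf,mortality_adult,mortality_old Annual mortality for
#'   ages 0-2, 3-40, and > 40.
#' @param founder_age_range Founder ages (uniform) at `start_year`.
#' @param dispersal_hazard Annual probability that a female who has had her
#'   first calf buds off with her descendants; 0 before first birth.
#' @param son_roving_prob Probability that a son permanently leaves his
#'   mother's unit at age 15 ("roving" male).
#' @param alliance_duration Years a budded daughter's unit remains allied
#'   (casual tier) to the unit she left; afterwards the two units fall back
#'   to the background tier.
#' @param p_within,p_allied,p_background Target tier association
#'   probabilities (must be strictly decreasing).
#' @param sampling_days Photo-identification sampling days per year.
#' @param p_unit_encounter Daily probability that a unit is encountered on
#'   its own on a sampling day.
#' @param p_sex_unknown_young,p_sex_unknown_adult Probability that the
#'   recorded sex is `U` for individuals dying before age 10 versus others
#'   (young whales are hard to sex in the field).
#' @return A `sim_config` list with derived observation parameters
#'   `p_id`, `q_joint_allied`, `q_joint_background` attached.
#' @export
sim_config <- function(n_founder_matrilines = 12,
                       n_years = 48,
                       start_year = 1973,
                       birth_prob = 0.25,
                       repro_age_first = 12,
                       repro_age_last = 40,
                       mortality_calf = 0.10,
                       mortality_adult = 0.02,
                       mortality_old = 0.08,
                       founder_age_range = c(12, 30),
                       dispersal_hazard = 0.08,
                       son_roving_prob = 0.05,
                       alliance_duration = 8,
                       p_within = 0.90,
                       p_allied = 0.11,
                       p_background = 0.01,
                       sampling_days = 60,
                       p_unit_encounter = 0.30,
                       p_sex_unknown_young = 0.8,
                       p_sex_unknown_adult = 0.05) {
  cfg <- as.list(environment())
  probs <- c(p_within, p_allied, p_background, birth_prob, dispersal_hazard,
             son_roving_prob, p_unit_encounter, mortality_calf,
             mortality_adult, mortality_old)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (!(p_within > p_allied && p_allied > p_background))
    stop("tier probabilities must satisfy p_within > p_allied > p_background")
  if (n_founder_matrilines < 1) stop("need at least one founder matriline")
  # derived observation parameters (see Details)
  cfg$p_id <- 2 * p_within / (1 + p_within)
  qa <- p_unit_encounter; p <- cfg$p_id
  qj <- function(s) 2 * s * qa / (p - s * (2 - p))
  cfg$q_joint_allied <- qj(p_allied)
  cfg$q_joint_background <- qj(p_background)
  structure(cfg, class = "sim_config")
}

#' Simulate a matrilineal demography
#'
#' Founding females seed matrilines; each reproductive female gives birth
#' annually with probability `birth_prob` between the first and last
#' reproductive ages; mortality is age-class specific; true sexes are 50/50.
#' Recorded sex is set to `U` for individuals that were hard to sex in the
#' field (mostly those dying young). Deterministic given `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list: `demography` (loader-dialect `data.frame`), `sex_true`
#'   (named character vector of true sexes).
#' @export
simulate_population <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  yrs <- seq(config$start_year, length.out = config$n_years)
  n0 <- config$n_founder_matrilines
  ages0 <- sample(seq(config$founder_age_range[1], config$founder_age_range[2]),
                  n0, replace = TRUE)
  ind <- data.frame(
    id = sprintf("F%02d", seq_len(n0)),
    sex_true = "F",
    birth_year = config$start_year - ages0,
    death_year = NA_integer_,
    mother_id = NA_character_,
    stringsAsFactors = FALSE
  )
  counter <- 0L
  for (y in yrs) {
    alive <- is.na(ind$death_year)
    age <- y - ind$birth_year
    # births
    fertile <- which(alive & ind$sex_true == "F" &
                       age >= config$repro_age_first &
                       age <= config$repro_age_last)
    if (length(fertile)) {
      gives_birth <- fertile[runif(length(fertile)) < config$birth_prob]
      for (m in gives_birth) {
        counter <- counter + 1L
        ind <- rbind(ind, data.frame(
          id = sprintf("W%04d", counter),
          sex_true = if (runif(1) < 0.5) "F" else "M",
          birth_year = y, death_year = NA_integer_,
          mother_id = ind$id[m], stringsAsFactors = FALSE))
      }
    }
    # deaths
    alive <- is.na(ind$death_year)
    age <- y - ind$birth_year
    mort <- ifelse(age <= 2, config$mortality_calf,
                   ifelse(age <= 40, config$mortality_adult,
                          config$mortality_old))
    dies <- alive & runif(nrow(ind)) < mort
    ind$death_year[dies] <- y
  }
  # recorded sex: young deaths mostly unsexed
  end_year <- yrs[length(yrs)]
  age_last <- ifelse(is.na(ind$death_year), end_year, ind$death_year) -
    ind$birth_year
  p_unk <- ifelse(age_last < 10, config$p_sex_unknown_young,
                  config$p_sex_unknown_adult)
  founder <- is.na(ind$mother_id)
  is_mother <- ind$id %in% ind$mother_id   # a recorded mother is known female
  unk <- !founder & !is_mother & runif(nrow(ind)) < p_unk
  demog <- data.frame(
    id = ind$id,
    sex = ifelse(unk, "U", ind$sex_true),
    birth_year = ind$birth_year,
    death_year = ind$death_year,
    mother_id = ind$mother_id,
    stringsAsFactors = FALSE
  )
  list(demography = validate_demography(demog),
       sex_true = setNames(ind$sex_true, ind$id))
}

#' Simulate social structure with budding dispersal
#'
#' Offspring are born into their mother's unit. From the year after her
#' first birth, a female buds off with annual probability
#' `dispersal_hazard`, founding a new unit and taking her whole co-resident
#' sub-lineage (her offspring and their descendants) with her, so a
#' mother-offspring pair is separated only by the offspring's own dispersal
#' event. The daughter's new unit stays allied (casual tier) to the unit
#' she left. Sons remain in their mother's unit except the rare rovers, who
#' leave to a solitary (background-tier) unit at age 15.
#'
#' @param pop Output of [simulate_population()].
#' @param config The [sim_config()] used to generate `pop`.
#' @param seed Integer seed.
#' @return A `kin_truth` list: `membership` (`data.frame` of `year`, `id`,
#'   `unit`), `allied` (`data.frame` of `year`, `unit_a`, `unit_b`),
#'   `rovers` (ids), `demography`, `sex_true`.
#' @export
simulate_social_structure <- function(pop, config = sim_config(), seed = 1) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed + 1003L)
  demog <- pop$demography
  sex_true <- pop$sex_true
  yrs <- seq(config$start_year, length.out = config$n_years)
  first_birth <- vapply(demog$id, function(m) {
    calves <- demog$birth_year[!is.na(demog$mother_id) & demog$mother_id == m]
    if (length(calves)) min(calves) else NA_integer_
  }, 0L)

  unit <- setNames(ifelse(is.na(demog$mother_id), paste0("U_", demog$id),
                          NA_character_), demog$id)
  allied_pairs <- data.frame(unit_a = character(), unit_b = character(),
                             start_year = integer())
  rovers <- character(0)
  membership <- vector("list", length(yrs))
  allied_by_year <- vector("list", length(yrs))
  unit_counter <- 0L

  for (t in seq_along(yrs)) {
    y <- yrs[t]
    alive <- demog$birth_year <= y &
      (is.na(demog$death_year) | demog$death_year >= y)
    # newborns join mother's unit
    born <- which(demog$birth_year == y & !is.na(demog$mother_id))
    if (length(born))
      unit[demog$id[born]] <- unit[demog$mother_id[born]]
    # roving sons leave at 15
    sons15 <- which(alive & sex_true[demog$id] == "M" &
                      (y - demog$birth_year) == 15 &
                      !is.na(demog$mother_id))
    for (s in sons15) {
      if (runif(1) < config$son_roving_prob) {
        id <- demog$id[s]
        unit[id] <- paste0("R_", id)
        rovers <- c(rovers, id)
      }
    }
    # budding dispersal of post-first-birth females
    eligible <- which(alive & sex_true[demog$id] == "F" &
                        !is.na(first_birth[demog$id]) &
                        first_birth[demog$id] < y &
                        !is.na(demog$mother_id))
    for (e in eligible) {
      id <- demog$id[e]
      # only those still co-resident with their mother can bud away from her
      mom <- demog$mother_id[e]
      if (is.na(unit[id]) || unit[id] != unit[mom]) next
      if (runif(1) < config$dispersal_hazard) {
        unit_counter <- unit_counter + 1L
        new_unit <- sprintf("B%04d", unit_counter)
        old_unit <- unit[id]
        movers <- .sublineage(demog, id)
        movers <- movers[!is.na(unit[movers]) & unit[movers] == old_unit]
        unit[movers] <- new_unit
        allied_pairs <- rbind(allied_pairs, data.frame(
          unit_a = min(old_unit, new_unit), unit_b = max(old_unit, new_unit),
          start_year = y))
      }
    }
    alive_ids <- demog$id[alive]
    alive_ids <- alive_ids[!is.na(unit[alive_ids])]
    membership[[t]] <- data.frame(year = y, id = alive_ids,
                                  unit = unname(unit[alive_ids]),
                                  stringsAsFactors = FALSE)
    units_now <- unique(unit[alive_ids])
    if (nrow(allied_pairs)) {
      keep <- allied_pairs$unit_a %in% units_now &
        allied_pairs$unit_b %in% units_now &
        (y - allied_pairs$start_year) < config$alliance_duration
      allied_by_year[[t]] <- if (any(keep))
        data.frame(year = y, unit_a = allied_pairs$unit_a[keep],
                   unit_b = allied_pairs$unit_b[keep],
                   stringsAsFactors = FALSE)
      else NULL
    }
  }
  structure(list(
    membership = do.call(rbind, membership),
    allied = do.call(rbind, allied_by_year),
    rovers = rovers,
    demography = demog,
    sex_true = sex_true
  ), class = "kin_truth")
}

# descendants of id through the maternal line, including id itself
.sublineage <- function(demog, id) {
  out <- id
  frontier <- id
  repeat {
    kids <- demog$id[!is.na(demog$mother_id) & demog$mother_id %in% frontier]
    kids <- setdiff(kids, out)
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' True association tier of dyads in a year
#'
#' @param truth A `kin_truth` object.
#' @param i,j Id vectors (recycled).
#' @param year Year vector (recycled).
#' @return Character vector: `"CONSTANT"` (same unit), `"CASUAL"` (allied
#'   units), `"WEAK"` (anything else), `NA` if either is not alive that year.
#' @export
true_tier <- function(truth, i, j, year) {
  n <- max(length(i), length(j), length(year))
  i <- rep_len(i, n); j <- rep_len(j, n); year <- rep_len(year, n)
  mkey <- paste(truth$membership$year, truth$membership$id)
  ui <- truth$membership$unit[match(paste(year, i), mkey)]
  uj <- truth$membership$unit[match(paste(year, j), mkey)]
  akey <- if (is.null(truth$allied)) character(0) else
    paste(truth$allied$year, truth$allied$unit_a, truth$allied$unit_b)
  pair_lo <- pmin(ui, uj); pair_hi <- pmax(ui, uj)
  allied <- paste(year, pair_lo, pair_hi) %in% akey
  out <- ifelse(is.na(ui) | is.na(uj), NA_character_,
                ifelse(ui == uj, "CONSTANT",
                       ifelse(allied, "CASUAL", "WEAK")))
  out
}

# Solve the daily joint-encounter rates that make the expected simple-ratio
# index of allied and background dyads hit the configured tier targets,
# given the number of units present. For a cross-unit dyad with joint rate
# q and per-unit extra encounter exposure E (alone + other joint draws):
#   SRI ~ q p^2 / (p (E1 + E2) - q p^2 - (E1 - q)(E2 - q) p^2)
# Solved by fixed-point iteration over the mutual exposure terms.
.solve_joint_rates <- function(n_units, config) {
  p <- config$p_id; qa <- config$p_unit_encounter
  qj <- config$q_joint_allied; qb <- config$q_joint_background
  sri_pred <- function(q, E) {
    (q * p^2) / (2 * E * p - q * p^2 - (E - q)^2 * p^2)
  }
  for (iter in 1:4) {
    E_all <- qa + qj + max(0, n_units - 2) * qb
    E_bg <- qa + qj + max(0, n_units - 2) * qb
    qj_new <- tryCatch(
      stats::uniroot(function(q) sri_pred(q, qa + q + max(0, n_units - 2) * qb) -
                       config$p_allied, c(1e-6, 0.9))$root,
      error = function(e) qj)
    qb_new <- tryCatch(
      stats::uniroot(function(q) sri_pred(q, qa + qj_new + max(0, n_units - 3) * q) -
                       config$p_background, c(1e-8, 0.5))$root,
      error = function(e) qb)
    if (abs(qj_new - qj) < 1e-8 && abs(qb_new - qb) < 1e-8) break
    qj <- qj_new; qb <- qb_new
  }
  list(q_allied = qj, q_background = qb)
}

#' Simulate the photo-identification observation process
#'
#' On each of `sampling_days` per year, each unit is encountered on its own
#' with probability `p_unit_encounter`; each allied unit pair is encountered
#' jointly (one encounter containing both units) at the derived rate for the
#' casual tier, and each other unit pair at the background rate. Every
#' member of an encountered unit is identified independently with
#' probability `p_id`; encounters with nobody identified are discarded.
#' Encounters are emitted in the package CSV dialect with
#' `full_encounter = TRUE` and the minimum estimated count set to the
#' number identified.
#'
#' @param truth A `kin_truth` from [simulate_social_structure()].
#' @param config The matching [sim_config()].
#' @param seed Integer seed.
#' @return An encounter `data.frame` in loader format.
#' @export
simulate_encounters <- function(truth, config = sim_config(), seed = 1) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed + 2007L)
  yrs <- sort(unique(truth$membership$year))
  enc_rows <- list(); eid <- 0L
  for (y in yrs) {
    mem <- truth$membership[truth$membership$year == y, , drop = FALSE]
    units <- split(mem$id, mem$unit)
    unames <- names(units)
    nu <- length(unames)
    ak <- if (is.null(truth$allied)) character(0) else {
      a <- truth$allied[truth$allied$year == y, , drop = FALSE]
      paste(pmin(a$unit_a, a$unit_b), pmax(a$unit_a, a$unit_b))
    }
    days <- sort(sample(seq_len(364), config$sampling_days))
    dates <- as.Date(sprintf("%d-01-01", y)) + days - 1L
    pair_idx <- if (nu >= 2) utils::combn(nu, 2) else NULL
    pair_allied <- if (!is.null(pair_idx))
      paste(pmin(unames[pair_idx[1, ]], unames[pair_idx[2, ]]),
            pmax(unames[pair_idx[1, ]], unames[pair_idx[2, ]])) %in% ak
    else logical(0)
    rates <- .solve_joint_rates(nu, config)
    for (dd in seq_along(dates)) {
      groups <- list()
      in_joint <- logical(nu)
      if (!is.null(pair_idx)) {
        qp <- ifelse(pair_allied, rates$q_allied, rates$q_background)
        joint <- which(runif(ncol(pair_idx)) < qp)
        groups <- lapply(joint, function(p)
          c(units[[pair_idx[1, p]]], units[[pair_idx[2, p]]]))
        in_joint[pair_idx[, joint]] <- TRUE
      }
      # a unit already in a joint encounter is not also encountered alone
      solo <- which(!in_joint & runif(nu) < config$p_unit_encounter)
      groups <- c(groups, lapply(solo, function(u) units[[u]]))
      for (g in groups) {
        idd <- g[runif(length(g)) < config$p_id]
        if (!length(idd)) next
        eid <- eid + 1L
        enc_rows[[eid]] <- list(id = eid, date = dates[dd], ids = idd)
      }
    }
  }
  if (!length(enc_rows))
    stop("simulation produced no encounters; check the configuration")
  enc <- data.frame(
    encounter_id = sprintf("E%06d", vapply(enc_rows, `[[`, 0L, "id")),
    date = as.Date(vapply(enc_rows, function(r) as.character(r$date), "")),
    source_org = "DFO",
    full_encounter = "TRUE",
    min_estimated_count = vapply(enc_rows, function(r) length(r$ids), 0L),
    stringsAsFactors = FALSE
  )
  enc$identified <- lapply(enc_rows, `[[`, "ids")
  validate_encounters(enc, truth$demography)
}

#' Closed-form mother-offspring tier probabilities implied by the generator
#'
#' For a mother-offspring pair with both alive, the probability the pair is
#' in each association tier at offspring age `a`. Daughters leave the
#' mother's unit only through their own budding event, whose annual hazard
#' `h` starts the year after their first birth; with annual birth
#' probability `b` from age `repro_age_first` onward, the co-residence
#' (constant-companion) probability is
#' `P(a) = sum_f b (1-b)^(f - first) (1-h)^(a-f) + (1-b)^(min(a,last)-first+1)`
#' over first-birth ages `f <= min(a, last)`. After budding the units stay
#' allied (casual) for `alliance_duration` years, then fall to the
#' background (weak) tier; so the weak probability at age `a` equals the
#' probability of having budded by age `a - alliance_duration`. Sons stay
#' for life except rovers, who leave (to the background tier) at age 15.
#'
#' @param config A [sim_config()].
#' @param ages Integer offspring ages.
#' @param sex `"F"` or `"M"`.
#' @param tier `"CONSTANT"`, `"CASUAL"` or `"WEAK"`.
#' @return Numeric vector of tier probabilities.
#' @export
dispersal_truth_curve <- function(config, ages, sex,
                                  tier = c("CONSTANT", "CASUAL", "WEAK")) {
  stopifnot(sex %in% c("F", "M"))
  tier <- match.arg(tier)
  if (sex == "M") {
    p_const <- ifelse(ages >= 15, 1 - config$son_roving_prob, 1)
    return(switch(tier, CONSTANT = p_const, CASUAL = rep(0, length(ages)),
                  WEAK = 1 - p_const))
  }
  b <- config$birth_prob; h <- config$dispersal_hazard
  first <- config$repro_age_first; last <- config$repro_age_last
  p_const_at <- function(a) {
    if (a < first) return(1)
    fs <- first:min(a, last)
    sum(b * (1 - b)^(fs - first) * (1 - h)^(a - fs)) +
      (1 - b)^(min(a, last) - first + 1)
  }
  p_const <- vapply(ages, p_const_at, 0)
  if (tier == "CONSTANT") return(p_const)
  p_weak <- vapply(ages - config$alliance_duration,
                   function(a) 1 - p_const_at(max(a, 0)), 0)
  if (tier == "WEAK") p_weak else 1 - p_const - p_weak
}

#' Canned benchmark scenarios with ground truth
#'
#' * `fig1_tiers`: 3000 dyad-year (x, d) counts drawn from the three-tier
#'   beta-binomial truth (weights 0.95 / 0.04 / 0.01; means 0.01 / 0.11 /
#'   0.90; d uniform on 10..60) with component labels — the regime of the
#'   observed annual index distribution.
#' * `fig2_stability`: a compact full simulation (8 matrilines, 20 years)
#'   for lagged-association-rate contrasts between mother-offspring and
#'   other dyads.
#' * `fig5_dispersal`: the full 48-year simulation with budding dispersal,
#'   for end-to-end classification and bond-dynamics recovery.
#' * `null_no_age_effect`: mother-offspring dyad-year records whose category
#'   probabilities do not depend on offspring age (dyad-level noise only),
#'   for null recovery of the dynamics model.
#'
#' @param scenario Scenario name.
#' @param seed Integer seed.
#' @return A list whose elements depend on the scenario (always includes
#'   `scenario`, `seed`, and ground truth; full simulations carry
#'   `demography`, `encounters`, `truth`, `config`).
#' @export
make_benchmark <- function(scenario = c("fig1_tiers", "fig2_stability",
                                        "fig5_dispersal",
                                        "null_no_age_effect"),
                           seed = 1) {
  scenario <- tryCatch(match.arg(scenario), error = function(e)
    stop("unknown scenario '", scenario[1], "'; available: fig1_tiers, ",
         "fig2_stability, fig5_dispersal, null_no_age_effect"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed + 5001L)
  if (scenario == "fig1_tiers") {
    n <- 3000
    pi_true <- c(0.95, 0.04, 0.01)
    mu_true <- c(0.01, 0.11, 0.90)
    rho_true <- c(0.005, 0.03, 0.03)
    comp <- sample.int(3, n, replace = TRUE, prob = pi_true)
    d <- sample(10:60, n, replace = TRUE)
    p <- rbeta(n, mu_true[comp] * (1 - rho_true[comp]) / rho_true[comp],
               (1 - mu_true[comp]) * (1 - rho_true[comp]) / rho_true[comp])
    x <- rbinom(n, d, p)
    return(list(scenario = scenario, seed = seed, x = x, d = d,
                truth_component = comp,
                pi_true = pi_true, mu_true = mu_true, rho_true = rho_true))
  }
  if (scenario == "null_no_age_effect") {
    n_dyads <- 150
    probs <- c(WEAK = 0.25, CASUAL = 0.25, CONSTANT = 0.50)
    recs <- list()
    for (k in seq_len(n_dyads)) {
      sx <- if (runif(1) < 0.5) "F" else "M"
      birth_age <- sample(0:8, 1)
      n_yr <- sample(4:12, 1)
      ages <- sort(sample(birth_age + 0:35, n_yr))
      shift <- rnorm(1, sd = 0.5)   # dyad-level propensity, age-independent
      lp <- log(probs)
      pr <- exp(lp + c(0, 0, shift)); pr <- pr / sum(pr)
      cat_i <- sample.int(3, n_yr, replace = TRUE, prob = pr)
      recs[[k]] <- data.frame(
        mother_id = sprintf("M%03d", k), offspring_id = sprintf("O%03d", k),
        year = 2000 + ages, age = ages, sex = sx,
        sex_known = TRUE, category = cat_i, stringsAsFactors = FALSE)
    }
    return(list(scenario = scenario, seed = seed,
                records = do.call(rbind, recs), probs_true = probs))
  }
  cfg <- if (scenario == "fig2_stability")
    sim_config(n_founder_matrilines = 8, n_years = 20, sampling_days = 40)
  else sim_config()
  pop <- simulate_population(cfg, seed)
  truth <- simulate_social_structure(pop, cfg, seed)
  enc <- simulate_encounters(truth, cfg, seed)
  list(scenario = scenario, seed = seed, config = cfg,
       demography = pop$demography, sex_true = pop$sex_true,
       encounters = enc, truth = truth)
}
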