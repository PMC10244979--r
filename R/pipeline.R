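#' Pipeline run configuration
#'
#' One structured object holds every stage parameter plus a single global
#' seed from which per-stage seeds are derived deterministically, so a run
#' is reproducible from its manifest alone.
#'
#' @param demography_path,encounters_path Input CSVs, or `NULL` when
#'   `scenario` names a synthetic benchmark to generate instead.
#' @param scenario Optional [make_benchmark()] scenario.
#' @param out_dir Output directory for stage tables and the manifest.
#' @param cutoff_year Encounter-filter cutoff year.
#' @param years Years for the annual index / mixture stages (`NULL` = all
#'   encounter years).
#' @param max_lag,jackknife Lagged-association-rate settings.
#' @param K,K_range,n_restarts Mixture settings.
#' @param dynamics A [dynamics_config()].
#' @param p_male Sex-imputation probability of male.
#' @param seed Global seed.
#' @param stages Character vector of stages to run, in order, from
#'   `c("filter", "sri", "lar", "mixture", "dynamics")`.
#' @return A `run_config` list.
#' @export
run_config <- function(demography_path = NULL, encounters_path = NULL,
                       scenario = NULL, out_dir = tempfile("kindyn_run_"),
                       cutoff_year = 2005, years = NULL, max_lag = 10,
                       jackknife = "year", K = 3, K_range = 2:5,
                       n_restarts = 20, dynamics = dynamics_config("desk"),
                       p_male = 0.5, seed = 1,
                       stages = c("filter", "sri", "lar", "mixture",
                                  "dynamics")) {
  cfg <- as.list(environment())
  if (is.null(scenario) &&
      (is.null(demography_path) || is.null(encounters_path)))
    stop("config error: provide demography_path and encounters_path, ",
         "or a scenario name")
  if (!is.null(demography_path) && !file.exists(demography_path))
    stop("config error: demography path does not exist: ", demography_path)
  if (!is.null(encounters_path) && !file.exists(encounters_path))
    stop("config error: encounters path does not exist: ", encounters_path)
  structure(cfg, class = "run_config")
}

.stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 11L, filter = 23L, sri = 37L, lar = 41L,
               mixture = 53L, dynamics = 67L)
  (cfg$seed * 131L + offsets[[stage]]) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Executes the stage chain filter -> annual SRI -> lagged association
#' rates -> per-year mixture classification -> bond dynamics, each stage
#' feeding the next, writing every stage's table plus a JSON manifest
#' (configuration, seeds, package version) and a summary report to
#' `out_dir`. A stage failure stops the chain with a stage-named error;
#' tables already written are retained. The summary tabulates bond category
#' against maternal dyad type (the dyad-type stratification of
#' classifications) and per-component association-probability summaries.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the stage outputs (`demography`,
#'   `encounters_filtered`, `sri`, `lar`, `bond_series`, `records`,
#'   `dynamics_fit`, `curves`, `summary`), also written under
#'   `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(cfg$scenario)) {
    bench <- stage("simulate",
                   make_benchmark(cfg$scenario, seed = .stage_seed(cfg, "simulate")))
    if (is.null(bench$encounters))
      stop("pipeline stage 'simulate' failed: scenario '", cfg$scenario,
           "' does not produce encounter data", call. = FALSE)
    demog <- bench$demography; enc <- bench$encounters
    write_demography(demog, file.path(cfg$out_dir, "demography.csv"))
    write_encounters(enc, file.path(cfg$out_dir, "encounters.csv"))
  } else {
    demog <- stage("load", load_demography(cfg$demography_path))
    enc <- stage("load", load_encounters(cfg$encounters_path, demog))
  }
  res$demography <- demog

  if ("filter" %in% cfg$stages) {
    enc <- stage("filter", filter_encounters(enc, cfg$cutoff_year))
    res$encounters_filtered <- enc
  }
  years <- cfg$years
  if (is.null(years)) years <- sort(unique(encounter_year(enc)))

  if ("sri" %in% cfg$stages) {
    sri <- stage("sri", annual_sri_range(enc, demog, years))
    utils::write.csv(sri, file.path(cfg$out_dir, "sri.csv"),
                     row.names = FALSE)
    res$sri <- sri
  }

  if ("lar" %in% cfg$stages) {
    sels <- dyad_selector_library(demog)
    use <- c("MOTHER_OFFSPRING", "ALL_OTHER_DYADS")
    lar_tabs <- stage("lar", lapply(use, function(nm) {
      r <- lagged_association_rate(enc, demog, dyad_selector = sels[[nm]],
                                   bins = lag_bins(cfg$max_lag),
                                   jackknife = cfg$jackknife)
      cbind(stratum = nm, r$table)
    }))
    lar_tab <- do.call(rbind, lar_tabs)
    utils::write.csv(lar_tab, file.path(cfg$out_dir, "lar.csv"),
                     row.names = FALSE)
    res$lar <- lar_tab
  }

  if ("mixture" %in% cfg$stages) {
    series <- stage("mixture",
                    annual_bond_series(enc, demog, years, K = cfg$K,
                                       n_restarts = cfg$n_restarts,
                                       seed = .stage_seed(cfg, "mixture")))
    utils::write.csv(series$bonds, file.path(cfg$out_dir, "bonds.csv"),
                     row.names = FALSE)
    utils::write.csv(series$summary,
                     file.path(cfg$out_dir, "mixture_summary.csv"),
                     row.names = FALSE)
    res$bond_series <- series
    res$summary <- stage("mixture", bond_report(series$bonds, demog))
    utils::write.csv(res$summary$by_dyad_type,
                     file.path(cfg$out_dir, "category_by_dyad_type.csv"),
                     row.names = FALSE)
    utils::write.csv(res$summary$by_component,
                     file.path(cfg$out_dir, "component_probabilities.csv"),
                     row.names = FALSE)
  }

  if ("dynamics" %in% cfg$stages) {
    if (is.null(res$bond_series))
      stop("pipeline stage 'dynamics' failed: mixture stage must run first",
           call. = FALSE)
    records <- stage("dynamics", build_model_data(res$bond_series$bonds, demog))
    res$records <- records
    imps <- stage("dynamics",
                  impute_sex(records, cfg$dynamics$n_imputations,
                             p_male = cfg$p_male,
                             seed = .stage_seed(cfg, "dynamics")))
    fit <- stage("dynamics",
                 fit_bond_dynamics(imps, cfg$dynamics,
                                   seed = .stage_seed(cfg, "dynamics")))
    curves <- predict_probability_curves(fit)
    utils::write.csv(curves, file.path(cfg$out_dir, "curves.csv"),
                     row.names = FALSE)
    res$dynamics_fit <- fit
    res$curves <- curves
  }

  manifest <- list(
    package = "kindyn",
    version = as.character(utils::packageVersion("kindyn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    stage_seeds = lapply(setNames(nm = c("simulate", "filter", "sri", "lar",
                                         "mixture", "dynamics")),
                         function(s) .stage_seed(cfg, s)),
    config = cfg[setdiff(names(cfg), "dynamics")],
    dynamics = unclass(cfg$dynamics)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(res)
}

#' Summaries of classifications by dyad type and component
#'
#' `by_dyad_type` counts dyad-year classifications within each maternal
#' kinship category (the stacked-bar stratification of bond categories);
#' `by_component` summarises the simple-ratio indices falling in each
#' component (mean, SD, quartiles).
#'
#' @param bonds Long bond table from [annual_bond_series()].
#' @param demography Validated demography table.
#' @return List of two `data.frame`s.
#' @export
bond_report <- function(bonds, demography) {
  dt <- classify_dyad_kinship(demography, bonds$i, bonds$j)
  by_type <- as.data.frame(table(dyad_type = dt, category = bonds$category))
  names(by_type)[3] <- "n"
  by_comp <- do.call(rbind, lapply(split(bonds$sri, bonds$category),
                                   function(v) {
    if (!length(v)) return(NULL)
    data.frame(n = length(v), mean = mean(v), sd = sd(v),
               q25 = quantile(v, 0.25, names = FALSE),
               median = quantile(v, 0.5, names = FALSE),
               q75 = quantile(v, 0.75, names = FALSE))
  }))
  by_comp <- cbind(category = rownames(by_comp), by_comp)
  rownames(by_comp) <- NULL
  list(by_dyad_type = by_type, by_component = by_comp)
}
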