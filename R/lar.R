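#' Yearly lag bins
#'
#' @param max_lag Maximum lag in years.
#' @param width Bin width in years.
#' @return A `data.frame` of `lag_lo` (exclusive) and `lag_hi` (inclusive)
#'   bounds tiling `(0, max_lag]`.
#' @export
lag_bins <- function(max_lag = 10, width = 1) {
  lo <- seq(0, max_lag - width, by = width)
  data.frame(lag_lo = lo, lag_hi = lo + width)
}

#' Lagged association rate with jackknife standard errors
#'
#' The lagged association rate g(tau) estimates the probability that a dyad
#' associated on day t is associated again on a later day t', given that
#' both members were identified on t'. For every ordered day pair
#' (t, t') with t' - t falling in a lag bin, and every dyad associated at t
#' (and, when a selector is given, satisfying it at t):
#' the denominator counts pairs with both members identified at t', the
#' numerator those where the dyad was associated again at t'. Conditioning
#' the denominator on both members being identified makes g a pure
#' re-association probability (g = 1 is attainable for perfectly stable
#' pairs).
#'
#' Standard errors come from delete-one-group jackknife resampling, where a
#' group is by default a calendar year of sampled days (configurable to
#' 30-day blocks); a day pair is dropped when either of its days falls in
#' the deleted group.
#'
#' @param enc Filtered, validated encounter table.
#' @param demography Validated demography table.
#' @param dyad_selector Optional predicate `function(i, j, year)` returning
#'   `TRUE` when the dyad belongs to the stratum at the (earlier) day's
#'   calendar year; `NULL` selects all dyads.
#' @param bins Lag bins from [lag_bins()].
#' @param jackknife Grouping for jackknife errors: `"year"`, `"block30"`
#'   (30-day blocks) or `"none"`.
#' @return An object of class `kin_lar`: a list with `table` (a `data.frame`
#'   of `lag_lo`, `lag_hi`, `g`, `se`, `num`, `den`; bins with `den = 0`
#'   have `g = NA`), `loo` (delete-one-group estimates, groups x bins),
#'   `no_data` flag, and the binning used.
#' @export
lagged_association_rate <- function(enc, demography, dyad_selector = NULL,
                                    bins = lag_bins(),
                                    jackknife = c("year", "block30", "none")) {
  jackknife <- match.arg(jackknife)
  stopifnot(all(bins$lag_lo < bins$lag_hi))
  if (nrow(bins) > 1 &&
      any(abs(bins$lag_lo[-1] - bins$lag_hi[-nrow(bins)]) > 1e-9))
    stop("lag bins must tile the lag axis without gaps or overlap")
  nb <- nrow(bins)
  breaks <- c(bins$lag_lo[1], bins$lag_hi)
  max_lag_days <- bins$lag_hi[nb] * 365.25

  daily <- daily_identification_sets(enc)
  if (nrow(daily$pairs) == 0)
    return(.lar_no_data(bins))

  day0 <- min(daily$ids$day)
  group_of <- switch(jackknife,
    year = function(d) as.integer(format(d, "%Y")),
    block30 = function(d) as.integer(as.numeric(d - day0) %/% 30L),
    none = function(d) rep(1L, length(d)))
  groups <- sort(unique(group_of(daily$ids$day)))
  ng <- length(groups)

  # per-individual identification days
  id_days <- split(as.integer(daily$ids$day), daily$ids$id)
  # per-dyad association days
  key <- paste(daily$pairs$i, daily$pairs$j, sep = "\r")
  assoc_days <- split(as.integer(daily$pairs$day), key)

  den_arr <- numeric(nb * ng * ng)
  num_arr <- numeric(nb * ng * ng)
  day_year <- function(d) as.integer(format(as.Date(d, origin = "1970-01-01"),
                                            "%Y"))
  for (k in seq_along(assoc_days)) {
    ij <- strsplit(names(assoc_days)[k], "\r", fixed = TRUE)[[1]]
    A_full <- sort(assoc_days[[k]])   # all association days (for t')
    A <- A_full                       # earlier days t, possibly stratified
    B <- sort(intersect(id_days[[ij[1]]], id_days[[ij[2]]]))
    if (!is.null(dyad_selector)) {
      yrs <- day_year(A)
      uy <- unique(yrs)
      ok <- uy[vapply(uy, function(y) isTRUE(dyad_selector(ij[1], ij[2], y)),
                      NA)]
      A <- A[yrs %in% ok]
      if (!length(A)) next
    }
    lag <- outer(B, A, "-")
    valid <- which(lag > 0 & lag <= max_lag_days)
    if (!length(valid)) next
    bin <- findInterval(lag[valid] / 365.25, breaks, left.open = TRUE)
    keep <- bin >= 1 & bin <= nb
    valid <- valid[keep]; bin <- bin[keep]
    if (!length(valid)) next
    ai <- ((valid - 1L) %/% length(B)) + 1L   # column index -> A
    bi <- ((valid - 1L) %% length(B)) + 1L    # row index -> B
    gA <- match(group_of(as.Date(A[ai], origin = "1970-01-01")), groups)
    gB <- match(group_of(as.Date(B[bi], origin = "1970-01-01")), groups)
    idx <- bin + nb * ((gA - 1L) + ng * (gB - 1L))
    den_arr <- den_arr + tabulate(idx, nbins = nb * ng * ng)
    again <- B[bi] %in% A_full
    if (any(again))
      num_arr <- num_arr + tabulate(idx[again], nbins = nb * ng * ng)
  }

  den3 <- array(den_arr, dim = c(nb, ng, ng))
  num3 <- array(num_arr, dim = c(nb, ng, ng))
  den <- apply(den3, 1, sum)
  num <- apply(num3, 1, sum)
  if (all(den == 0)) return(.lar_no_data(bins))
  g <- ifelse(den > 0, num / den, NA_real_)

  loo <- NULL
  se <- rep(NA_real_, nb)
  if (jackknife != "none" && ng >= 2) {
    loo <- matrix(NA_real_, ng, nb, dimnames = list(groups, NULL))
    for (k in seq_len(ng)) {
      dk <- den - apply(den3[, k, , drop = FALSE], 1, sum) -
        apply(den3[, , k, drop = FALSE], 1, sum) + den3[, k, k]
      nk <- num - apply(num3[, k, , drop = FALSE], 1, sum) -
        apply(num3[, , k, drop = FALSE], 1, sum) + num3[, k, k]
      loo[k, ] <- ifelse(dk > 0, nk / dk, NA_real_)
    }
    se <- jackknife_se(loo)
  }

  structure(list(
    table = data.frame(lag_lo = bins$lag_lo, lag_hi = bins$lag_hi,
                       g = g, se = se, num = num, den = den),
    loo = loo, no_data = FALSE, bins = bins, jackknife = jackknife
  ), class = "kin_lar")
}

.lar_no_data <- function(bins) {
  structure(list(
    table = data.frame(lag_lo = bins$lag_lo, lag_hi = bins$lag_hi,
                       g = NA_real_, se = NA_real_, num = 0, den = 0),
    loo = NULL, no_data = TRUE, bins = bins, jackknife = "none"
  ), class = "kin_lar")
}

#' @export
print.kin_lar <- function(x, ...) {
  if (x$no_data) cat("Lagged association rate: no data\n")
  else {
    cat("Lagged association rate (", nrow(x$table), " bins, jackknife = ",
        x$jackknife, ")\n", sep = "")
    print(x$table, digits = 3)
  }
  invisible(x)
}

#' Delete-one-group jackknife standard errors
#'
#' Given delete-one estimates g(-k) for n groups, the jackknife standard
#' error is `sqrt(((n - 1) / n) * sum_k (g(-k) - mean(g(-)))^2)`, computed
#' column-wise. Columns with any undefined delete-one estimate yield `NA`.
#'
#' @param loo Matrix of delete-one-group estimates (groups in rows) or a
#'   vector for a single statistic.
#' @return Numeric vector of standard errors, one per column.
#' @export
jackknife_se <- function(loo) {
  if (is.null(dim(loo))) loo <- matrix(loo, ncol = 1)
  n <- nrow(loo)
  if (n < 2) stop("jackknife SE requires at least two groups")
  apply(loo, 2, function(col) {
    if (anyNA(col)) return(NA_real_)
    sqrt(((n - 1) / n) * sum((col - mean(col))^2))
  })
}

#' Library of mother-offspring dyad selectors for stratified lagged rates
#'
#' Builds the strata used to compare bond stability across offspring classes:
#' mother x {adult son, adult daughter, juvenile offspring}, each crossed
#' with the mother's reproductive status (evaluated, like life stage, at the
#' calendar year of the earlier day of each lag pair), plus the
#' mother-offspring pool and its complement. Adulthood uses the sex-specific
#' strict thresholds (female > 12 years, male > 14 years).
#'
#' @param demography Validated demography table.
#' @param repro_rule Rule passed to [reproductive_status()].
#' @return Named list of predicates `function(i, j, year)`.
#' @export
dyad_selector_library <- function(demography, repro_rule = "last_birth") {
  mo_of <- function(i, j) {
    # returns c(mother, offspring) or NULL when not a mother-offspring dyad
    mi <- demography$mother_id[match(i, demography$id)]
    mj <- demography$mother_id[match(j, demography$id)]
    if (!is.na(mj) && mj == i) c(i, j)
    else if (!is.na(mi) && mi == j) c(j, i)
    else NULL
  }
  status <- function(mother, year) {
    alive <- life_stage(demography, mother, year) != "NOT_ALIVE"
    if (!alive) return(NA_character_)
    reproductive_status(demography, mother, year, rule = repro_rule)
  }
  offspring_class <- function(off, year) {
    st <- life_stage(demography, off, year)
    if (st == "NOT_ALIVE") return(NA_character_)
    if (st == "JUVENILE") return("JUVENILE")
    sex <- demography$sex[match(off, demography$id)]
    if (sex == "M") "ADULT_SON" else if (sex == "F") "ADULT_DAUGHTER"
    else "ADULT_UNKNOWN"
  }
  make_sel <- function(class_wanted, status_wanted) {
    force(class_wanted); force(status_wanted)
    function(i, j, year) {
      mo <- mo_of(i, j)
      if (is.null(mo)) return(FALSE)
      cls <- offspring_class(mo[2], year)
      if (is.na(cls) || cls != class_wanted) return(FALSE)
      if (is.null(status_wanted)) return(TRUE)
      st <- status(mo[1], year)
      !is.na(st) && st == status_wanted
    }
  }
  sels <- list(MOTHER_OFFSPRING = function(i, j, year) !is.null(mo_of(i, j)),
               ALL_OTHER_DYADS = function(i, j, year) is.null(mo_of(i, j)))
  for (cls in c("ADULT_SON", "ADULT_DAUGHTER", "JUVENILE")) {
    nm <- if (cls == "JUVENILE") "MOTHER_JUVENILE_OFFSPRING"
          else paste0("MOTHER_", cls)
    sels[[nm]] <- make_sel(cls, NULL)
    for (st in c("REPRODUCTIVE", "POST_REPRODUCTIVE"))
      sels[[paste(nm, st, sep = "_x_")]] <- make_sel(cls, st)
  }
  sels
}
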