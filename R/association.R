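#' Collapse encounters to daily identification and co-encounter sets
#'
#' Association is defined at the day level: two individuals are associated
#' on a day if they were identified in at least one common encounter that
#' day; a day with multiple encounters contributes once per pair. Being
#' identified on the same day in different encounters does not count as
#' association.
#'
#' @param enc A validated (and usually filtered) encounter table.
#' @return A list with two data.frames: `ids` (`day` as `Date`, `id`) giving
#'   one row per (day, identified individual), and `pairs`
#'   (`day`, `i`, `j` with `i < j`) giving one row per (day, co-encountered
#'   unordered pair).
#' @export
daily_identification_sets <- function(enc) {
  if (nrow(enc) == 0) {
    return(list(
      ids = data.frame(day = as.Date(character()), id = character()),
      pairs = data.frame(day = as.Date(character()), i = character(),
                         j = character())
    ))
  }
  n_ids <- lengths(enc$identified)
  ids <- data.frame(
    day = rep(enc$date, n_ids),
    id = unlist(enc$identified, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  ids <- unique(ids)

  with_pairs <- which(n_ids >= 2)
  if (length(with_pairs)) {
    pair_list <- lapply(with_pairs, function(r) {
      p <- utils::combn(sort(enc$identified[[r]]), 2)
      data.frame(day = rep(enc$date[r], ncol(p)), i = p[1, ], j = p[2, ],
                 stringsAsFactors = FALSE)
    })
    pairs <- unique(do.call(rbind, pair_list))
  } else {
    pairs <- data.frame(day = as.Date(character()), i = character(),
                        j = character())
  }
  rownames(ids) <- rownames(pairs) <- NULL
  list(ids = ids, pairs = pairs)
}

#' Annual simple-ratio association indices
#'
#' For every unordered pair of individuals alive in `year` (alive = the year
#' lies within both life-year intervals; the death year itself counts as
#' alive), the simple ratio index is `x / d` where `d` is the number of days
#' in the year on which at least one member of the pair was identified and
#' `x` the number of those days on which the pair shared an encounter.
#' Pairs with `d = 0` (neither member identified all year) carry no
#' information and are omitted.
#'
#' @param enc A validated, filtered encounter table.
#' @param demography A validated demography table.
#' @param year Integer calendar year.
#' @return A `data.frame` with columns `i`, `j` (canonical order `i < j`),
#'   `year`, `x`, `d`, `sri`, one row per pair with `d > 0`.
#' @export
annual_sri <- function(enc, demography, year) {
  year <- as.integer(year)
  alive <- demography$id[demography$birth_year <= year &
                           (is.na(demography$death_year) |
                              demography$death_year >= year)]
  alive <- sort(alive)
  empty <- data.frame(i = character(), j = character(), year = integer(),
                      x = integer(), d = integer(), sri = numeric())
  if (length(alive) < 2) return(empty)

  enc_y <- enc[encounter_year(enc) == year, , drop = FALSE]
  daily <- daily_identification_sets(enc_y)
  ids <- daily$ids[daily$ids$id %in% alive, , drop = FALSE]
  if (nrow(ids) == 0) return(empty)

  seen <- sort(unique(ids$id))
  days <- sort(unique(ids$day))
  # incidence matrix individuals x days of daily identification
  M <- matrix(0L, length(seen), length(days),
              dimnames = list(seen, as.character(days)))
  M[cbind(match(ids$id, seen), match(ids$day, days))] <- 1L
  n_days <- rowSums(M)
  both_days <- tcrossprod(M)   # days both identified (any encounters)

  # joint-encounter day counts per pair
  pairs <- daily$pairs
  pairs <- pairs[pairs$i %in% alive & pairs$j %in% alive, , drop = FALSE]
  x_mat <- matrix(0L, length(seen), length(seen), dimnames = list(seen, seen))
  if (nrow(pairs)) {
    tab <- table(paste(pairs$i, pairs$j, sep = "\r"))
    ij <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    x_mat[cbind(match(ij[, 1], seen), match(ij[, 2], seen))] <- as.integer(tab)
  }

  # pairs among seen individuals
  if (length(seen) >= 2) {
    pr <- utils::combn(seq_along(seen), 2)
    a <- pr[1, ]; b <- pr[2, ]
    d_seen <- n_days[a] + n_days[b] - both_days[cbind(a, b)]
    res_seen <- data.frame(i = seen[a], j = seen[b], year = year,
                           x = x_mat[cbind(a, b)], d = as.integer(d_seen),
                           stringsAsFactors = FALSE)
  } else {
    res_seen <- NULL
  }

  # pairs of one seen and one alive-but-unseen individual: x = 0, d = days(seen)
  unseen <- setdiff(alive, seen)
  if (length(unseen)) {
    g <- expand.grid(s = seen, u = unseen, stringsAsFactors = FALSE)
    ii <- pmin(g$s, g$u); jj <- pmax(g$s, g$u)
    res_mix <- data.frame(i = ii, j = jj, year = year, x = 0L,
                          d = as.integer(n_days[g$s]),
                          stringsAsFactors = FALSE)
  } else {
    res_mix <- NULL
  }
  out <- rbind(res_seen, res_mix)
  out <- out[out$d > 0, , drop = FALSE]
  out$sri <- out$x / out$d
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annual SRI over a range of years
#'
#' @param enc,demography As in [annual_sri()].
#' @param years Integer vector of calendar years.
#' @return Row-bound annual SRI tables.
#' @export
annual_sri_range <- function(enc, demography, years) {
  do.call(rbind, lapply(years, function(y) annual_sri(enc, demography, y)))
}
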