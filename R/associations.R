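# Time spent in proximity bins, closest / least frequent associates, and
# affiliation strata summaries.

# default bin upper edges in cm: <=3 m, (3,6], (6,9], (9,12] m
.default_bins <- c(300, 600, 900, 1200)

.bin_labels <- function(edges) {
  lab <- sprintf("<=%gm", edges[1] / 100)
  if (length(edges) > 1) {
    lab <- c(lab, sprintf("(%g,%g]m", edges[-length(edges)] / 100,
                          edges[-1] / 100))
  }
  c(lab, sprintf(">%gm", edges[length(edges)] / 100))
}

#' Fraction of time spent in each proximity bin
#'
#' Counts the retained samples falling in each distance bin and divides by
#' the dyad's total retained samples (1 Hz, so 1 sample = 1 s). The first
#' bin is closed (`<= 3 m`, so a reading of exactly 300 cm counts as close
#' proximity); later bins are half-open; the remainder beyond the last edge
#' is reported as an explicit `> 12 m` bin so all fractions sum to 1.
#'
#' @param d numeric distances (cm) of the dyad's retained samples, or a
#'   [distance_series()].
#' @param bins upper bin edges in cm.
#' @return named numeric vector of fractions (sums to 1), or all-`NA` with a
#'   warning for an empty series.
#' @export
time_in_bins <- function(d, bins = .default_bins) {
  if (inherits(d, "distance_series")) d <- d$d
  labs <- .bin_labels(bins)
  if (!length(d)) {
    warning("dyad has zero retained samples; fractions undefined")
    return(stats::setNames(rep(NA_real_, length(labs)), labs))
  }
  counts <- tabulate(findInterval(d, bins, left.open = TRUE) + 1L,
                     nbins = length(bins) + 1L)
  stats::setNames(counts / length(d), labs)
}

#' Build the association structure of a group
#'
#' For every dyad: per-bin fraction of time and median distance; stored as
#' symmetric animal x animal matrices.
#'
#' @param series_list named list of [distance_series()] (one per dyad).
#' @param roster character vector of animal ids (matrix order).
#' @param bins upper bin edges in cm.
#' @return object of class `association_matrix`: list with `fractions`
#'   (3-d array animal x animal x bin), `median_cm` (matrix), `roster`,
#'   `bins`.
#' @export
association_matrix <- function(series_list, roster, bins = .default_bins) {
  n <- length(roster)
  labs <- .bin_labels(bins)
  fr <- array(NA_real_, dim = c(n, n, length(labs)),
              dimnames = list(roster, roster, labs))
  med <- matrix(NA_real_, n, n, dimnames = list(roster, roster))
  for (s in series_list) {
    i <- match(s$dyad[1], roster); j <- match(s$dyad[2], roster)
    if (is.na(i) || is.na(j)) next
    if (!length(s$d)) next
    f <- time_in_bins(s$d, bins)
    fr[i, j, ] <- f; fr[j, i, ] <- f
    med[i, j] <- med[j, i] <- stats::median(s$d)
  }
  structure(list(fractions = fr, median_cm = med, roster = roster,
                 bins = bins), class = "association_matrix")
}

# proximity (first-bin) fractions of `animal` against all partners
.close_fracs <- function(assoc, animal) {
  i <- match(animal, assoc$roster)
  stop_if(is.na(i), sprintf("unknown animal %s", animal))
  f <- assoc$fractions[i, , 1]
  f[assoc$roster != animal]
}

# shared argbest logic for closest / least frequent associate
.pick_associate <- function(assoc, animal, decreasing) {
  f <- .close_fracs(assoc, animal)
  f <- f[!is.na(f)]
  stop_if(length(f) == 0, sprintf("no partner with defined fraction for %s",
                                  animal))
  best <- if (decreasing) max(f) else min(f)
  cand <- names(f)[f == best]
  if (length(cand) > 1) {
    i <- match(animal, assoc$roster)
    meds <- assoc$median_cm[i, cand]
    cand <- cand[order(meds, cand)]  # smaller median, then lexicographic
  }
  cand[1]
}

#' Closest associate of an animal
#'
#' The partner with whom the focal animal spent the largest fraction of time
#' within the close-proximity bin (<= 3 m). Ties are broken by the smaller
#' median dyad distance, then lexicographically by id.
#'
#' @param assoc an [association_matrix()].
#' @param animal focal animal id.
#' @return partner id.
#' @export
closest_associate <- function(assoc, animal) {
  .pick_associate(assoc, animal, decreasing = TRUE)
}

#' Least frequent associate of an animal
#'
#' The partner with the smallest close-proximity fraction; ties broken as in
#' [closest_associate()].
#'
#' @inheritParams closest_associate
#' @return partner id.
#' @export
least_frequent_associate <- function(assoc, animal) {
  .pick_associate(assoc, animal, decreasing = FALSE)
}

#' Associate table for a condition
#'
#' @param assoc an [association_matrix()].
#' @param condition label carried into the output.
#' @return data.frame with one row per animal: closest and least frequent
#'   associate and their close-proximity fractions.
#' @export
associate_table <- function(assoc, condition = "paddock") {
  rows <- lapply(assoc$roster, function(an) {
    f <- .close_fracs(assoc, an)
    if (all(is.na(f))) return(NULL)
    ca <- closest_associate(assoc, an)
    la <- least_frequent_associate(assoc, an)
    data.frame(animal = an, condition = condition, closest = ca,
               closest_frac = unname(f[ca]), least_frequent = la,
               least_frequent_frac = unname(f[la]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Affiliation-stratum summaries
#'
#' Splits every animal's dyads into three strata — its closest associate,
#' its least frequent associate, and the group overall — and summarises
#' median distance and close-proximity fraction per stratum, the structure
#' behind affiliation-level comparisons between conditions.
#'
#' @param assoc an [association_matrix()].
#' @param condition label carried into the output.
#' @return data.frame: animal, condition, stratum (`closest` / `overall` /
#'   `least_frequent`), partner (NA for overall), median_cm,
#'   close_frac.
#' @export
affiliation_strata <- function(assoc, condition = "paddock") {
  rows <- lapply(assoc$roster, function(an) {
    i <- match(an, assoc$roster)
    f <- .close_fracs(assoc, an)
    if (all(is.na(f))) return(NULL)
    ca <- closest_associate(assoc, an)
    la <- least_frequent_associate(assoc, an)
    meds <- assoc$median_cm[i, ]
    data.frame(
      animal = an, condition = condition,
      stratum = c("closest", "overall", "least_frequent"),
      partner = c(ca, NA_character_, la),
      median_cm = c(assoc$median_cm[i, ca],
                    stats::median(meds[assoc$roster != an], na.rm = TRUE),
                    assoc$median_cm[i, la]),
      close_frac = c(unname(f[ca]), stats::median(f, na.rm = TRUE),
                     unname(f[la])),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
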