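# Absolute and relative interindividual distance statistics per dyad and
# per group/condition.

#' Space available per horse
#'
#' Enclosure surface divided by the number of animals present, the
#' denominator of the relative interindividual distance.
#'
#' @param area_m2 enclosure surface (m^2).
#' @param n_horses number of animals (>= 1).
#' @param digits decimals for half-up rounding at the reporting layer; use
#'   `NULL` for full precision.
#' @return space per horse in m^2.
#' @export
#' @examples
#' space_per_horse(450, 8)   # 56.25
space_per_horse <- function(area_m2, n_horses, digits = 2) {
  stop_if(any(n_horses < 1), "n_horses must be >= 1")
  out <- area_m2 / n_horses
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Median with bootstrap confidence interval
#'
#' Sample median and a seeded percentile-bootstrap 95% confidence interval.
#'
#' @param x numeric sample (cm), length >= 1.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed for the resampling.
#' @param conf confidence level.
#' @return list with `median`, `ci` (length-2 lo/hi), `n`.
#' @export
median_with_ci <- function(x, n_boot = 1000, seed = 1L, conf = 0.95) {
  x <- x[!is.na(x)]
  stop_if(length(x) == 0, "empty sample")
  med <- stats::median(x)
  if (length(x) == 1) {
    return(list(median = med, ci = c(med, med), n = 1L))
  }
  boots <- with_seed(seed, {
    m <- matrix(sample(x, length(x) * n_boot, replace = TRUE),
                nrow = n_boot)
    apply(m, 1, stats::median)
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  list(median = med, ci = ci, n = length(x))
}

#' Relative interindividual distance
#'
#' Median absolute interindividual distance (cm) divided by the space
#' available per horse (m^2), in cm/m^2. Low absolute but high relative
#' distance indicates forced proximity; low absolute and low relative
#' distance indicates voluntary proximity.
#'
#' @param median_cm median absolute distance (cm).
#' @param space_m2_per_horse space per horse (m^2), > 0.
#' @param digits decimals for half-up rounding; `NULL` for full precision.
#' @return relative distance in cm/m^2.
#' @export
#' @examples
#' relative_distance(2153, 515.21)  # 4.18
relative_distance <- function(median_cm, space_m2_per_horse, digits = 2) {
  stop_if(any(space_m2_per_horse <= 0), "space per horse must be positive")
  out <- median_cm / space_m2_per_horse
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Per-dyad and pooled distance summary for one condition
#'
#' Computes, for every dyad series, the median distance with bootstrap CI
#' and the relative distance, then pools at group level over the per-dyad
#' medians (each dyad contributes one value, so dyads with more retained
#' samples do not dominate).
#'
#' Two pathways for the pooled relative distance are reported:
#' `"per_dyad"` (the median of the per-dyad relative distances, the
#' default) and `"pooled_ratio"` (pooled median divided by space per
#' horse); the chosen pathway is flagged in the output.
#'
#' @param series_list named list of [distance_series()].
#' @param enclosure an [enclosure_config()].
#' @param condition label, e.g. `"paddock"` or `"field"`.
#' @param n_boot,seed bootstrap parameters passed to [median_with_ci()].
#' @param relative_method pooled relative-distance pathway (see above).
#' @return list with `dyads` (data.frame: dyad, condition, n_samples,
#'   median_cm, ci_lo, ci_hi, relative_cm_m2) and `pooled` (one-row
#'   data.frame with pooled median, CI, relative distance and the pathway
#'   flag). All values full precision; round at the reporting layer.
#' @export
group_summary <- function(series_list, enclosure, condition = "paddock",
                          n_boot = 1000, seed = 1L,
                          relative_method = c("per_dyad", "pooled_ratio")) {
  relative_method <- match.arg(relative_method)
  stop_if(length(series_list) == 0, "need at least one dyad series")
  space <- space_per_horse(enclosure$area_m2, enclosure$n_horses, digits = NULL)
  rows <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    if (!length(s$t)) return(NULL)
    mc <- median_with_ci(s$d, n_boot = n_boot, seed = seed + i)
    data.frame(dyad = paste(s$dyad, collapse = "|"), condition = condition,
               n_samples = mc$n, median_cm = mc$median,
               ci_lo = mc$ci[1], ci_hi = mc$ci[2],
               relative_cm_m2 = relative_distance(mc$median, space,
                                                  digits = NULL),
               stringsAsFactors = FALSE)
  })
  dyads <- do.call(rbind, rows)
  stop_if(is.null(dyads) || !nrow(dyads), "no dyad has retained samples")
  pooled_mc <- median_with_ci(dyads$median_cm, n_boot = n_boot, seed = seed)
  pooled_rel <- if (relative_method == "per_dyad") {
    stats::median(dyads$relative_cm_m2)
  } else {
    relative_distance(pooled_mc$median, space, digits = NULL)
  }
  rel_mc <- median_with_ci(dyads$relative_cm_m2, n_boot = n_boot,
                           seed = seed + 1L)
  pooled <- data.frame(
    condition = condition, n_dyads = nrow(dyads),
    median_cm = pooled_mc$median, ci_lo = pooled_mc$ci[1],
    ci_hi = pooled_mc$ci[2], relative_cm_m2 = pooled_rel,
    rel_ci_lo = rel_mc$ci[1], rel_ci_hi = rel_mc$ci[2],
    space_m2_per_horse = space, relative_method = relative_method,
    stringsAsFactors = FALSE)
  list(dyads = dyads, pooled = pooled)
}
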