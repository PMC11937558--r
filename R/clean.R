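# Ingest and clean raw UWB distance channels: range filter (enclosure
# diagonal / 5 cm floor), frozen-run filter, feeder-proximity exclusion,
# then technical-replicate averaging into one series per unordered dyad.

#' Enclosure / group configuration
#'
#' Geometry and roster of one turn-out condition. The maximum theoretically
#' possible interindividual distance is the enclosure diagonal,
#' `100 * sqrt(length^2 + width^2)` cm.
#'
#' @param length_m,width_m enclosure dimensions in m.
#' @param n_horses number of animals present (>= 2).
#' @param tracking_hours total tracking duration (h).
#' @param area_m2 enclosure surface; defaults to `length_m * width_m` but can
#'   be overridden when the reported surface differs from the bounding
#'   rectangle.
#' @param feeder_channel optional id of the feeder sensor channel.
#' @return an object of class `enclosure_config`.
#' @export
enclosure_config <- function(length_m, width_m, n_horses, tracking_hours,
                             area_m2 = length_m * width_m,
                             feeder_channel = NULL) {
  stop_if(length_m <= 0 || width_m <= 0, "enclosure dimensions must be positive")
  stop_if(area_m2 <= 0, "area_m2 must be positive")
  stop_if(n_horses < 2, "n_horses must be >= 2")
  stop_if(tracking_hours <= 0, "tracking_hours must be positive")
  structure(list(length_m = length_m, width_m = width_m, area_m2 = area_m2,
                 n_horses = as.integer(n_horses),
                 tracking_hours = tracking_hours,
                 feeder_channel = feeder_channel),
            class = "enclosure_config")
}

#' Maximum theoretical interindividual distance
#'
#' @param enclosure an [enclosure_config()].
#' @return the enclosure diagonal in cm.
#' @export
max_theoretical_cm <- function(enclosure) {
  100 * sqrt(enclosure$length_m^2 + enclosure$width_m^2)
}

#' Load a raw long-format distance CSV
#'
#' Reads `timestamp,sensor_a,sensor_b,distance_cm` rows, parses ISO-8601 (or
#' plain numeric) timestamps to epoch seconds, drops malformed rows and rows
#' whose ids fall outside the roster, and reports the rejection counts.
#'
#' @param path CSV file path.
#' @param roster character vector of valid animal ids; feeder channels are
#'   kept when their id is listed here or passed as `feeder_id`.
#' @param feeder_id id of the feeder channel, kept in addition to the roster.
#' @return list with `data` (data.frame `t`, `a`, `b`, `d`) and `rejected`
#'   (named counts: `malformed`, `unknown_id`).
#' @export
load_distance_csv <- function(path, roster, feeder_id = "FEEDER") {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(nrow(raw) == 0, "empty distance file")
  need <- c("timestamp", "sensor_a", "sensor_b", "distance_cm")
  stop_if(!all(need %in% names(raw)),
          sprintf("missing columns: %s",
                  paste(setdiff(need, names(raw)), collapse = ", ")))
  ts <- suppressWarnings(as.numeric(raw$timestamp))
  iso <- is.na(ts)
  if (any(iso)) {
    cand <- rep(NA_real_, sum(iso))
    for (fmt in c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                  "%Y-%m-%d %H:%M:%OS")) {
      miss <- is.na(cand)
      if (!any(miss)) break
      cand[miss] <- as.numeric(strptime(raw$timestamp[iso][miss], fmt,
                                        tz = "UTC"))
    }
    ts[iso] <- cand
  }
  d <- suppressWarnings(as.numeric(raw$distance_cm))
  malformed <- is.na(ts) | is.na(d) | !nzchar(raw$sensor_a) | !nzchar(raw$sensor_b)
  ok_ids <- c(roster, feeder_id)
  unknown <- !malformed & (!(raw$sensor_a %in% ok_ids) | !(raw$sensor_b %in% ok_ids))
  keep <- !malformed & !unknown
  list(data = data.frame(t = ts[keep], a = raw$sensor_a[keep],
                         b = raw$sensor_b[keep], d = d[keep],
                         stringsAsFactors = FALSE),
       rejected = c(malformed = sum(malformed), unknown_id = sum(unknown)))
}

# collapse duplicate timestamps within one channel by their mean, sort by t
collapse_duplicates <- function(ch) {
  if (!nrow(ch)) return(ch[, c("t", "d")])
  agg <- tapply(ch$d, ch$t, mean)
  data.frame(t = as.numeric(names(agg)), d = as.numeric(agg))
}

#' Range filter: enclosure diagonal and 5 cm floor
#'
#' Removes samples above the maximum theoretical distance (the enclosure
#' diagonal) or below 5 cm, which is impossible given sensor placement.
#'
#' @param series data.frame with columns `t`, `d` (one sensor channel).
#' @param enclosure an [enclosure_config()].
#' @param min_cm lower plausibility bound (cm).
#' @return the filtered data.frame; the number of removed samples is in
#'   `attr(, "removed")`.
#' @export
filter_range <- function(series, enclosure, min_cm = 5) {
  lim <- max_theoretical_cm(enclosure)
  keep <- series$d <= lim & series$d >= min_cm
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  out
}

#' Frozen-run filter
#'
#' Removes, in full, every maximal run of bit-identical consecutive values
#' longer than `window_s` samples (at 1 Hz, "no variation for over 10 s").
#' Runs of exactly `window_s` identical samples survive.
#'
#' @param series data.frame with columns `t`, `d`.
#' @param window_s run-length threshold in seconds (strictly-greater rule).
#' @return filtered data.frame with removal count in `attr(, "removed")`.
#' @export
filter_frozen <- function(series, window_s = 10) {
  if (!nrow(series)) {
    attr(series, "removed") <- 0L
    return(series)
  }
  r <- rle(series$d)
  drop_run <- r$lengths > window_s
  keep <- rep(!drop_run, r$lengths)
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  out
}

#' Feeder-proximity filter
#'
#' Removes samples where *both* animals of the dyad are within `radius_cm`
#' of the hay feeder, eliminating forced proximity around the feeder.
#' Samples where only one animal is near the feeder are retained. Each
#' animal's feeder distance is taken from its feeder channel's nearest
#' sample within +/- 1 s; samples with no concurrent feeder reading are
#' retained.
#'
#' @param series data.frame with columns `t`, `d` (dyad channel).
#' @param feeder_a,feeder_b data.frames `t`, `d` with each animal's distance
#'   to the feeder; pass `NULL` when no feeder channel exists (the series is
#'   returned unchanged with a warning).
#' @param radius_cm feeder-proximity radius (cm).
#' @return filtered data.frame with removal count in `attr(, "removed")`.
#' @export
filter_feeder <- function(series, feeder_a, feeder_b, radius_cm = 300) {
  if (is.null(feeder_a) || is.null(feeder_b)) {
    warning("no feeder channel available; feeder filter skipped")
    attr(series, "removed") <- 0L
    return(series)
  }
  near <- function(feed) {
    if (!nrow(feed)) return(rep(FALSE, nrow(series)))
    idx <- findInterval(series$t, feed$t)
    cand_lo <- pmax(idx, 1L)
    cand_hi <- pmin(idx + 1L, nrow(feed))
    d_lo <- abs(feed$t[cand_lo] - series$t)
    d_hi <- abs(feed$t[cand_hi] - series$t)
    best <- ifelse(d_hi < d_lo, cand_hi, cand_lo)
    best_dt <- pmin(d_lo, d_hi)
    best_dt <= 1 & feed$d[best] <= radius_cm
  }
  both_near <- near(feeder_a) & near(feeder_b)
  out <- series[!both_near, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(both_near)
  out
}

#' Average the two technical-replicate channels of a dyad
#'
#' The A->B and B->A channels measure the same distance; after cleaning they
#' are averaged per timestamp. Timestamps present in only one channel are
#' retained with that channel's value.
#'
#' @param channel_ab,channel_ba data.frames `t`, `d` (cleaned channels).
#' @param a,b animal ids of the dyad.
#' @param provenance optional named removal counts carried into the result.
#' @return a [distance_series()].
#' @export
average_replicates <- function(channel_ab, channel_ba, a = "A", b = "B",
                               provenance = integer(0)) {
  all_t <- sort(unique(c(channel_ab$t, channel_ba$t)))
  v1 <- channel_ab$d[match(all_t, channel_ab$t)]
  v2 <- channel_ba$d[match(all_t, channel_ba$t)]
  d <- rowMeans(cbind(v1, v2), na.rm = TRUE)
  keep <- !is.nan(d)
  distance_series(a, b, all_t[keep], d[keep], provenance = provenance)
}

#' Clean a raw distance table into per-dyad series
#'
#' Full cleaning pipeline, applied per directed channel in the order
#' range -> frozen -> feeder, followed by technical-replicate averaging into
#' one [distance_series()] per unordered dyad. Frozen-run detection happens
#' on the raw channels, before averaging, because a stuck value is a
#' per-sensor-pair failure. Duplicate timestamps within a channel are
#' collapsed by their mean before any filter.
#'
#' @param raw data.frame `t`, `a`, `b`, `d` (epoch s, ids, cm), e.g. from
#'   [load_distance_csv()] or [trajectories_to_distances()].
#' @param enclosure an [enclosure_config()].
#' @param feeder_id id of the feeder channel in `raw` (rows with
#'   `b == feeder_id` are used by the feeder filter and excluded from dyads).
#' @param min_cm,frozen_s,feeder_cm filter thresholds.
#' @return list with `series` (named list of [distance_series()], keys
#'   `"A|B"`) and `report` (per-dyad data.frame of sample counts removed by
#'   each filter and kept).
#' @export
clean_distances <- function(raw, enclosure, feeder_id = "FEEDER",
                            min_cm = 5, frozen_s = 10, feeder_cm = 300) {
  is_feed <- raw$a == feeder_id | raw$b == feeder_id
  feed_raw <- raw[is_feed, , drop = FALSE]
  dyad_raw <- raw[!is_feed, , drop = FALSE]
  feeder_of <- function(id) {
    ch <- feed_raw[feed_raw$a == id | feed_raw$b == id, , drop = FALSE]
    if (!nrow(ch)) return(NULL)
    collapse_duplicates(ch)
  }
  have_feeder <- nrow(feed_raw) > 0

  keys <- dyad_key(dyad_raw$a, dyad_raw$b)
  out <- list()
  rep_rows <- list()
  for (k in sort(unique(keys))) {
    sub <- dyad_raw[keys == k, , drop = FALSE]
    ab_name <- paste(sub$a, sub$b, sep = "->")
    chans <- split(sub[, c("t", "d")], ab_name)
    ids <- split_dyad(k)[1, ]
    n_raw <- 0L; n_range <- 0L; n_frozen <- 0L; n_feeder <- 0L
    fa <- if (have_feeder) feeder_of(ids[1]) else NULL
    fb <- if (have_feeder) feeder_of(ids[2]) else NULL
    cleaned <- lapply(chans, function(ch) {
      ch <- collapse_duplicates(ch)
      n_raw <<- n_raw + nrow(ch)
      ch <- filter_range(ch, enclosure, min_cm = min_cm)
      n_range <<- n_range + attr(ch, "removed")
      ch <- filter_frozen(ch, window_s = frozen_s)
      n_frozen <<- n_frozen + attr(ch, "removed")
      if (have_feeder && !is.null(fa) && !is.null(fb)) {
        ch <- filter_feeder(ch, fa, fb, radius_cm = feeder_cm)
        n_feeder <<- n_feeder + attr(ch, "removed")
      }
      ch
    })
    ab <- cleaned[[1]]
    ba <- if (length(cleaned) > 1) cleaned[[2]] else cleaned[[1]][0, ]
    prov <- c(raw = n_raw, range = n_range, frozen = n_frozen,
              feeder = n_feeder)
    ser <- average_replicates(ab, ba, a = ids[1], b = ids[2],
                              provenance = prov)
    out[[k]] <- ser
    rep_rows[[k]] <- data.frame(
      dyad = k, raw = n_raw, removed_range = n_range,
      removed_frozen = n_frozen, removed_feeder = n_feeder,
      kept_channel = n_raw - n_range - n_frozen - n_feeder,
      kept_averaged = length(ser$t), stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  list(series = out, report = report)
}

#' Rebuild per-dyad series from a cleaned long table
#'
#' Inverse of flattening a list of [distance_series()] to a long data.frame
#' (`t`, `a`, `b`, `d`): groups rows by unordered dyad. Used to re-load
#' stage intermediates written as CSV.
#'
#' @param df data.frame with columns `t`, `a`, `b`, `d`.
#' @return named list of [distance_series()], keys `"A|B"`.
#' @export
series_from_table <- function(df) {
  keys <- dyad_key(df$a, df$b)
  out <- lapply(sort(unique(keys)), function(k) {
    sub <- df[keys == k, ]
    ids <- split_dyad(k)[1, ]
    distance_series(ids[1], ids[2], sub$t, sub$d)
  })
  stats::setNames(out, sort(unique(keys)))
}

#' Flatten per-dyad series to a long table
#'
#' @param series_list named list of [distance_series()].
#' @return data.frame with columns `t`, `a`, `b`, `d`.
#' @export
series_to_table <- function(series_list) {
  do.call(rbind, lapply(series_list, function(s) {
    if (!length(s$t)) return(NULL)
    data.frame(t = s$t, a = s$dyad[1], b = s$dyad[2], d = s$d,
               stringsAsFactors = FALSE)
  }))
}
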