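# Rule-based detection of agonistic approaches and high/low-intensity
# retreats from dyadic distance series, plus event rates and speed
# conversions.
#
# Approach criteria: a decrease of at least `min_drop_cm` to a distance
# below `end_below_cm` within `window_s` seconds, mean closing speed of at
# least `min_speed_cm_s`, exactly two animals involved, and consistent
# direction of movement (monotone distance change within a small jitter
# tolerance). Retreats are rises of at least `min_drop_cm` within
# `window_s` starting within `retreat_lag_s` of a detected approach; the
# high-intensity class additionally requires the speed floor.

default_event_thresholds <- function() {
  list(min_drop_cm = 100, end_below_cm = 200, window_s = 3,
       min_speed_cm_s = 85, max_speed_cm_s = 800, retreat_lag_s = 3,
       direction_tol_cm = 1)
}

#' Per-step signed speed of a distance series
#'
#' `speed = (d[n] - d[n-1]) / (t[n] - t[n-1])` across consecutive retained
#' samples (so a 5 s gap gives a 5 s denominator). Steps faster than
#' `max_speed_cm_s` in absolute value are physically impossible and flagged
#' as measurement errors; the later sample of a flagged step is excluded
#' from all event logic.
#'
#' @param series a [distance_series()] or data.frame `t`, `d`.
#' @param max_speed_cm_s error threshold (cm/s).
#' @return data.frame: `t` (of the later sample), `dt`, `v` (cm/s),
#'   `flagged`.
#' @export
compute_speeds <- function(series, max_speed_cm_s = 800) {
  t <- series$t; d <- series$d
  if (length(t) < 2) {
    return(data.frame(t = numeric(0), dt = numeric(0), v = numeric(0),
                      flagged = logical(0)))
  }
  dt <- diff(t); v <- diff(d) / dt
  data.frame(t = t[-1], dt = dt, v = v, flagged = abs(v) > max_speed_cm_s)
}

# per-series window scan shared by approach and retreat detection.
# direction = -1 scans for decreases, +1 for increases. Returns qualifying
# windows as a data.frame of sample indices and times.
.scan_windows <- function(t, d, direction, thr, enforce_end_below,
                          enforce_speed) {
  n <- length(t)
  if (n < 2) return(NULL)
  dt <- diff(t)
  v <- diff(d) / dt
  samp_ok <- c(TRUE, abs(v) <= thr$max_speed_cm_s)  # later sample of a fast step
  step_contig <- dt == 1
  # consistent direction: every step moves the right way within tolerance
  step_mono <- if (direction < 0) diff(d) <= thr$direction_tol_cm else
    diff(d) >= -thr$direction_tol_cm
  bad_step <- !(step_contig & step_mono & samp_ok[-1])
  cum_bad <- c(0, cumsum(bad_step))
  out <- list()
  for (L in seq_len(thr$window_s)) {
    i <- seq_len(n - L)
    j <- i + L
    ok <- samp_ok[i] & (cum_bad[j] - cum_bad[i]) == 0
    delta <- direction * (d[j] - d[i])
    ok <- ok & delta >= thr$min_drop_cm
    if (enforce_end_below) ok <- ok & d[j] < thr$end_below_cm
    if (enforce_speed) ok <- ok & delta / (t[j] - t[i]) >= thr$min_speed_cm_s
    if (any(ok)) {
      out[[L]] <- data.frame(i = i[ok], j = j[ok], t_start = t[i[ok]],
                             t_end = t[j[ok]])
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# merge overlapping windows into events (earliest start, latest end)
.merge_windows <- function(w, t, d) {
  w <- w[order(w$t_start, w$t_end), , drop = FALSE]
  groups <- integer(nrow(w)); g <- 1L; cur_end <- w$t_end[1]; groups[1] <- g
  for (k in seq_len(nrow(w))[-1]) {
    if (w$t_start[k] <= cur_end) {
      groups[k] <- g
      cur_end <- max(cur_end, w$t_end[k])
    } else {
      g <- g + 1L; groups[k] <- g; cur_end <- w$t_end[k]
    }
  }
  do.call(rbind, lapply(split(w, groups), function(grp) {
    i0 <- min(grp$i); j1 <- max(grp$j)
    data.frame(t_start = t[i0], t_end = t[j1],
               displacement_cm = d[j1] - d[i0],
               mean_speed_cm_s = abs(d[j1] - d[i0]) / (t[j1] - t[i0]))
  }))
}

#' Detect agonistic approaches across all dyads of a group
#'
#' Scans every dyad's cleaned series with sliding windows of up to
#' `window_s` seconds over contiguous 1 Hz samples (events never span a
#' cleaning gap or a flagged-speed sample), merges overlapping qualifying
#' windows into one event, and enforces the two-animals-only criterion by
#' discarding any pair of concurrent events that share an animal.
#'
#' @param series_list named list of [distance_series()] covering the group.
#' @param thresholds threshold list, see `default_event_thresholds()`.
#' @param speed_rule `"window"` applies the 85 cm/s floor to the window-mean
#'   closing speed (default); `"step"` requires every step to meet it.
#' @return data.frame of approach events: `event_id`, `kind`, `a`, `b`,
#'   `t_start`, `t_end`, `displacement_cm`, `mean_speed_cm_s`.
#' @export
detect_approaches <- function(series_list, thresholds = list(),
                              speed_rule = c("window", "step")) {
  speed_rule <- match.arg(speed_rule)
  thr <- utils::modifyList(default_event_thresholds(), thresholds)
  evs <- list()
  for (s in series_list) {
    t <- s$t; d <- s$d
    if (speed_rule == "step") {
      # per-step floor: on contiguous 1 Hz steps, every step must itself
      # drop by at least the speed floor, which the direction constraint
      # can express directly
      thr_step <- thr
      thr_step$direction_tol_cm <- -thr$min_speed_cm_s
      w <- .scan_windows(t, d, -1, thr_step, TRUE, TRUE)
    } else {
      w <- .scan_windows(t, d, -1, thr, TRUE, TRUE)
    }
    if (is.null(w)) next
    m <- .merge_windows(w, t, d)
    m$a <- s$dyad[1]; m$b <- s$dyad[2]
    evs[[length(evs) + 1]] <- m
  }
  empty <- data.frame(event_id = integer(0), kind = character(0),
                      a = character(0), b = character(0),
                      t_start = numeric(0), t_end = numeric(0),
                      displacement_cm = numeric(0),
                      mean_speed_cm_s = numeric(0))
  if (!length(evs)) return(empty)
  ev <- do.call(rbind, evs)
  # two-animals-only: concurrent events sharing an animal void each other
  n_ev <- nrow(ev)
  drop <- rep(FALSE, n_ev)
  if (n_ev > 1) {
    for (p in seq_len(n_ev - 1)) {
      for (q in seq(p + 1, n_ev)) {
        share <- length(intersect(c(ev$a[p], ev$b[p]),
                                  c(ev$a[q], ev$b[q]))) > 0
        same_dyad <- ev$a[p] == ev$a[q] && ev$b[p] == ev$b[q]
        overlap <- ev$t_start[p] <= ev$t_end[q] && ev$t_start[q] <= ev$t_end[p]
        if (share && !same_dyad && overlap) drop[p] <- drop[q] <- TRUE
      }
    }
  }
  ev <- ev[!drop, , drop = FALSE]
  if (!nrow(ev)) return(empty)
  ev <- ev[order(ev$t_start, ev$a, ev$b), , drop = FALSE]
  ev$kind <- "approach"
  ev$event_id <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  ev[, names(empty)]
}

#' Detect retreats following approaches
#'
#' For each approach, scans for rise windows (>= `min_drop_cm` increase
#' within `window_s`, consistent direction) beginning within
#' `retreat_lag_s` seconds of the approach end. The earliest qualifying
#' window is linked; it is classified `high_retreat` when its mean speed
#' meets the `min_speed_cm_s` floor and `low_retreat` otherwise (a
#' high-speed retreat is never double-counted as low). At most one retreat
#' is linked per approach.
#'
#' @param approaches output of [detect_approaches()].
#' @param series_list named list of [distance_series()].
#' @param thresholds threshold list, see `default_event_thresholds()`.
#' @return data.frame of retreat events with `linked_id` referencing the
#'   approach `event_id`.
#' @export
detect_retreats <- function(approaches, series_list, thresholds = list()) {
  thr <- utils::modifyList(default_event_thresholds(), thresholds)
  keys <- vapply(series_list, function(s) paste(s$dyad, collapse = "|"), "")
  empty <- data.frame(event_id = integer(0), kind = character(0),
                      a = character(0), b = character(0),
                      t_start = numeric(0), t_end = numeric(0),
                      displacement_cm = numeric(0),
                      mean_speed_cm_s = numeric(0), linked_id = integer(0))
  if (!nrow(approaches)) return(empty)
  out <- list()
  for (k in seq_len(nrow(approaches))) {
    ap <- approaches[k, ]
    s <- series_list[[which(keys == dyad_key(ap$a, ap$b))[1]]]
    w <- .scan_windows(s$t, s$d, +1, thr, FALSE, FALSE)
    if (is.null(w)) next
    w <- w[w$t_start >= ap$t_end & w$t_start <= ap$t_end + thr$retreat_lag_s,
           , drop = FALSE]
    if (!nrow(w)) next
    # earliest qualifying start; there, the fastest (then longest) window,
    # so a fast flight is classified by its fast leg rather than diluted by
    # a slow tail
    w$rise <- s$d[w$j] - s$d[w$i]
    w$spd <- w$rise / (w$t_end - w$t_start)
    w <- w[order(w$t_start, -w$spd, -w$rise), , drop = FALSE][1, ]
    rise <- w$rise
    spd <- w$spd
    out[[length(out) + 1]] <- data.frame(
      kind = if (spd >= thr$min_speed_cm_s) "high_retreat" else "low_retreat",
      a = ap$a, b = ap$b, t_start = w$t_start, t_end = w$t_end,
      displacement_cm = rise, mean_speed_cm_s = spd, linked_id = ap$event_id,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  ret <- do.call(rbind, out)
  ret$event_id <- max(approaches$event_id) + seq_len(nrow(ret))
  rownames(ret) <- NULL
  ret[, names(empty)]
}

#' Detect all agonistic events of a group
#'
#' Convenience wrapper: approaches, then linked retreats, as one event log.
#'
#' @inheritParams detect_approaches
#' @return data.frame with approaches and retreats (`linked_id` is `NA` for
#'   approaches).
#' @export
detect_agonistic_events <- function(series_list, thresholds = list(),
                                    speed_rule = c("window", "step")) {
  ap <- detect_approaches(series_list, thresholds, speed_rule)
  rt <- detect_retreats(ap, series_list, thresholds)
  ap$linked_id <- rep(NA_integer_, nrow(ap))
  rbind(ap, rt)
}

#' Agonistic event rate
#'
#' `rate = n_events / (n_horses * tracking_hours)`: events per horse per
#' hour. With `n_horses = 1` this is the pooled per-group-hour rate.
#'
#' @param n_events event count.
#' @param n_horses number of animals in the group.
#' @param tracking_hours tracking duration (h), > 0.
#' @param digits decimals for half-up rounding; `NULL` for full precision.
#' @return event rate.
#' @export
#' @examples
#' event_rate(9151, 1, 406)  # 22.54 events per group-hour
event_rate <- function(n_events, n_horses, tracking_hours, digits = 2) {
  stop_if(any(tracking_hours <= 0), "tracking_hours must be positive")
  stop_if(any(n_horses < 1), "n_horses must be >= 1")
  out <- n_events / (n_horses * tracking_hours)
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Convert cm/s to km/h
#'
#' @param v speed in cm/s.
#' @param digits decimals for half-up rounding; `NULL` for full precision.
#' @return speed in km/h (`v * 0.036`).
#' @export
#' @examples
#' cm_s_to_km_h(89)  # 3.2
cm_s_to_km_h <- function(v, digits = 2) {
  out <- v * 0.036
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Score detected events against simulator ground truth
#'
#' A detected event matches a ground-truth event when the dyad agrees, the
#' kinds agree, and the time windows overlap. Precision is the matched
#' fraction of detected events; recall the matched fraction of ground-truth
#' events.
#'
#' @param detected event data.frame from [detect_agonistic_events()].
#' @param truth ground-truth events from [simulate_herd()]
#'   (`sim$ground_truth$events`).
#' @return list: `precision`, `recall`, `n_detected`, `n_truth`, and the
#'   same split by kind.
#' @export
evaluate_event_recovery <- function(detected, truth) {
  match_one <- function(det, tru) {
    if (!nrow(det) || !nrow(tru)) {
      return(list(det_hit = rep(FALSE, nrow(det)),
                  tru_hit = rep(FALSE, nrow(tru))))
    }
    det_key <- dyad_key(det$a, det$b); tru_key <- dyad_key(tru$a, tru$b)
    det_hit <- rep(FALSE, nrow(det)); tru_hit <- rep(FALSE, nrow(tru))
    for (i in seq_len(nrow(det))) {
      cand <- which(tru_key == det_key[i] & tru$kind == det$kind[i] &
                      tru$t_start <= det$t_end[i] & det$t_start[i] <= tru$t_end)
      if (length(cand)) {
        det_hit[i] <- TRUE
        tru_hit[cand[1]] <- TRUE
      }
    }
    list(det_hit = det_hit, tru_hit = tru_hit)
  }
  res <- match_one(detected, truth)
  by_kind <- lapply(unique(truth$kind), function(kk) {
    r <- match_one(detected[detected$kind == kk, , drop = FALSE],
                   truth[truth$kind == kk, , drop = FALSE])
    list(kind = kk,
         precision = if (length(r$det_hit)) mean(r$det_hit) else NA_real_,
         recall = if (length(r$tru_hit)) mean(r$tru_hit) else NA_real_)
  })
  list(precision = if (nrow(detected)) mean(res$det_hit) else NA_real_,
       recall = if (nrow(truth)) mean(res$tru_hit) else NA_real_,
       n_detected = nrow(detected), n_truth = nrow(truth),
       by_kind = by_kind)
}
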