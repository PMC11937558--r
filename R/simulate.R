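# Agent-based herd simulator: attraction-repulsion spacing with slow-moving
# grazing anchors, optional feeder bouts, and choreographed agonistic
# approach/retreat episodes. Provides ground truth (positions, event windows,
# injected sensor artifacts) for every downstream analysis stage.

#' Sensor-noise model for simulated distance channels
#'
#' Describes how true interindividual distances are corrupted on their way
#' into the two directed sensor channels of a dyad: shared ranging jitter,
#' independent replicate (channel) noise, sporadic out-of-range spikes,
#' impossible sub-5 cm readings, and frozen (stuck-value) segments.
#'
#' @param jitter_sd_cm sd (cm) of ranging noise shared by both channels of a
#'   dyad at a timestamp.
#' @param replicate_sd_cm sd (cm) of independent per-channel noise; the
#'   difference between the two channels of a dyad then has sd
#'   `sqrt(2) * replicate_sd_cm`.
#' @param p_spike per-sample probability of an out-of-range spike (reading
#'   above the enclosure diagonal).
#' @param p_under5 per-sample probability of an impossible reading below 5 cm.
#' @param frozen_segments list of stuck-sensor episodes, each a list with
#'   elements `a`, `b` (animal ids), `t_start` (s) and `length_s`; the dyad's
#'   channels repeat the value at `t_start` for the whole segment.
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(jitter_sd_cm = 2, replicate_sd_cm = 3,
                         p_spike = 0.001, p_under5 = 0.0005,
                         frozen_segments = list()) {
  stop_if(jitter_sd_cm < 0 || replicate_sd_cm < 0, "noise sds must be >= 0")
  stop_if(p_spike < 0 || p_spike > 1 || p_under5 < 0 || p_under5 > 1,
          "artifact probabilities must be in [0, 1]")
  structure(list(jitter_sd_cm = jitter_sd_cm, replicate_sd_cm = replicate_sd_cm,
                 p_spike = p_spike, p_under5 = p_under5,
                 frozen_segments = frozen_segments),
            class = "noise_config")
}

#' Zero-noise sensor model
#'
#' Convenience constructor: perfect sensors, no artifacts.
#' @return a `noise_config` with all noise terms zero.
#' @export
noise_off <- function() {
  noise_config(jitter_sd_cm = 0, replicate_sd_cm = 0, p_spike = 0,
               p_under5 = 0, frozen_segments = list())
}

#' Scripted agonistic episode
#'
#' A choreographed approach-retreat sequence between two agents. By
#' construction the executed approach satisfies the four detection criteria
#' (>= 100 cm decrease to < 200 cm within 3 s, mean closing speed >= 85 cm/s,
#' two animals only, consistent direction); the retreat leg separates the
#' high-intensity (120 cm/s) and low-intensity (40 cm/s) classes.
#'
#' @param t_start_s scheduled start time (s from simulation start).
#' @param aggressor,target agent ids (must differ).
#' @param kind `"approach_then_high_retreat"` or
#'   `"approach_then_low_retreat"`.
#' @param approach_speed_cm_s closing speed of the charge, >= 85 cm/s.
#' @return an object of class `scripted_event`.
#' @export
scripted_event <- function(t_start_s, aggressor, target,
                           kind = c("approach_then_high_retreat",
                                    "approach_then_low_retreat"),
                           approach_speed_cm_s = 100) {
  kind <- match.arg(kind)
  stop_if(identical(aggressor, target), "aggressor and target must differ")
  stop_if(approach_speed_cm_s < 85, "approach speed must be >= 85 cm/s")
  structure(list(t_start_s = as.numeric(t_start_s),
                 aggressor = as.character(aggressor),
                 target = as.character(target), kind = kind,
                 approach_speed_cm_s = approach_speed_cm_s),
            class = "scripted_event")
}

#' Pair-partner affinity structure
#'
#' Default social structure: consecutive agents form mutually preferred
#' pairs (affinity `high`), all other dyads share a background affinity
#' `low`. With an odd roster the last agent has only background ties.
#'
#' @param n number of agents.
#' @param high,low affinities in \[0, 1\] for partner and background dyads.
#' @return symmetric `n x n` affinity matrix with zero diagonal.
#' @export
affinity_pairs <- function(n, high = 0.9, low = 0.3) {
  A <- matrix(low, n, n)
  diag(A) <- 0
  for (i in seq(1, n - 1, by = 2)) {
    if (i + 1 <= n) A[i, i + 1] <- A[i + 1, i] <- high
  }
  A
}

#' Herd simulation configuration
#'
#' Bundles the enclosure geometry, roster, social-affinity structure, motion
#' parameters, feeder, scripted agonistic episodes and the sensor-noise model
#' into a validated configuration object.
#'
#' Movement model: each agent relaxes toward a private "grazing anchor" that
#' performs a slow reflected random walk through the enclosure (anchors of
#' high-affinity dyads are coupled so preferred partners graze together);
#' pairs interact through a piecewise-linear spring toward a per-dyad
#' equilibrium distance `equilibrium_dist_m * (1 + 2 * (1 - affinity))`
#' (repulsive inside, attractive beyond, gain scaled by squared affinity)
#' with a hard-core repulsion below 1 m; isotropic Gaussian motion jitter is
#' added and the per-step speed of non-scripted motion is capped at
#' 300 cm/s.
#'
#' @param enclosure_length_m,enclosure_width_m enclosure dimensions (m).
#' @param n_agents number of agents (>= 2).
#' @param duration_s simulated duration in seconds (>= 60; 1 Hz steps).
#' @param seed integer seed; identical configurations and seeds give
#'   bit-identical output.
#' @param ids agent identifiers (default `H01`, `H02`, ...).
#' @param affinity symmetric matrix of affinities in \[0, 1\]; diagonal
#'   ignored. Default [affinity_pairs()].
#' @param equilibrium_dist_m preferred distance (m) of a maximal-affinity
#'   dyad; lower-affinity dyads equilibrate proportionally farther.
#' @param feeder_xy optional feeder location `c(x, y)` in m; when present,
#'   agents take Markov feeding bouts during which they walk to the feeder.
#' @param event_schedule list of [scripted_event()]s.
#' @param noise a [noise_config()].
#' @param motion_sd_m_s sd (m/s) of per-axis motion jitter.
#' @param spring_gain pair spring gain (1/s) at affinity 1.
#' @param anchor_speed_m_s sd (m/s) of the anchor random walk.
#' @param anchor_gain relaxation rate (1/s) of an agent toward its anchor.
#' @param anchor_couple coupling rate (1/s) pulling high-affinity anchors
#'   together (scaled by squared affinity).
#' @param feeder_start_prob,feeder_stop_prob per-second probabilities of
#'   starting/ending a feeding bout.
#' @param feeder_speed_m_s walking speed toward the feeder while feeding.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(enclosure_length_m, enclosure_width_m, n_agents,
                       duration_s, seed = 1L, ids = NULL, affinity = NULL,
                       equilibrium_dist_m = 3, feeder_xy = NULL,
                       event_schedule = list(), noise = noise_config(),
                       motion_sd_m_s = 0.10, spring_gain = 0.05,
                       anchor_speed_m_s = 0.35, anchor_gain = 0.02,
                       anchor_couple = 0.05, feeder_start_prob = 0.001,
                       feeder_stop_prob = 0.01, feeder_speed_m_s = 0.5) {
  stop_if(enclosure_length_m <= 0 || enclosure_width_m <= 0,
          "enclosure dimensions must be positive")
  stop_if(n_agents < 2, "n_agents must be >= 2")
  stop_if(duration_s < 60, "duration_s must be >= 60")
  ids <- ids %||% sprintf("H%02d", seq_len(n_agents))
  stop_if(length(ids) != n_agents || anyDuplicated(ids) > 0,
          "ids must be n_agents unique identifiers")
  affinity <- affinity %||% affinity_pairs(n_agents)
  stop_if(!is.matrix(affinity) || any(dim(affinity) != n_agents),
          "affinity must be an n_agents x n_agents matrix")
  stop_if(max(abs(affinity - t(affinity))) > 1e-12,
          "affinity matrix must be symmetric")
  stop_if(any(affinity < 0 | affinity > 1), "affinities must be in [0, 1]")
  if (!is.null(feeder_xy)) {
    stop_if(length(feeder_xy) != 2 ||
              feeder_xy[1] < 0 || feeder_xy[1] > enclosure_length_m ||
              feeder_xy[2] < 0 || feeder_xy[2] > enclosure_width_m,
            "feeder_xy must lie inside the enclosure")
  }
  for (ev in event_schedule) {
    stop_if(!inherits(ev, "scripted_event"),
            "event_schedule entries must be scripted_event objects")
    stop_if(!(ev$aggressor %in% ids) || !(ev$target %in% ids),
            sprintf("event agents %s/%s not in roster", ev$aggressor, ev$target))
    stop_if(ev$t_start_s + 10 > duration_s,
            "scripted event must start at least 10 s before the end")
  }
  stop_if(!inherits(noise, "noise_config"), "noise must be a noise_config")
  structure(list(
    enclosure_length_m = enclosure_length_m,
    enclosure_width_m = enclosure_width_m,
    n_agents = as.integer(n_agents), duration_s = as.integer(duration_s),
    seed = as.integer(seed), ids = as.character(ids), affinity = affinity,
    equilibrium_dist_m = equilibrium_dist_m, feeder_xy = feeder_xy,
    event_schedule = event_schedule, noise = noise,
    motion_sd_m_s = motion_sd_m_s, spring_gain = spring_gain,
    anchor_speed_m_s = anchor_speed_m_s, anchor_gain = anchor_gain,
    anchor_couple = anchor_couple, feeder_start_prob = feeder_start_prob,
    feeder_stop_prob = feeder_stop_prob, feeder_speed_m_s = feeder_speed_m_s
  ), class = "sim_config")
}

# reflect coordinates into [0, hi]
.reflect <- function(x, hi) {
  x <- abs(x)
  over <- x > hi
  x[over] <- 2 * hi - x[over]
  pmin(pmax(x, 0), hi)
}

# minimum distance from points (px, py) to segment (x1,y1)-(x2,y2)
.dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  if (len2 < 1e-12) return(sqrt((px - x1)^2 + (py - y1)^2))
  u <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
  sqrt((px - (x1 + u * dx))^2 + (py - (y1 + u * dy))^2)
}

#' Simulate a herd of socially interacting agents
#'
#' Integrates the movement model of [sim_config()] with 1 s Euler steps and
#' executes the scripted agonistic episodes, logging ground-truth windows
#' for every executed approach and retreat. An episode is only launched when
#' a charge corridor with sufficient clearance from bystanders exists (the
#' choreography must involve exactly two animals); if no clear corridor is
#' found within 30 s of the scheduled start the episode is skipped and
#' logged as such.
#'
#' @param config a [sim_config()].
#' @return an object of class `herd_sim`: list with `x`, `y` (T x n position
#'   matrices in m, 1 Hz), `ids`, `config`, and `ground_truth` (list with
#'   `events` — executed approach/retreat windows — and `skipped_events`).
#' @export
simulate_herd <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_herd_impl(config))
}

.simulate_herd_impl <- function(cfg) {
  n <- cfg$n_agents
  T_ <- cfg$duration_s
  L <- cfg$enclosure_length_m
  W <- cfg$enclosure_width_m
  aff <- cfg$affinity
  eq_m <- cfg$equilibrium_dist_m * (1 + 2 * (1 - aff))  # per-dyad equilibrium
  gain <- cfg$spring_gain * aff^2
  diag(eq_m) <- 0; diag(gain) <- 0

  X <- matrix(NA_real_, T_, n); Y <- matrix(NA_real_, T_, n)
  X[1, ] <- stats::runif(n, 0.05 * L, 0.95 * L)
  Y[1, ] <- stats::runif(n, 0.05 * W, 0.95 * W)
  ax <- X[1, ]; ay <- Y[1, ]  # grazing anchors
  feeding <- rep(FALSE, n)
  has_feeder <- !is.null(cfg$feeder_xy)

  # event machinery -------------------------------------------------------
  sched <- cfg$event_schedule
  if (length(sched)) sched <- sched[order(vapply(sched, `[[`, 0, "t_start_s"))]
  ev_status <- rep("pending", length(sched))
  next_ev <- if (length(sched)) 1L else 0L
  active <- NULL            # state of the running episode, or NULL
  defer_limit_s <- 60
  events_log <- list()
  skipped_log <- list()

  id_idx <- stats::setNames(seq_len(n), cfg$ids)

  try_activate <- function(ev, px, py, time_s) {
    ai <- id_idx[[ev$aggressor]]; ti <- id_idx[[ev$target]]
    spd_m <- ev$approach_speed_cm_s / 100
    start_dist <- max(3, 1.5 + 2.5 * spd_m)          # m; charge start range
    retreat_spd <- if (ev$kind == "approach_then_high_retreat") 1.2 else 0.4
    retreat_reach <- 3 * retreat_spd + 1             # m beyond target
    angles <- seq(0, 2 * pi, length.out = 25)[-25]
    best <- NULL; best_clear <- -Inf
    others <- setdiff(seq_len(n), c(ai, ti))
    for (th in angles) {
      ux <- cos(th); uy <- sin(th)
      pxs <- px[ti] + ux * start_dist; pys <- py[ti] + uy * start_dist
      qx <- px[ti] - ux * retreat_reach; qy <- py[ti] - uy * retreat_reach
      if (pxs < 0.5 || pxs > L - 0.5 || pys < 0.5 || pys > W - 0.5) next
      if (qx < 0.5 || qx > L - 0.5 || qy < 0.5 || qy > W - 0.5) next
      # keep the whole choreography clear of the feeder: samples with both
      # animals near it are excised by the feeder filter downstream
      if (!is.null(cfg$feeder_xy)) {
        fcl <- min(
          .dist_to_segment(cfg$feeder_xy[1], cfg$feeder_xy[2],
                           pxs, pys, px[ti], py[ti]),
          .dist_to_segment(cfg$feeder_xy[1], cfg$feeder_xy[2],
                           px[ti], py[ti], qx, qy))
        if (fcl < 4) next
      }
      # the walk to the charge start must not brush past the target either
      # (never closer to it than the aggressor already is)
      d_at <- sqrt((px[ai] - px[ti])^2 + (py[ai] - py[ti])^2)
      if (.dist_to_segment(px[ti], py[ti], px[ai], py[ai], pxs, pys) <
            min(2.5, d_at - 0.1)) next
      if (length(others)) {
        cl <- min(
          .dist_to_segment(px[others], py[others], px[ai], py[ai], pxs, pys),
          .dist_to_segment(px[others], py[others], pxs, pys, px[ti], py[ti]),
          .dist_to_segment(px[others], py[others], px[ti], py[ti], qx, qy)
        )
      } else cl <- Inf
      if (cl > best_clear) {
        best_clear <- cl
        best <- list(ux = ux, uy = uy, sx = pxs, sy = pys)
      }
    }
    if (is.null(best)) return(NULL)
    # clearance margin grows with the walk the aggressor must make to the
    # charge start, since bystanders drift while he travels
    walk_s <- sqrt((px[ai] - best$sx)^2 + (py[ai] - best$sy)^2) / 3
    if (best_clear < 2.3 + 0.08 * walk_s) return(NULL)
    list(ev = ev, ai = ai, ti = ti, phase = "separate",
         sx = best$sx, sy = best$sy, retreat_spd = retreat_spd,
         spd_m = spd_m, approach_start = NA_real_, approach_end = NA_real_,
         retreat_steps = 0L, activated_at = time_s)
  }

  for (step in seq_len(T_ - 1)) {
    time_s <- step - 1
    px <- X[step, ]; py <- Y[step, ]

    # -- scripted episode bookkeeping
    agitation <- NA_integer_
    if (is.null(active) && next_ev > 0 && next_ev <= length(sched)) {
      ev <- sched[[next_ev]]
      if (time_s >= ev$t_start_s) {
        if (time_s - ev$t_start_s > defer_limit_s) {
          ev_status[next_ev] <- "skipped"
          skipped_log[[length(skipped_log) + 1]] <- data.frame(
            kind = ev$kind, a = ev$aggressor, b = ev$target,
            t_sched = ev$t_start_s, stringsAsFactors = FALSE)
          next_ev <- next_ev + 1L
        } else {
          act <- try_activate(ev, px, py, time_s)
          if (!is.null(act)) {
            active <- act
            ev_status[next_ev] <- "running"
          } else {
            agitation <- id_idx[[ev$target]]  # clear space around the target
          }
        }
      }
    }

    involved <- if (!is.null(active)) c(active$ai, active$ti) else integer(0)

    # -- background social forces (overdamped: velocity in m/s)
    dxm <- outer(px, px, "-"); dym <- outer(py, py, "-")
    dm <- sqrt(dxm^2 + dym^2); diag(dm) <- Inf
    # spring toward per-dyad equilibrium, capped at 0.5 m/s per pair
    fmag <- gain * (dm - eq_m)
    fmag[!is.finite(fmag)] <- 0
    fmag <- pmin(pmax(fmag, -0.5), 0.5)
    ux <- -dxm / dm; uy <- -dym / dm   # unit vector from i toward j
    # affinity-scaled spring is averaged over partners so cohesion does not
    # grow with group size; personal space (< 2.5 m) is defended against
    # every neighbour regardless of affinity with a graded push whose gain
    # stays below the violation depth (no overshoot oscillation), plus an
    # extra ramp below 1 m; the summed evasion is capped well under the
    # 85 cm/s charge threshold so avoidance never resembles a charge
    hc <- -0.35 * pmax(2.5 - dm, 0) - 0.5 * pmax(1 - dm, 0)
    hx <- rowSums(hc * ux); hy <- rowSums(hc * uy)
    hmag <- sqrt(hx^2 + hy^2)
    scale_h <- ifelse(hmag > 0.7, 0.7 / hmag, 1)
    vx <- rowSums(fmag * ux) / (n - 1) + hx * scale_h
    vy <- rowSums(fmag * uy) / (n - 1) + hy * scale_h
    # anchor pull, capped so homing never looks like a charge
    adx <- ax - px; ady <- ay - py
    ad <- pmax(sqrt(adx^2 + ady^2), 1e-9)
    pull <- pmin(cfg$anchor_gain * ad, 0.3)
    vx <- vx + pull * adx / ad
    vy <- vy + pull * ady / ad
    # feeder bouts
    if (has_feeder) {
      start <- !feeding & stats::runif(n) < cfg$feeder_start_prob
      stop_ <- feeding & stats::runif(n) < cfg$feeder_stop_prob
      feeding <- (feeding | start) & !stop_
      if (length(involved)) feeding[involved] <- FALSE
      if (any(feeding)) {
        fx <- cfg$feeder_xy[1] - px[feeding]
        fy <- cfg$feeder_xy[2] - py[feeding]
        fd <- pmax(sqrt(fx^2 + fy^2), 1e-9)
        pull <- cfg$feeder_speed_m_s * pmin(fd / 1.2, 1)  # ease in near feeder
        vx[feeding] <- vx[feeding] + pull * fx / fd
        vy[feeding] <- vy[feeding] + pull * fy / fd
      }
    }
    # motion jitter
    vx <- vx + stats::rnorm(n, 0, cfg$motion_sd_m_s)
    vy <- vy + stats::rnorm(n, 0, cfg$motion_sd_m_s)
    # pre-conflict agitation: while an episode is waiting for a clear
    # corridor, neighbours of the intended target gently move off
    if (!is.na(agitation)) {
      for (k in setdiff(seq_len(n), agitation)) {
        ddx <- px[k] - px[agitation]; ddy <- py[k] - py[agitation]
        dd <- sqrt(ddx^2 + ddy^2)
        if (dd < 6.5 && dd > 1e-9) {
          push <- min(0.2 * (6.5 - dd), 0.5)
          vx[k] <- vx[k] + push * ddx / dd
          vy[k] <- vy[k] + push * ddy / dd
        }
      }
    }
    # cap background speed at 300 cm/s
    spd <- sqrt(vx^2 + vy^2)
    over <- spd > 3
    if (any(over)) {
      vx[over] <- vx[over] * 3 / spd[over]
      vy[over] <- vy[over] * 3 / spd[over]
    }

    # -- scripted override for the involved dyad
    if (!is.null(active)) {
      ai <- active$ai; ti <- active$ti
      # bystanders scatter from the ongoing confrontation (graded push away
      # from the involved animals, well below the charge-speed threshold)
      for (k in setdiff(seq_len(n), c(ai, ti))) {
        for (m in c(ai, ti)) {
          ddx <- px[k] - px[m]; ddy <- py[k] - py[m]
          dd <- sqrt(ddx^2 + ddy^2)
          if (dd < 4.5 && dd > 1e-9) {
            push <- min(0.3 * (4.5 - dd), 0.6)
            vx[k] <- vx[k] + push * ddx / dd
            vy[k] <- vy[k] + push * ddy / dd
          }
        }
      }
      vx[c(ai, ti)] <- 0; vy[c(ai, ti)] <- 0
      if (active$phase == "separate") {
        ddx <- active$sx - px[ai]; ddy <- active$sy - py[ai]
        dd <- sqrt(ddx^2 + ddy^2)
        if (dd <= 3) {  # arrive this step and begin the charge next step
          vx[ai] <- ddx; vy[ai] <- ddy
          active$phase <- "approach"
          active$approach_start <- time_s + 1
        } else {
          vx[ai] <- 3 * ddx / dd; vy[ai] <- 3 * ddy / dd
        }
      } else if (active$phase == "approach") {
        ddx <- px[ti] - px[ai]; ddy <- py[ti] - py[ai]
        dd <- sqrt(ddx^2 + ddy^2)
        stepm <- min(active$spd_m, max(dd - 1.2, 0))
        vx[ai] <- stepm * ddx / dd; vy[ai] <- stepm * ddy / dd
        if (dd - stepm < 1.5) {  # next recorded position is within 150 cm
          active$phase <- "retreat"
          active$approach_end <- time_s + 1
          active$rux <- ddx / dd; active$ruy <- ddy / dd
        }
      } else if (active$phase == "retreat") {
        vx[ti] <- active$retreat_spd * active$rux
        vy[ti] <- active$retreat_spd * active$ruy
        active$retreat_steps <- active$retreat_steps + 1L
        if (active$retreat_steps >= 3L) {
          ev <- active$ev
          rk <- if (ev$kind == "approach_then_high_retreat")
            "high_retreat" else "low_retreat"
          events_log[[length(events_log) + 1]] <- data.frame(
            event_id = next_ev, kind = c("approach", rk),
            a = ev$aggressor, b = ev$target,
            t_start = c(active$approach_start, active$approach_end),
            t_end = c(active$approach_end, time_s + 1),
            stringsAsFactors = FALSE)
          ev_status[next_ev] <- "done"
          next_ev <- next_ev + 1L
          active <- NULL
        }
      }
    }

    X[step + 1, ] <- .reflect(px + vx, L)
    Y[step + 1, ] <- .reflect(py + vy, W)

    # -- anchor dynamics: slow reflected random walk; preferred partners'
    # anchors are spring-coupled toward their pair equilibrium distance, so
    # partners graze together while unrelated animals drift apart
    cax <- outer(ax, ax, "-"); cay <- outer(ay, ay, "-")
    adm <- sqrt(cax^2 + cay^2); diag(adm) <- Inf
    cmag <- cfg$anchor_couple * (aff > 0.6) * (adm - eq_m)
    cmag[!is.finite(cmag)] <- 0
    cmag <- pmin(pmax(cmag, -0.15), 0.15)
    ax <- ax + rowSums(cmag * (-cax / adm)) +
      stats::rnorm(n, 0, cfg$anchor_speed_m_s)
    ay <- ay + rowSums(cmag * (-cay / adm)) +
      stats::rnorm(n, 0, cfg$anchor_speed_m_s)
    ax <- .reflect(ax, L); ay <- .reflect(ay, W)
  }

  events <- if (length(events_log)) do.call(rbind, events_log) else
    data.frame(event_id = integer(0), kind = character(0), a = character(0),
               b = character(0), t_start = numeric(0), t_end = numeric(0))
  skipped <- if (length(skipped_log)) do.call(rbind, skipped_log) else
    data.frame(kind = character(0), a = character(0), b = character(0),
               t_sched = numeric(0))
  structure(list(x = X, y = Y, ids = cfg$ids, config = cfg,
                 ground_truth = list(events = events, skipped_events = skipped,
                                     artifacts = NULL)),
            class = "herd_sim")
}

#' @export
print.herd_sim <- function(x, ...) {
  cat(sprintf("<herd_sim: %d agents, %d s, %.0fx%.0f m, %d executed / %d skipped events>\n",
              x$config$n_agents, x$config$duration_s,
              x$config$enclosure_length_m, x$config$enclosure_width_m,
              length(unique(x$ground_truth$events$event_id)),
              nrow(x$ground_truth$skipped_events)))
  invisible(x)
}

#' Convert simulated trajectories to raw dyadic distance channels
#'
#' Emits both directed sensor channels (A->B and B->A) for every dyad at
#' 1 Hz, in cm, applying the sensor-noise model: shared ranging jitter,
#' independent replicate noise per channel, out-of-range spikes, sub-5 cm
#' readings and frozen segments. Every injected artifact is logged so
#' cleaning filters can be scored against ground truth. When the
#' configuration has a feeder, one extra channel per agent reports its
#' distance to the feeder (id `"FEEDER"`).
#'
#' @param sim a `herd_sim` from [simulate_herd()].
#' @param noise a [noise_config()]; defaults to the one in the simulation
#'   configuration.
#' @param seed seed for the sensor-noise draws (independent of the motion
#'   seed); default derives from the simulation seed.
#' @return list with `distances` (data.frame `t`, `a`, `b`, `d` — `t` in
#'   epoch seconds, `d` in cm) and `artifacts` (data.frame `a`, `b`, `t`,
#'   `class` with class one of `"spike"`, `"under5"`, `"frozen"`).
#' @export
trajectories_to_distances <- function(sim, noise = NULL, seed = NULL) {
  stopifnot(inherits(sim, "herd_sim"))
  noise <- noise %||% sim$config$noise
  seed <- seed %||% (sim$config$seed + 7919L)
  with_seed(seed, .traj_to_dist_impl(sim, noise))
}

.traj_to_dist_impl <- function(sim, noise) {
  cfg <- sim$config
  n <- cfg$n_agents
  T_ <- nrow(sim$x)
  tt <- seq_len(T_) - 1
  diag_cm <- 100 * sqrt(cfg$enclosure_length_m^2 + cfg$enclosure_width_m^2)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- vector("list", nrow(pairs) * 2)
  art <- list()
  frozen_by_dyad <- list()
  for (fs in noise$frozen_segments) {
    k <- dyad_key(fs$a, fs$b)
    frozen_by_dyad[[k]] <- c(frozen_by_dyad[[k]], list(fs))
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    a <- cfg$ids[i]; b <- cfg$ids[j]
    true_cm <- 100 * sqrt((sim$x[, i] - sim$x[, j])^2 +
                            (sim$y[, i] - sim$y[, j])^2)
    jit <- if (noise$jitter_sd_cm > 0)
      stats::rnorm(T_, 0, noise$jitter_sd_cm) else 0
    ch <- list(
      ab = true_cm + jit + if (noise$replicate_sd_cm > 0)
        stats::rnorm(T_, 0, noise$replicate_sd_cm) else 0,
      ba = true_cm + jit + if (noise$replicate_sd_cm > 0)
        stats::rnorm(T_, 0, noise$replicate_sd_cm) else 0
    )
    # frozen segments first: stuck sensors repeat the value at onset
    frozen_mask <- rep(FALSE, T_)
    for (fs in frozen_by_dyad[[dyad_key(a, b)]] %||% list()) {
      idx <- which(tt >= fs$t_start & tt < fs$t_start + fs$length_s)
      if (!length(idx)) next
      frozen_mask[idx] <- TRUE
      ch$ab[idx] <- ch$ab[idx[1]]
      ch$ba[idx] <- ch$ba[idx[1]]
      art[[length(art) + 1]] <- data.frame(
        a = a, b = b, t = tt[idx], class = "frozen", stringsAsFactors = FALSE)
    }
    for (nm in names(ch)) {
      ends <- if (nm == "ab") c(a, b) else c(b, a)
      u <- stats::runif(T_)
      spike <- u < noise$p_spike & !frozen_mask
      under <- !spike & u < noise$p_spike + noise$p_under5 & !frozen_mask
      if (any(spike)) {
        ch[[nm]][spike] <- diag_cm * stats::runif(sum(spike), 1.05, 1.8)
        art[[length(art) + 1]] <- data.frame(
          a = ends[1], b = ends[2], t = tt[spike], class = "spike",
          stringsAsFactors = FALSE)
      }
      if (any(under)) {
        ch[[nm]][under] <- stats::runif(sum(under), 0, 4.9)
        art[[length(art) + 1]] <- data.frame(
          a = ends[1], b = ends[2], t = tt[under], class = "under5",
          stringsAsFactors = FALSE)
      }
      out[[2 * (r - 1) + (nm == "ba") + 1]] <- data.frame(
        t = tt, a = ends[1], b = ends[2], d = ch[[nm]],
        stringsAsFactors = FALSE)
    }
  }
  dist_df <- do.call(rbind, out)
  if (!is.null(cfg$feeder_xy)) {
    feed <- lapply(seq_len(n), function(i) {
      dcm <- 100 * sqrt((sim$x[, i] - cfg$feeder_xy[1])^2 +
                          (sim$y[, i] - cfg$feeder_xy[2])^2)
      if (noise$jitter_sd_cm > 0) dcm <- dcm + stats::rnorm(T_, 0, noise$jitter_sd_cm)
      data.frame(t = tt, a = cfg$ids[i], b = "FEEDER", d = dcm,
                 stringsAsFactors = FALSE)
    })
    dist_df <- rbind(dist_df, do.call(rbind, feed))
  }
  artifacts <- if (length(art)) do.call(rbind, art) else
    data.frame(a = character(0), b = character(0), t = numeric(0),
               class = character(0))
  list(distances = dist_df, artifacts = artifacts)
}

#' Schedule non-overlapping scripted agonistic episodes
#'
#' Generates an event schedule with a target per-horse-hour rate, episode
#' kinds drawn with probability `p_high` for the high-intensity retreat
#' variant, aggressor/target pairs drawn uniformly, and starts spread over
#' the duration with enough spacing for each choreography (including
#' possible deferral) to finish before the next begins.
#'
#' @param ids roster of agent ids.
#' @param duration_s simulated duration (s).
#' @param rate_per_horse_hour target scheduled-episode rate per horse-hour.
#' @param seed integer seed.
#' @param p_high probability an episode ends in a high-intensity retreat.
#' @param min_slot_s minimum spacing between scheduled starts.
#' @param speed_range_cm_s range of charge speeds sampled per episode.
#' @return list of [scripted_event()]s.
#' @export
schedule_agonistic_events <- function(ids, duration_s, rate_per_horse_hour,
                                      seed = 1L, p_high = 0.15,
                                      min_slot_s = 45,
                                      speed_range_cm_s = c(95, 130)) {
  n_ev <- round(rate_per_horse_hour * length(ids) * duration_s / 3600)
  if (n_ev == 0) return(list())
  slot <- (duration_s - 60) / n_ev
  stop_if(slot < min_slot_s,
          sprintf("schedule too dense: %.1f s per episode < %d s", slot, min_slot_s))
  with_seed(seed, {
    lapply(seq_len(n_ev), function(k) {
      pair <- sample(ids, 2)
      scripted_event(
        t_start_s = floor((k - 1) * slot) + sample.int(max(floor(slot) - 44, 1), 1),
        aggressor = pair[1], target = pair[2],
        kind = if (stats::runif(1) < p_high) "approach_then_high_retreat"
               else "approach_then_low_retreat",
        approach_speed_cm_s = stats::runif(1, speed_range_cm_s[1],
                                           speed_range_cm_s[2]))
    })
  })
}

#' Write simulated raw distances as a long CSV
#'
#' Serialises a raw distance table in the sensor-export schema
#' `timestamp,sensor_a,sensor_b,distance_cm` with ISO-8601 timestamps.
#'
#' @param distances data.frame `t`, `a`, `b`, `d` (seconds / ids / cm).
#' @param path output file path.
#' @param origin POSIXct origin mapped to `t = 0`.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(distances, path,
                               origin = as.POSIXct("2024-06-01 06:00:00",
                                                   tz = "UTC")) {
  df <- data.frame(
    timestamp = format(origin + distances$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    sensor_a = distances$a, sensor_b = distances$b,
    distance_cm = distances$d)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
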