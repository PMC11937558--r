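test_that("identical configuration and seed give bit-identical output", {
  cfg <- sim_config(30, 15, 4, duration_s = 120, seed = 7L)
  s1 <- simulate_herd(cfg)
  s2 <- simulate_herd(cfg)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$y, s2$y)
  d1 <- trajectories_to_distances(s1)
  d2 <- trajectories_to_distances(s2)
  expect_identical(d1$distances, d2$distances)
})

test_that("two high-affinity agents settle near the equilibrium distance", {
  cfg <- sim_config(30, 15, 2, duration_s = 600, seed = 2L,
                    affinity = matrix(c(0, 1, 1, 0), 2),
                    equilibrium_dist_m = 3, motion_sd_m_s = 0,
                    anchor_speed_m_s = 0)
  sim <- simulate_herd(cfg)
  d <- sqrt((sim$x[, 1] - sim$x[, 2])^2 + (sim$y[, 1] - sim$y[, 2])^2)
  avg <- mean(tail(d, 300))
  expect_gt(avg, 3 * 0.8)
  expect_lt(avg, 3 * 1.2)
})

test_that("positions stay inside the enclosure and empty schedules yield no events", {
  cfg <- sim_config(20, 10, 5, duration_s = 300, seed = 3L)
  sim <- simulate_herd(cfg)
  expect_true(all(sim$x >= 0 & sim$x <= 20))
  expect_true(all(sim$y >= 0 & sim$y <= 10))
  expect_equal(nrow(sim$ground_truth$events), 0)
})

test_that("configuration validation rejects invalid inputs", {
  expect_error(sim_config(30, 15, 1, 120), "n_agents")
  expect_error(sim_config(30, 15, 3, 30), "duration_s")
  expect_error(sim_config(30, 15, 2, 120, feeder_xy = c(40, 5)), "feeder")
  expect_error(sim_config(30, 15, 2, 120,
                          affinity = matrix(c(0, 0.2, 0.8, 0), 2)),
               "symmetric")
  expect_error(scripted_event(10, "A", "A"), "differ")
  expect_error(scripted_event(10, "A", "B", approach_speed_cm_s = 50),
               ">= 85")
  ev <- scripted_event(115, "H01", "H02")
  expect_error(sim_config(30, 15, 2, 120, event_schedule = list(ev)),
               "10 s before")
})

test_that("stationary agents produce constant equal channels without noise", {
  T_ <- 80
  x <- cbind(rep(5, T_), rep(15, T_))
  y <- cbind(rep(5, T_), rep(5, T_))
  sim <- make_static_sim(x, y)
  td <- trajectories_to_distances(sim, noise = noise_off())
  ab <- td$distances[td$distances$a == "H01" & td$distances$b == "H02", ]
  ba <- td$distances[td$distances$a == "H02" & td$distances$b == "H01", ]
  expect_equal(ab$d, rep(1000, T_))
  expect_equal(ba$d, rep(1000, T_))
  expect_equal(nrow(td$artifacts), 0)
})

test_that("replicate noise gives channel differences with sd near sqrt(2) * sd", {
  T_ <- 4000
  x <- cbind(rep(5, T_), rep(15, T_))
  y <- cbind(rep(5, T_), rep(5, T_))
  sim <- make_static_sim(x, y)
  nz <- noise_config(jitter_sd_cm = 0, replicate_sd_cm = 5, p_spike = 0,
                     p_under5 = 0)
  td <- trajectories_to_distances(sim, noise = nz, seed = 99L)
  ab <- td$distances[td$distances$a == "H01", "d"]
  ba <- td$distances[td$distances$a == "H02", "d"]
  expect_equal(sd(ab - ba), sqrt(2) * 5, tolerance = 0.05)
})

test_that("injected artifacts are logged sample-by-sample", {
  T_ <- 80
  x <- cbind(rep(5, T_), rep(15, T_))
  y <- cbind(rep(5, T_), rep(5, T_))
  sim <- make_static_sim(x, y)
  nz <- noise_config(jitter_sd_cm = 1, replicate_sd_cm = 0, p_spike = 0,
                     p_under5 = 0,
                     frozen_segments = list(
                       list(a = "H01", b = "H02", t_start = 20,
                            length_s = 12)))
  td <- trajectories_to_distances(sim, noise = nz, seed = 4L)
  fr <- td$artifacts[td$artifacts$class == "frozen", ]
  expect_equal(nrow(fr), 12)
  expect_equal(fr$t, 20:31)
  ab <- td$distances[td$distances$a == "H01", ]
  expect_equal(length(unique(ab$d[ab$t %in% 20:31])), 1)
})

test_that("out-of-range spikes exceed the diagonal and sub-5 readings fall below 5", {
  T_ <- 600
  x <- cbind(rep(5, T_), rep(15, T_))
  y <- cbind(rep(5, T_), rep(5, T_))
  sim <- make_static_sim(x, y)
  nz <- noise_config(jitter_sd_cm = 0, replicate_sd_cm = 0, p_spike = 0.05,
                     p_under5 = 0.05)
  td <- trajectories_to_distances(sim, noise = nz, seed = 5L)
  diag_cm <- 100 * sqrt(30^2 + 15^2)
  art <- td$artifacts
  expect_gt(nrow(art[art$class == "spike", ]), 0)
  expect_gt(nrow(art[art$class == "under5", ]), 0)
  for (k in seq_len(nrow(art))) {
    val <- td$distances$d[td$distances$a == art$a[k] &
                            td$distances$b == art$b[k] &
                            td$distances$t == art$t[k]]
    if (art$class[k] == "spike") expect_gt(val, diag_cm)
    if (art$class[k] == "under5") expect_lt(val, 5)
  }
})

test_that("median spacing grows with enclosure size under the same roster policy", {
  meds <- vapply(c("paddock", "field"), function(cond) {
    sco <- study_scenario(cond, n_agents = 6, duration_s = 1200, seed = 77L,
                          approach_rate_per_horse_hour = 0)
    sim <- simulate_herd(sco$sim)
    n <- ncol(sim$x)
    dd <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dd <- c(dd, sqrt((sim$x[, i] - sim$x[, j])^2 +
                         (sim$y[, i] - sim$y[, j])^2))
    }
    median(dd)
  }, 0)
  expect_gt(meds["field"], meds["paddock"])
})

test_that("every executed scripted episode satisfies the four approach criteria", {
  sco <- study_scenario("field", n_agents = 6, duration_s = 1500, seed = 31L,
                        approach_rate_per_horse_hour = 6,
                        noise = noise_off())
  sim <- simulate_herd(sco$sim)
  tru <- sim$ground_truth$events
  appr <- tru[tru$kind == "approach", ]
  expect_gt(nrow(appr), 2)
  ids <- sim$ids
  for (k in seq_len(nrow(appr))) {
    i <- match(appr$a[k], ids); j <- match(appr$b[k], ids)
    tt <- appr$t_start[k]:appr$t_end[k]
    d <- 100 * sqrt((sim$x[tt + 1, i] - sim$x[tt + 1, j])^2 +
                      (sim$y[tt + 1, i] - sim$y[tt + 1, j])^2)
    # somewhere in the window: >=100 cm drop to <200 cm within <=3 s at
    # mean speed >=85 cm/s, monotone within jitter
    found <- FALSE
    nw <- length(d)
    for (a in seq_len(nw - 1)) for (b in seq(a + 1, min(a + 3, nw))) {
      drop <- d[a] - d[b]
      if (drop >= 100 && d[b] < 200 && drop / (b - a) >= 85 &&
          all(diff(d[a:b]) <= 1)) found <- TRUE
    }
    expect_true(found)
  }
})

test_that("scheduling respects spacing and errors when too dense", {
  ids <- sprintf("H%02d", 1:8)
  sched <- schedule_agonistic_events(ids, 7200, 2.6, seed = 1L)
  expect_equal(length(sched), round(2.6 * 8 * 2))
  starts <- vapply(sched, `[[`, 0, "t_start_s")
  expect_true(all(diff(starts) > 0))
  expect_true(all(starts + 10 <= 7200))
  expect_error(schedule_agonistic_events(ids, 600, 20, seed = 1L), "dense")
})
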