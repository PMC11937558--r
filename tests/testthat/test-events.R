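test_that("speeds use true time denominators and flag impossible steps", {
  sp <- compute_speeds(make_series(c(100, 50)))
  expect_equal(sp$v, -50)
  expect_false(sp$flagged)

  sp2 <- compute_speeds(make_series(c(0.1, 900.1)))
  expect_true(sp2$flagged)

  s_gap <- distance_series("A", "B", t = c(0, 5), d = c(100, 400))
  sp3 <- compute_speeds(s_gap)
  expect_equal(sp3$v, 60)
  expect_equal(sp3$dt, 5)
})

test_that("the textbook approach window is detected with its printed statistics", {
  s <- make_series(c(400, 310, 220, 130))
  ev <- detect_approaches(list(s))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$displacement_cm, -270)
  expect_equal(ev$mean_speed_cm_s, 90)
  expect_equal(ev$kind, "approach")
})

test_that("windows failing the end-distance or speed criteria are rejected", {
  expect_equal(nrow(detect_approaches(list(make_series(c(400, 350, 300, 250))))), 0)
  expect_equal(nrow(detect_approaches(list(make_series(rep(150, 10))))), 0)
  # fast enough but never below 200 cm
  expect_equal(nrow(detect_approaches(list(make_series(c(800, 700, 600, 500))))), 0)
})

test_that("events never span cleaning gaps or flagged-speed samples", {
  # the same qualifying shape, but with a missing sample in the middle
  s_gap <- distance_series("A", "B", t = c(0, 1, 3), d = c(400, 310, 130))
  expect_equal(nrow(detect_approaches(list(s_gap))), 0)
  # an 850 cm/s error step inside the window voids it
  s_err <- make_series(c(400, 310, 1160, 130, 120, 110))
  expect_equal(nrow(detect_approaches(list(s_err))), 0)
})

test_that("overlapping qualifying windows merge into one event", {
  s <- make_series(c(600, 500, 400, 300, 190, 180))
  ev <- detect_approaches(list(s))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_start, 1)  # 500 -> 190 is the earliest qualifying window
  expect_equal(ev$t_end, 4)
})

test_that("concurrent events sharing an animal void each other", {
  ab <- make_series(c(400, 310, 220, 130, 140, 150, 160, 170),
                    a = "A", b = "B")
  ac <- make_series(c(420, 330, 240, 150, 150, 150, 150, 150),
                    a = "A", b = "C")
  bc <- make_series(rep(800, 8), a = "B", b = "C")
  ev <- detect_approaches(list(ab, ac, bc))
  expect_equal(nrow(ev), 0)
  # a later clean approach on one dyad survives
  ab2 <- make_series(c(400, 310, 220, 130, 140, 150, 500, 400, 300, 180),
                     a = "A", b = "B")
  ev2 <- detect_approaches(list(ab2, bc))
  expect_equal(nrow(ev2), 2)
})

test_that("retreats are linked, classified by speed, and unlinked rises ignored", {
  s_high <- make_series(c(400, 310, 220, 130, 230, 330, 340, 350))
  out <- detect_agonistic_events(list(s_high))
  expect_equal(out$kind, c("approach", "high_retreat"))
  rt <- out[out$kind == "high_retreat", ]
  expect_equal(rt$displacement_cm, 200)
  expect_equal(rt$mean_speed_cm_s, 100)
  expect_equal(rt$linked_id, out$event_id[out$kind == "approach"])

  s_low <- make_series(c(400, 310, 220, 130, 180, 235, 240, 245))
  out2 <- detect_agonistic_events(list(s_low))
  expect_equal(out2$kind, c("approach", "low_retreat"))
  expect_equal(out2$displacement_cm[2], 105)
  expect_equal(out2$mean_speed_cm_s[2], 52.5)

  # a rise with no approach within the preceding 3 s is not a retreat
  s_rise <- make_series(c(150, 150, 150, 150, 260, 370, 480))
  expect_equal(nrow(detect_agonistic_events(list(s_rise))), 0)
})

test_that("at most one retreat links per approach, the earliest qualifying", {
  s <- make_series(c(400, 310, 220, 130, 240, 350, 460, 570))
  out <- detect_agonistic_events(list(s))
  rt <- out[grepl("retreat", out$kind), ]
  expect_equal(nrow(rt), 1)
  expect_equal(rt$t_start, 3)
})

test_that("the per-step speed rule is stricter than the window-mean rule", {
  # steps of -90, -80, -100: window mean 90 >= 85 but one step at 80 fails
  s <- make_series(c(450, 360, 280, 180))
  expect_equal(nrow(detect_approaches(list(s), speed_rule = "window")), 1)
  ev_step <- detect_approaches(list(s), speed_rule = "step")
  # only sub-windows with every step >= 85 cm/s survive; none drops >= 100
  # to below 200 with all steps fast here except the last single step
  expect_true(nrow(ev_step) <= 1)
  if (nrow(ev_step) == 1) expect_gte(-ev_step$displacement_cm /
                                       (ev_step$t_end - ev_step$t_start), 85)
})

test_that("event rates and unit conversions reproduce simple arithmetic", {
  expect_equal(event_rate(9151, 1, 406), 22.54)
  expect_equal(event_rate(919, 1, 406), 2.26)
  expect_equal(event_rate(0, 8, 10), 0)
  expect_equal(event_rate(100, 8, 2.5), 5)
  expect_error(event_rate(10, 8, 0), "tracking_hours")
  expect_equal(cm_s_to_km_h(89), 3.2)
  expect_equal(cm_s_to_km_h(110), 3.96)
  expect_equal(cm_s_to_km_h(0), 0)
  expect_equal(cm_s_to_km_h(100, digits = NULL), 3.6)
})

test_that("detection counts are invariant to the dyad's id ordering", {
  d <- c(400, 310, 220, 130, 230, 330)
  s1 <- make_series(d, a = "A", b = "B")
  s2 <- make_series(d, a = "B", b = "A")
  e1 <- detect_agonistic_events(list(s1))
  e2 <- detect_agonistic_events(list(s2))
  expect_equal(e1[, c("kind", "a", "b", "t_start", "t_end")],
               e2[, c("kind", "a", "b", "t_start", "t_end")])
})

test_that("scripted episodes are recovered exactly from a noise-free simulation", {
  sco <- study_scenario("field", n_agents = 6, duration_s = 2400, seed = 52L,
                        approach_rate_per_horse_hour = 6,
                        noise = noise_off())
  sim <- simulate_herd(sco$sim)
  td <- trajectories_to_distances(sim)
  cl <- clean_distances(td$distances, sco$enclosure)
  ev <- detect_agonistic_events(cl$series)
  tru <- sim$ground_truth$events
  expect_gt(length(unique(tru$event_id)), 3)
  rec <- evaluate_event_recovery(ev, tru)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
  # every retreat is linked to an approach that precedes it
  rts <- ev[grepl("retreat", ev$kind), ]
  aps <- ev[ev$kind == "approach", ]
  expect_true(all(rts$linked_id %in% aps$event_id))
  expect_true(all(rts$t_start >= aps$t_end[match(rts$linked_id,
                                                 aps$event_id)]))
})
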