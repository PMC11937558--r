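enc_3015 <- enclosure_config(30, 15, n_horses = 8, tracking_hours = 2)

test_that("CSV loading parses timestamps, rejects unknown ids and malformed rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,sensor_a,sensor_b,distance_cm",
    "2024-06-01T06:00:00Z,A,B,100",
    "2024-06-01T06:00:01Z,A,B,110",
    "2024-06-01T06:00:02Z,B,A,120",
    "2024-06-01T06:00:03Z,A,X,130",
    "not-a-time,A,B,140"), path)
  out <- load_distance_csv(path, roster = c("A", "B"))
  expect_equal(nrow(out$data), 3)
  expect_equal(unname(out$rejected["unknown_id"]), 1)
  expect_equal(unname(out$rejected["malformed"]), 1)
  expect_equal(diff(out$data$t[1:2]), 1)
})

test_that("empty or malformed files error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp,sensor_a,sensor_b,distance_cm", path)
  expect_error(load_distance_csv(path, "A"), "empty")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path2)
  expect_error(load_distance_csv(path2, "A"), "missing columns")
  expect_error(load_distance_csv("no/such/file.csv", "A"), "not found")
})

test_that("range filter removes beyond-diagonal and sub-5 cm readings", {
  expect_equal(max_theoretical_cm(enc_3015), 100 * sqrt(30^2 + 15^2))
  s <- data.frame(t = 0:3, d = c(3400, 3, 1000, 3354))
  out <- filter_range(s, enc_3015)
  # diagonal ~3354.1 cm: 3400 out, 3 out, 1000 and 3354 in
  expect_equal(out$d, c(1000, 3354))
  expect_equal(attr(out, "removed"), 2)
})

test_that("frozen filter drops runs strictly longer than the window", {
  s12 <- data.frame(t = 0:14, d = c(500, rep(700, 12), 600, 650))
  out <- filter_frozen(s12, window_s = 10)
  expect_equal(out$d, c(500, 600, 650))
  expect_equal(attr(out, "removed"), 12)

  s10 <- data.frame(t = 0:11, d = c(500, rep(700, 10), 600))
  expect_equal(nrow(filter_frozen(s10, window_s = 10)), 12)

  alt <- data.frame(t = 0:19, d = rep(c(700, 701), 10))
  expect_equal(nrow(filter_frozen(alt, window_s = 10)), 20)
})

test_that("feeder filter removes samples only when both animals are near", {
  s <- data.frame(t = 0:2, d = c(400, 420, 440))
  fa <- data.frame(t = 0:2, d = c(250, 250, 900))
  fb <- data.frame(t = 0:2, d = c(280, 900, 250))
  out <- filter_feeder(s, fa, fb, radius_cm = 300)
  expect_equal(out$t, c(1, 2))  # only t = 0 has both within 3 m
  expect_equal(attr(out, "removed"), 1)
  expect_warning(out2 <- filter_feeder(s, NULL, NULL), "feeder")
  expect_equal(nrow(out2), 3)
})

test_that("feeder lookup uses the nearest reading within one second", {
  s <- data.frame(t = c(10, 20), d = c(400, 400))
  fa <- data.frame(t = c(9.6, 19), d = c(250, 250))
  fb <- data.frame(t = c(10.4, 15), d = c(250, 250))  # 15 is 5 s from 20
  out <- filter_feeder(s, fa, fb)
  expect_equal(out$t, 20)
})

test_that("technical replicates average per timestamp with one-sided retention", {
  ab <- data.frame(t = c(0, 1, 2), d = c(100, 200, 300))
  ba <- data.frame(t = c(0, 2, 3), d = c(110, 320, 400))
  ser <- average_replicates(ab, ba, a = "B", b = "A")
  expect_s3_class(ser, "distance_series")
  expect_equal(ser$dyad, c("A", "B"))
  expect_equal(ser$t, 0:3)
  expect_equal(ser$d, c(105, 200, 310, 400))
})

test_that("filters are idempotent", {
  withr::local_seed(5)
  d <- c(round(runif(200, 0, 4000)), rep(777, 15), round(runif(50, 0, 4000)))
  s <- data.frame(t = seq_along(d) - 1, d = d)
  f1 <- filter_range(s, enc_3015)
  expect_equal(filter_range(f1, enc_3015)$d, f1$d)
  g1 <- filter_frozen(s)
  expect_equal(filter_frozen(g1)$d, g1$d)
})

test_that("duplicate timestamps within a channel collapse by mean", {
  raw <- data.frame(t = c(0, 0, 1, 1, 2), a = "A", b = "B",
                    d = c(100, 200, 300, 300, 500))
  out <- clean_distances(raw, enc_3015)
  ser <- out$series[["A|B"]]
  expect_equal(ser$t, 0:2)
  expect_equal(ser$d, c(150, 300, 500))
})

test_that("cleaning report accounts for every raw sample", {
  px <- shared_paddock()
  rep_ <- px$clean$report
  expect_true(all(rep_$raw == rep_$removed_range + rep_$removed_frozen +
                    rep_$removed_feeder + rep_$kept_channel))
  # per-dyad averaged series never exceeds the per-channel retention
  expect_true(all(rep_$kept_averaged * 2 >= rep_$kept_channel))
  expect_true(all(rep_$kept_averaged <= rep_$raw))
})

test_that("cleaned series respect the distance-series invariants", {
  px <- shared_paddock()
  for (s in px$clean$series) {
    expect_true(all(diff(s$t) > 0))
    expect_true(all(s$d >= 5))
    expect_true(all(s$d <= max_theoretical_cm(px$scenario$enclosure)))
  }
})

test_that("range and frozen filters remove exactly the injected artifacts", {
  sco <- study_scenario("paddock", n_agents = 4, duration_s = 900,
                        seed = 88L)
  sim <- simulate_herd(sco$sim)
  nz <- noise_config(jitter_sd_cm = 2, replicate_sd_cm = 3, p_spike = 0.01,
                     p_under5 = 0.005,
                     frozen_segments = list(
                       list(a = "H01", b = "H03", t_start = 100,
                            length_s = 14),
                       list(a = "H02", b = "H04", t_start = 400,
                            length_s = 12)))
  td <- trajectories_to_distances(sim, noise = nz, seed = 12L)
  art <- td$artifacts
  expect_gt(nrow(art), 50)
  dd <- td$distances
  dd <- dd[dd$b != "FEEDER", ]
  enc <- sco$enclosure
  chan_key <- paste(dd$a, dd$b, sep = "->")
  art_chan <- split(art, paste(art$a, art$b, sep = "->"))
  for (ck in unique(chan_key)) {
    ch <- dd[chan_key == ck, c("t", "d")]
    ends <- strsplit(ck, "->", fixed = TRUE)[[1]]
    a1 <- art[art$a == ends[1] & art$b == ends[2] &
                art$class %in% c("spike", "under5"), ]
    a_frozen <- art[((art$a == ends[1] & art$b == ends[2]) |
                       (art$a == ends[2] & art$b == ends[1])) &
                      art$class == "frozen", ]
    r1 <- filter_range(ch, enc)
    removed_range <- setdiff(ch$t, r1$t)
    expect_setequal(removed_range, a1$t)
    r2 <- filter_frozen(r1)
    removed_frozen <- setdiff(r1$t, r2$t)
    expect_setequal(removed_frozen, a_frozen$t)
  }
})
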