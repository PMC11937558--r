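# Shared fixtures: tiny hand-built series and reference implementations used
# as independent oracles.

# distance_series from a plain vector at 1 Hz
make_series <- function(d, t = seq_along(d) - 1, a = "A", b = "B") {
  distance_series(a, b, t, d)
}

# a hand-rolled herd_sim with fully specified trajectories (metres), for
# exercising the sensor model without movement randomness
make_static_sim <- function(x, y, ids = sprintf("H%02d", seq_len(ncol(x))),
                            length_m = 30, width_m = 15, feeder_xy = NULL,
                            noise = noise_off(), seed = 1L) {
  cfg <- sim_config(length_m, width_m, n_agents = ncol(x),
                    duration_s = max(nrow(x), 60), seed = seed, ids = ids,
                    feeder_xy = feeder_xy, noise = noise)
  cfg$duration_s <- nrow(x)  # allow short fixture runs
  structure(list(x = x, y = y, ids = ids, config = cfg,
                 ground_truth = list(events = NULL, skipped_events = NULL)),
            class = "herd_sim")
}

# independent centrality oracle: path counting via adjacency-matrix powers
# (walks of length k between s and t equal shortest-path counts when k is
# the shortest-path length)
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  pow <- vector("list", max(n - 1, 1))
  pow[[1]] <- adj
  if (n > 2) for (k in 2:(n - 1)) pow[[k]] <- pow[[k - 1]] %*% adj
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (k in seq_len(n - 1)) {
    newly <- is.infinite(D) & pow[[k]] > 0
    D[newly] <- k
  }
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s != t && is.finite(D[s, t])) sigma[s, t] <- pow[[D[s, t]]][s, t]
  }
  btw <- numeric(n); clo <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    if (n >= 3) {
      for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
        if (s == v || t == v || !is.finite(D[s, t])) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    btw[v] <- acc
    reach <- D[v, -v]
    reach <- reach[is.finite(reach)]
    clo[v] <- if (length(reach) && sum(reach) > 0) 1 / sum(reach) else 0
  }
  list(degree = as.integer(rowSums(adj)), betweenness = btw, closeness = clo)
}

# random symmetric binary adjacency
random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, p)
  adj + t(adj)
}

# small simulated paddock shared by several test files (built once per run)
shared_paddock <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sco <- study_scenario("paddock", n_agents = 6, duration_s = 1800,
                            seed = 421L)
      sim <- simulate_herd(sco$sim)
      td <- trajectories_to_distances(sim)
      cl <- clean_distances(td$distances, sco$enclosure)
      cache <<- list(scenario = sco, sim = sim, raw = td, clean = cl)
    }
    cache
  }
})
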