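path_adjacency <- function(n) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1
  adj
}

test_that("mean distance matrix is symmetric with per-dyad arithmetic means", {
  series <- list(make_series(rep(500, 10), a = "A", b = "B"),
                 make_series(c(400, 600), a = "A", b = "C"),
                 make_series(rep(900, 4), a = "B", b = "C"))
  m <- mean_distance_matrix(series, c("A", "B", "C"))
  expect_equal(m["A", "B"], 500)
  expect_equal(m["A", "C"], 500)
  expect_equal(m["B", "C"], 900)
  expect_true(isSymmetric(m))
  expect_warning(mean_distance_matrix(series[1:2], c("A", "B", "C")),
                 "no retained samples")
  expect_error(mean_distance_matrix(series, c("A", "B")), "at least 3")
})

test_that("binarization thresholds at the median with a strict below rule", {
  m <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m["A", "B"] <- m["B", "A"] <- 200
  m["A", "C"] <- m["C", "A"] <- 400
  m["B", "C"] <- m["C", "B"] <- 600
  bn <- binarize_network(m)
  expect_equal(bn$threshold_cm, 400)
  expect_equal(sum(bn$adjacency) / 2, 1)
  expect_equal(bn$adjacency["A", "B"], 1)

  m_eq <- matrix(500, 4, 4); diag(m_eq) <- 0
  expect_warning(bn2 <- binarize_network(m_eq), "empty graph")
  expect_equal(sum(bn2$adjacency), 0)
})

test_that("edge count equals the number of dyads strictly below the median", {
  withr::local_seed(21)
  for (i in 1:15) {
    n <- sample(4:9, 1)
    vals <- sample(100:2000, n * (n - 1) / 2, replace = TRUE)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    bn <- binarize_network(m)
    expect_equal(sum(bn$adjacency) / 2, sum(vals < median(vals)))
  }
})

test_that("centralities on a path graph match hand enumeration", {
  cent <- graph_centralities(path_adjacency(4))
  expect_equal(cent$degree, c(1, 2, 2, 1))
  expect_equal(cent$betweenness, c(0, 2, 2, 0))
  expect_equal(cent$closeness, c(1 / 6, 1 / 4, 1 / 4, 1 / 6))
})

test_that("a hub tied to its whole 6-node component scores closeness 0.2", {
  adj <- matrix(0, 6, 6)
  adj[1, 2:6] <- adj[2:6, 1] <- 1
  cent <- graph_centralities(adj)
  expect_equal(cent$degree[1], 5)
  expect_equal(cent$closeness[1], 0.2)
  expect_equal(cent$betweenness[1], choose(5, 2))
  expect_equal(cent$closeness[2], 1 / (1 + 4 * 2))
})

test_that("an isolated node scores zero on all three centralities", {
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- 1
  cent <- graph_centralities(adj)
  expect_equal(unlist(cent[3, c("degree", "betweenness", "closeness")],
                      use.names = FALSE), c(0, 0, 0))
})

test_that("centralities match the path-counting oracle on all 4-node graphs", {
  ut <- which(upper.tri(matrix(0, 4, 4)))
  for (code in 0:63) {
    adj <- matrix(0, 4, 4)
    adj[ut] <- as.integer(intToBits(code))[1:6]
    adj <- adj + t(adj)
    mine <- graph_centralities(adj)
    orc <- oracle_centralities(adj)
    expect_equal(mine$degree, orc$degree)
    expect_equal(mine$betweenness, orc$betweenness)
    expect_equal(mine$closeness, orc$closeness)
  }
})

test_that("centralities match the oracle on random graphs up to 7 nodes", {
  withr::local_seed(99)
  for (i in 1:120) {
    n <- sample(5:7, 1)
    adj <- random_adjacency(n, p = runif(1, 0.15, 0.8))
    mine <- graph_centralities(adj)
    orc <- oracle_centralities(adj)
    expect_equal(mine$betweenness, orc$betweenness)
    expect_equal(mine$closeness, orc$closeness)
  }
})

test_that("relabelling nodes permutes centralities identically", {
  withr::local_seed(7)
  adj <- random_adjacency(6, 0.5)
  perm <- sample(6)
  c1 <- graph_centralities(adj)
  c2 <- graph_centralities(adj[perm, perm])
  expect_equal(c2$degree, c1$degree[perm])
  expect_equal(c2$betweenness, c1$betweenness[perm])
  expect_equal(c2$closeness, c1$closeness[perm])
})

test_that("adding an edge never lowers a degree nor lengthens a shortest path", {
  withr::local_seed(13)
  shortest_paths <- function(adj) {
    n <- nrow(adj)
    D <- matrix(Inf, n, n); diag(D) <- 0
    D[adj == 1] <- 1
    for (k in 1:n) for (i in 1:n) for (j in 1:n) {
      if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
    }
    D
  }
  for (rep_ in 1:10) {
    adj <- random_adjacency(6, 0.3)
    off <- which(adj == 0 & upper.tri(adj))
    if (!length(off)) next
    pick <- sample(length(off), 1)
    adj2 <- adj
    adj2[off[pick]] <- 1
    adj2 <- adj2 + t(adj2) - adj2 * t(adj2)  # keep symmetric binary
    adj2[adj2 > 1] <- 1
    adj2 <- pmax(adj2, t(adj2))
    expect_true(all(graph_centralities(adj2)$degree >=
                      graph_centralities(adj)$degree))
    expect_true(all(shortest_paths(adj2) <= shortest_paths(adj)))
  }
})

test_that("graph export round-trips through GraphML and edge lists", {
  series <- list(make_series(rep(200, 5), a = "A", b = "B"),
                 make_series(rep(400, 5), a = "A", b = "C"),
                 make_series(rep(600, 5), a = "B", b = "C"))
  net <- build_social_network(series, c("A", "B", "C"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  csv <- withr::local_tempfile(fileext = ".csv")
  g <- export_graph(net, gml, csv)
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 1)
  g2 <- igraph::read_graph(gml, format = "graphml")
  adj2 <- as.matrix(igraph::as_adjacency_matrix(g2))
  expect_equal(unname(adj2), unname(net$adjacency))
  el <- read.csv(csv)
  expect_equal(nrow(el), 1)
  expect_equal(el$mean_distance_cm, 200)

  # empty graph still exports a valid file
  m_eq <- matrix(500, 3, 3); diag(m_eq) <- 0
  rownames(m_eq) <- colnames(m_eq) <- c("A", "B", "C")
  suppressWarnings(bn <- binarize_network(m_eq))
  net0 <- structure(list(mean_distance = m_eq, threshold_cm = bn$threshold_cm,
                         adjacency = bn$adjacency,
                         centralities = graph_centralities(bn$adjacency),
                         roster = c("A", "B", "C")),
                    class = "social_network")
  gml0 <- withr::local_tempfile(fileext = ".graphml")
  g0 <- export_graph(net0, gml0)
  expect_equal(igraph::gsize(g0), 0)
  expect_true(file.exists(gml0))
})

test_that("a simulated group yields a median-threshold network with half the dyads", {
  px <- shared_paddock()
  net <- build_social_network(px$clean$series, px$sim$ids)
  n <- length(px$sim$ids)
  n_dyads <- n * (n - 1) / 2
  expect_lte(sum(net$adjacency) / 2, floor(n_dyads / 2))
  expect_equal(net$centralities$degree,
               as.integer(rowSums(net$adjacency)))
})
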