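# Random symmetric nonnegative weight matrix with labels.
rand_w <- function(n = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("n", 1:n), paste0("n", 1:n))
  m / max(m)
}

# Binary ring lattice, each node connected to `k` nearest neighbours.
ring_lattice <- function(n, k) {
  w <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  for (d in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      j <- ((i + d - 1) %% n) + 1
      w[i, j] <- w[j, i] <- 1
    }
  }
  w
}

test_that("graph construction zeroes negatives and normalizes", {
  r <- matrix(c(0, 0.5, -0.3, 0.5, 0, 0.25, -0.3, 0.25, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  w <- as_weighted_graph(r)
  expect_equal(max(w), 1)
  expect_equal(w["a", "c"], 0)
  expect_equal(diag(w), c(a = 0, b = 0, c = 0))
})

test_that("proportional thresholding keeps the right edges", {
  w <- rand_w(44, seed = 2)
  wt <- proportional_threshold(w, 0.5)
  expect_equal(sum(wt[upper.tri(wt)] > 0), floor(0.5 * 44 * 43 / 2))
  expect_equal(sum(wt[upper.tri(wt)] > 0), 473)

  # nestedness across increasing proportions
  e10 <- proportional_threshold(w, 0.10) > 0
  e30 <- proportional_threshold(w, 0.30) > 0
  expect_true(all(e30[e10]))

  # all-equal weights: deterministic reproducible tie-break
  we <- matrix(1, 10, 10, dimnames = list(paste0("n", 1:10), paste0("n", 1:10)))
  diag(we) <- 0
  t1 <- proportional_threshold(we, 0.3)
  t2 <- proportional_threshold(we, 0.3)
  expect_identical(t1, t2)
  expect_equal(sum(t1[upper.tri(t1)] > 0), floor(0.3 * 45))

  expect_error(proportional_threshold(w, 0), "in \\(0, 1\\]")
})

test_that("null models preserve degrees and connectedness", {
  w <- proportional_threshold(rand_w(25, seed = 3), 0.3)
  nm <- null_models(w, n_null = 5, seed = 4)
  deg <- rowSums(w > 0)
  for (r in nm$random) {
    expect_equal(rowSums(r > 0), deg)
    g <- igraph::graph_from_adjacency_matrix(r > 0, mode = "undirected")
    expect_true(igraph::is_connected(g))
    expect_equal(sort(r[upper.tri(r) & r > 0]),
                 sort(w[upper.tri(w) & w > 0]))
  }
  # lattice reference keeps the weight multiset and edge count
  expect_equal(sort(nm$lattice[upper.tri(nm$lattice) & nm$lattice > 0]),
               sort(w[upper.tri(w) & w > 0]))
})

test_that("rewired nulls break up clustering of modular graphs", {
  # two dense modules joined by a bridge: strong clustering
  n <- 20
  w <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  w[1:10, 1:10] <- 1
  w[11:20, 11:20] <- 1
  diag(w) <- 0
  w[10, 11] <- w[11, 10] <- 1
  nm <- null_models(w, n_null = 10, seed = 5)
  c_null <- mean(vapply(nm$random, function(x) {
    mean(onnela_clustering(x))
  }, 0))
  expect_lt(c_null, mean(onnela_clustering(w)))
})

test_that("small-world propensity hits its limiting values", {
  # ring lattice: dC ~ 0, dL ~ 1, SWP ~ 1 - sqrt(1/2)
  wl <- ring_lattice(44, 8)
  sl <- small_world_propensity(wl, n_null = 10, seed = 6)
  expect_lt(sl$delta_C, 0.1)
  expect_gt(sl$delta_L, 0.9)
  expect_lt(abs(sl$swp - (1 - sqrt(0.5))), 0.05)

  # dense uniform random graph: dC ~ 1, dL ~ 0, same SWP
  wr <- proportional_threshold(rand_w(44, seed = 7), 0.25)
  sr <- small_world_propensity(wr, n_null = 10, seed = 8)
  expect_gt(sr$delta_C, 0.9)
  expect_lt(sr$delta_L, 0.1)
  expect_lt(abs(sr$swp - (1 - sqrt(0.5))), 0.05)

  # Watts-Strogatz rewiring 0.1: genuinely small-world (mean over
  # realizations to damp Monte-Carlo noise of single graphs)
  set.seed(9)
  swp_ws <- replicate(5, {
    g <- igraph::sample_smallworld(1, 44, 4, 0.1)
    ws <- igraph::as_adjacency_matrix(g, sparse = FALSE) * 1
    dimnames(ws) <- list(paste0("n", 1:44), paste0("n", 1:44))
    diag(ws) <- 0
    small_world_propensity(ws, n_null = 20,
                           seed = sample.int(1e6, 1))$swp
  })
  expect_gt(mean(swp_ws), 0.6)
})

test_that("SWP components stay in [0, 1] across random inputs", {
  set.seed(11)
  for (k in 1:25) {
    w <- proportional_threshold(rand_w(16, seed = 100 + k), 0.4)
    if (!attr(w, "connected")) next
    s <- small_world_propensity(w, n_null = 5, seed = 200 + k)
    expect_true(s$delta_C >= 0 && s$delta_C <= 1)
    expect_true(s$delta_L >= 0 && s$delta_L <= 1)
    expect_true(s$swp >= 0 && s$swp <= 1)
  }
})

test_that("local metrics match brute-force strength and participation", {
  w <- proportional_threshold(rand_w(15, seed = 12), 0.5)
  part <- louvain_partition(w, restarts = 10, seed = 13)
  lm <- local_metrics(w, part)
  orc <- oracle_local(w, part[rownames(w)])
  expect_equal(lm$strength, orc$strength, tolerance = 1e-12)
  expect_equal(lm$participation, orc$participation, tolerance = 1e-12)

  # star graph: center strength is the sum of spoke weights
  n <- 6
  ws <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  ws[1, 2:n] <- ws[2:n, 1] <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  part1 <- stats::setNames(rep(1L, n), rownames(ws))
  lms <- local_metrics(ws, part1)
  expect_equal(lms$strength[1], 3.0)
  # single module: participation 0 everywhere
  expect_equal(lms$participation, rep(0, n))

  # equal split over two modules: P = 0.5 (coefficient), 0.5 (ratio)
  w2 <- matrix(0, 3, 3, dimnames = list(c("x", "m1", "m2"),
                                        c("x", "m1", "m2")))
  w2["x", "m1"] <- w2["m1", "x"] <- 1
  w2["x", "m2"] <- w2["m2", "x"] <- 1
  p2 <- stats::setNames(c(1L, 1L, 2L), rownames(w2))
  expect_equal(local_metrics(w2, p2)$participation[1], 0.5)
  expect_equal(local_metrics(w2, p2, participation = "ratio")$participation[1],
               0.5)
})

test_that("metrics are invariant to node relabeling", {
  w <- proportional_threshold(rand_w(12, seed = 14), 0.5)
  part <- louvain_partition(w, restarts = 5, seed = 15)
  perm <- sample(12)
  wp <- w[perm, perm]
  s1 <- small_world_propensity(w, n_null = 5, seed = 16)
  s2 <- small_world_propensity(wp, n_null = 5, seed = 16)
  expect_equal(s1$C, s2$C, tolerance = 1e-12)
  expect_equal(s1$L, s2$L, tolerance = 1e-12)
  lm1 <- local_metrics(w, part)
  lm2 <- local_metrics(wp, part)
  expect_equal(lm1$strength[match(lm2$node, lm1$node)], lm2$strength,
               tolerance = 1e-12)
})

test_that("threshold averaging handles flags and the uniform grid", {
  props <- seq(0.10, 0.50, by = 0.01)
  expect_length(props, 41)
  # metric linear in p: mean equals the value at the 30% midpoint
  lin <- 2 * props + 1
  expect_equal(threshold_average(lin)$mean, 2 * 0.30 + 1)
  # constant metric passes through
  expect_equal(threshold_average(rep(3.3, 41))$mean, 3.3)
  # flagged thresholds are excluded and counted
  x <- c(NA, 1, 2, NA, 3)
  ta <- threshold_average(x)
  expect_equal(ta$mean, 2)
  expect_equal(ta$n_flagged, 2)
  expect_true(is.na(threshold_average(c(NA_real_, NA_real_))$mean))
})

test_that("the threshold-sweep wrapper averages global and local metrics", {
  ses <- quick_session(seed = 30, n_frames = 680)
  ep <- split_epochs(bandpass(ses$roi_ts, tr = ses$tr))
  r <- tanh(fc_matrix(ep$tp1))  # back to correlation scale
  diag(r) <- 0
  # denser thresholds: at sparse densities the strongly modular synthetic
  # graph disconnects (and is flagged), so the sweep is exercised where
  # the graph stays connected
  gm <- graph_metrics(r, proportions = seq(0.40, 0.50, by = 0.02),
                      n_null = 5, seed = 31)
  expect_equal(nrow(gm$global), 6)
  expect_equal(gm$n_used + gm$n_flagged, 6)
  used <- gm$global[gm$global$connected, ]
  expect_equal(unname(gm$global_mean["swp"]), mean(used$swp))
  expect_true(all(used$swp >= 0 & used$swp <= 1))
  expect_equal(gm$local_mean$node, region_labels())
  expect_true(all(gm$local_mean$strength >= 0))
  expect_true(all(gm$local_mean$participation >= 0 &
                    gm$local_mean$participation <= 1, na.rm = TRUE))
})
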