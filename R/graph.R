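#' Build a weighted brain graph from a correlation matrix
#'
#' Negative weights are set to zero (nonnegativity is required by the
#' weighted clustering and small-world definitions), the diagonal is
#' zeroed, and weights are normalized by the maximum.
#'
#' @param r Symmetric correlation (or connectivity) matrix with region
#'   dimnames; `NA` entries are treated as absent edges.
#'
#' @return Nonnegative symmetric weight matrix with max weight 1.
#' @export
as_weighted_graph <- function(r) {
  w <- as.matrix(r)
  w[is.na(w)] <- 0
  w[w < 0] <- 0
  diag(w) <- 0
  mx <- max(w)
  if (mx > 0) w <- w / mx
  w
}

#' Proportional threshold of a weighted graph
#'
#' Keeps the `floor(p * E)` strongest edges, where `E = n (n - 1) / 2` is
#' the number of possible edges. Ties are broken deterministically by
#' (weight descending, node-index pair ascending), so equal-weight graphs
#' threshold reproducibly and edge sets are nested across increasing `p`.
#' A disconnected result is flagged (attribute `connected`), not an error.
#'
#' @param w Weight matrix from [as_weighted_graph()].
#' @param p Proportion of edges to retain, in (0, 1].
#'
#' @return Thresholded weight matrix with attribute `connected`.
#' @export
proportional_threshold <- function(w, p) {
  if (p <= 0 || p > 1) stopf("p must be in (0, 1]")
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  k <- floor(p * nrow(ut))
  wt <- w[upper.tri(w)]
  ord <- order(-wt, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(k, sum(wt > 0)))]
  out <- matrix(0, n, n, dimnames = dimnames(w))
  out[cbind(ut[keep, 1], ut[keep, 2])] <- wt[keep]
  out <- out + t(out)
  g <- igraph::graph_from_adjacency_matrix(out, mode = "undirected",
                                           weighted = TRUE)
  attr(out, "connected") <- igraph::is_connected(g)
  out
}

# Ring-lattice reference: same nodes and edge count, edges filled in order
# of increasing ring distance; observed weights are reassigned so that the
# strongest weights sit on the shortest-range lattice edges.
lattice_reference <- function(w) {
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  ring_dist <- pmin(ut[, 2] - ut[, 1], n - (ut[, 2] - ut[, 1]))
  wt <- w[upper.tri(w)]
  m <- sum(wt > 0)
  slot <- order(ring_dist, ut[, 1], ut[, 2])[seq_len(m)]
  out <- matrix(0, n, n, dimnames = dimnames(w))
  out[cbind(ut[slot, 1], ut[slot, 2])] <- sort(wt[wt > 0], decreasing = TRUE)
  out + t(out)
}

#' Degree-preserving random null models and a lattice reference
#'
#' Random nulls preserve node count, degree sequence and connectedness via
#' igraph edge rewiring (retried until connected), with the observed
#' weight multiset reshuffled onto the rewired topology. The lattice
#' reference reorders the weights onto a ring-lattice topology of matching
#' density (strongest weights at shortest range).
#'
#' @param w Connected thresholded weight matrix.
#' @param n_null Number of random nulls (default 20).
#' @param seed RNG seed.
#' @param max_retry Rewiring retries per null before erroring.
#'
#' @return List: `random` (list of weight matrices), `lattice` (one
#'   matrix).
#' @export
null_models <- function(w, n_null = 20, seed = 1, max_retry = 50) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  if (!igraph::is_connected(g)) stopf("graph must be connected")
  m <- igraph::ecount(g)
  wt <- igraph::E(g)$weight
  with_seed(seed, {
    random <- lapply(seq_len(n_null), function(k) {
      for (try in seq_len(max_retry)) {
        gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 20 * m))
        if (igraph::is_connected(gr)) {
          adj <- igraph::as_adjacency_matrix(gr, sparse = FALSE)
          ut <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
          out <- matrix(0, nrow(w), nrow(w), dimnames = dimnames(w))
          out[ut] <- sample(wt)
          return(out + t(out))
        }
      }
      stopf("failed to produce a connected rewired null in %d tries", max_retry)
    })
    list(random = random, lattice = lattice_reference(w))
  })
}

# Onnela weighted clustering coefficient per node (weights pre-normalized
# by the matrix maximum); nodes with binary degree < 2 get 0.
onnela_clustering <- function(w) {
  mx <- max(w)
  wn <- if (mx > 0) w / mx else w
  w13 <- wn^(1 / 3)
  num <- diag(w13 %*% w13 %*% w13)
  k <- rowSums(w > 0)
  c_i <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  names(c_i) <- rownames(w)
  c_i
}

# Characteristic path length with distance = 1 / weight; NA if any pair
# is unreachable.
char_path_length <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::ecount(g) == 0) return(NA_real_)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  d <- d[upper.tri(d)]
  if (any(!is.finite(d))) return(NA_real_)
  mean(d)
}

#' Small-world propensity of a weighted graph
#'
#' Density-independent small-worldness: the deviations of the observed
#' mean clustering coefficient and characteristic path length from lattice
#' and random references,
#' `dC = (C_latt - C_obs) / (C_latt - C_rand)` and
#' `dL = (L_obs - L_rand) / (L_latt - L_rand)`, each clipped to `[0, 1]`,
#' combined as `SWP = 1 - sqrt((dC^2 + dL^2) / 2)`. A lattice therefore
#' scores `dC = 0, dL = 1` and a random graph `dC = 1, dL = 0`, both with
#' `SWP = 1 - sqrt(1/2)`; genuinely small-world graphs approach 1.
#'
#' @param w Connected thresholded weight matrix.
#' @param nulls Result of [null_models()] for `w` (generated if `NULL`).
#' @param n_null,seed Passed to [null_models()] when `nulls` is `NULL`.
#'
#' @return List: `C`, `L` (observed), `C_rand`, `L_rand`, `C_latt`,
#'   `L_latt`, `delta_C`, `delta_L`, `swp`. Degenerate normalization
#'   (`C_latt = C_rand`) yields `NA` with a warning.
#' @export
small_world_propensity <- function(w, nulls = NULL, n_null = 20, seed = 1) {
  if (is.null(nulls)) nulls <- null_models(w, n_null = n_null, seed = seed)
  c_obs <- mean(onnela_clustering(w))
  l_obs <- char_path_length(w)
  c_rand <- mean(vapply(nulls$random, function(x) mean(onnela_clustering(x)), 0))
  l_rand <- mean(vapply(nulls$random, char_path_length, 0), na.rm = TRUE)
  c_latt <- mean(onnela_clustering(nulls$lattice))
  l_latt <- char_path_length(nulls$lattice)
  if (!is.finite(c_latt - c_rand) || abs(c_latt - c_rand) < 1e-12) {
    warnf("degenerate clustering normalization (C_latt = C_rand)")
    dc <- NA_real_
  } else {
    dc <- clip((c_latt - c_obs) / (c_latt - c_rand), 0, 1)
  }
  if (!is.finite(l_latt - l_rand) || abs(l_latt - l_rand) < 1e-12) {
    dl <- NA_real_
  } else {
    dl <- clip((l_obs - l_rand) / (l_latt - l_rand), 0, 1)
  }
  swp <- 1 - sqrt((dc^2 + dl^2) / 2)
  list(C = c_obs, L = l_obs, C_rand = c_rand, L_rand = l_rand,
       C_latt = c_latt, L_latt = l_latt, delta_C = dc, delta_L = dl,
       swp = swp)
}

#' Modularity-maximizing module partition
#'
#' Louvain community detection, best modularity over seeded restarts with
#' permuted vertex orders. Typically run on a group-mean baseline graph
#' and held fixed across conditions, so that participation changes
#' reflect connectivity rather than partition changes.
#'
#' @param w Weight matrix.
#' @param restarts Number of restarts (default 50).
#' @param seed RNG seed.
#'
#' @return Named integer vector of module assignments.
#' @export
louvain_partition <- function(w, restarts = 50, seed = 1) {
  n <- nrow(w)
  with_seed(seed, {
    best <- NULL
    best_q <- -Inf
    for (k in seq_len(restarts)) {
      ord <- sample.int(n)
      g <- igraph::graph_from_adjacency_matrix(w[ord, ord],
                                               mode = "undirected",
                                               weighted = TRUE)
      cl <- igraph::cluster_louvain(g)
      q <- igraph::modularity(cl)
      if (q > best_q) {
        best_q <- q
        memb <- integer(n)
        memb[ord] <- igraph::membership(cl)
        best <- memb
      }
    }
    names(best) <- rownames(w)
    best
  })
}

#' Local weighted graph metrics
#'
#' Per-node strength (sum of connection weights), Onnela weighted
#' clustering coefficient, and participation relative to a module
#' partition. The default participation is the standard participation
#' coefficient `P_i = 1 - sum_s (kappa_is / k_i)^2`; the `"ratio"` variant
#' is the literal ratio of intermodule strength to total nodal strength.
#' Isolated nodes get strength 0, clustering 0 and `NA` participation.
#'
#' @param w Weight matrix.
#' @param partition Named module assignment covering all nodes (see
#'   [louvain_partition()]).
#' @param participation `"coefficient"` (default) or `"ratio"`.
#'
#' @return `data.frame`: `node`, `strength`, `clustering`,
#'   `participation`.
#' @export
local_metrics <- function(w, partition,
                          participation = c("coefficient", "ratio")) {
  participation <- match.arg(participation)
  labs <- rownames(w)
  if (!all(labs %in% names(partition))) stopf("partition must cover all nodes")
  part <- partition[labs]
  k <- rowSums(w)
  mods <- sort(unique(part))
  kappa <- vapply(mods, function(s) rowSums(w[, part == s, drop = FALSE]),
                  numeric(nrow(w)))
  p_i <- rep(NA_real_, nrow(w))
  nz <- k > 0
  if (participation == "coefficient") {
    p_i[nz] <- 1 - rowSums((kappa[nz, , drop = FALSE] / k[nz])^2)
  } else {
    own <- kappa[cbind(seq_len(nrow(w)), match(part, mods))]
    p_i[nz] <- 1 - own[nz] / k[nz]
  }
  data.frame(node = labs, strength = k, clustering = onnela_clustering(w),
             participation = p_i, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Graph metrics across a proportional threshold range
#'
#' Evaluates global (C, L, delta-C, delta-L, SWP) and local (strength,
#' clustering, participation) metrics at each proportional threshold
#' (default 10-50% in 1% steps, 41 graphs) and averages across thresholds;
#' disconnected thresholds are flagged and excluded from the average, with
#' the exclusion count reported.
#'
#' @param r Correlation matrix (passed through [as_weighted_graph()]).
#' @param proportions Thresholds (default `seq(0.10, 0.50, by = 0.01)`).
#' @param partition Module partition for participation; computed by
#'   [louvain_partition()] on the full graph if `NULL`.
#' @param n_null Random nulls per threshold (default 20).
#' @param seed RNG seed.
#'
#' @return List: `global` (data.frame per threshold), `global_mean`,
#'   `local_mean` (data.frame per node), `n_used`, `n_flagged`.
#' @export
graph_metrics <- function(r, proportions = seq(0.10, 0.50, by = 0.01),
                          partition = NULL, n_null = 20, seed = 1) {
  w <- as_weighted_graph(r)
  if (is.null(partition)) partition <- louvain_partition(w, seed = seed)
  glob <- vector("list", length(proportions))
  loc <- vector("list", length(proportions))
  for (i in seq_along(proportions)) {
    p <- proportions[i]
    wt <- proportional_threshold(w, p)
    if (!attr(wt, "connected")) {
      glob[[i]] <- data.frame(p = p, C = NA, L = NA, delta_C = NA,
                              delta_L = NA, swp = NA, connected = FALSE)
      next
    }
    s <- small_world_propensity(wt, n_null = n_null, seed = sub_seed(seed, i))
    glob[[i]] <- data.frame(p = p, C = s$C, L = s$L, delta_C = s$delta_C,
                            delta_L = s$delta_L, swp = s$swp,
                            connected = TRUE)
    loc[[i]] <- local_metrics(wt, partition)
  }
  glob <- do.call(rbind, glob)
  used <- which(glob$connected)
  if (!length(used)) stopf("all thresholds flagged disconnected")
  local_mean <- Reduce(`+`, lapply(loc[used], function(x) {
    as.matrix(x[, c("strength", "clustering", "participation")])
  })) / length(used)
  local_mean <- data.frame(node = rownames(w), local_mean,
                           row.names = NULL, stringsAsFactors = FALSE)
  list(global = glob,
       global_mean = colMeans(glob[used, c("C", "L", "delta_C", "delta_L",
                                           "swp")]),
       local_mean = local_mean,
       n_used = length(used), n_flagged = sum(!glob$connected))
}

#' Arithmetic mean of a metric across thresholds
#'
#' Averages per-threshold metric values, excluding flagged (`NA`)
#' thresholds and reporting how many entered the mean.
#'
#' @param x Numeric vector of per-threshold values (`NA` = flagged).
#'
#' @return List: `mean`, `n_used`, `n_flagged`. All-flagged input yields
#'   `NA`.
#' @export
threshold_average <- function(x) {
  ok <- is.finite(x)
  list(mean = if (any(ok)) mean(x[ok]) else NA_real_,
       n_used = sum(ok), n_flagged = sum(!ok))
}
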