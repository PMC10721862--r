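# Connected-component labeling of a 3D logical array. connectivity 6
# (face), 18 (face+edge) or 26 (face+edge+corner).
label_clusters <- function(mask, connectivity = 6) {
  d <- dim(mask)
  if (length(d) != 3) stopf("mask must be 3D")
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- switch(as.character(connectivity),
                 "6" = offs[ord == 1, ],
                 "18" = offs[ord <= 2, ],
                 "26" = offs,
                 stopf("connectivity must be 6, 18 or 26"))
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  inmask <- array(FALSE, d)
  inmask[mask] <- TRUE
  for (v in seq_len(nrow(idx))) {
    if (lab[idx[v, 1], idx[v, 2], idx[v, 3]] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(idx[v, ], 1)
    lab[idx[v, 1], idx[v, 2], idx[v, 3]] <- nxt
    while (nrow(queue)) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        nb <- cur + c(offs$dx[k], offs$dy[k], offs$dz[k])
        if (any(nb < 1) || any(nb > d)) next
        if (inmask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  lab
}

#' Cluster-extent FWE correction by permutation
#'
#' Voxel-wise statistic maps are thresholded at a cluster-defining
#' threshold (CDT, in t units); contiguous suprathreshold voxels (default
#' 6-connectivity, configurable to 18/26) form clusters whose extents are
#' compared with the permutation null of the maximum cluster extent.
#' Two permutation schemes: `"paired"` computes a one-sample t across
#' subject difference maps and sign-flips the maps under the null;
#' `"correlation"` computes voxel-wise Spearman correlations with a
#' covariate, transforms them with [rho_to_t()], and shuffles the
#' covariate under the null (so both correlation signs are captured).
#'
#' @param maps List of per-subject 3D arrays (difference maps or metric
#'   maps), all sharing `mask`.
#' @param cdt Cluster-defining threshold in t units.
#' @param mask 3D logical array; defaults to voxels finite in all maps.
#' @param type `"paired"` or `"correlation"`.
#' @param covariate Numeric vector (one per map) for `"correlation"`.
#' @param n_perm Number of permutations (default 1000).
#' @param connectivity 6, 18 or 26.
#' @param seed RNG seed.
#'
#' @return List of class `cluster_inference`: `clusters` (data.frame with
#'   `extent` and `p_fwe`), `label_map`, `stat_map`, `null_max_extent`,
#'   `cdt`.
#' @export
cluster_correct <- function(maps, cdt, mask = NULL,
                            type = c("paired", "correlation"),
                            covariate = NULL, n_perm = 1000,
                            connectivity = 6, seed = 1) {
  type <- match.arg(type)
  if (!is.finite(cdt)) stopf("cdt must be finite")
  d <- dim(maps[[1]])
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(maps, function(m) is.finite(m)))
  }
  n <- length(maps)
  if (type == "correlation" && (is.null(covariate) || length(covariate) != n)) {
    stopf("covariate must have one value per map")
  }
  if (2^n < 100 && type == "paired") {
    warnf("only %d distinct sign-flips available; p-values are coarse", 2^n)
  }
  idx <- which(mask)
  y <- do.call(rbind, lapply(maps, function(m) m[idx]))  # n x voxels

  paired_t <- function(y) {
    mu <- colMeans(y)
    s <- sqrt(colSums(sweep(y, 2, mu)^2) / (nrow(y) - 1))
    ifelse(s > 0, mu / (s / sqrt(nrow(y))), 0)
  }
  corr_t <- function(y, cov) {
    ry <- apply(y, 2, rank)
    rc <- rank(cov)
    rho <- suppressWarnings(cor(ry, rc))
    rho[!is.finite(rho)] <- 0
    abs(rho) / sqrt((1 - pmin(rho^2, 1 - 1e-12)) / (nrow(y) - 2))
  }
  stat_fun <- if (type == "paired") {
    function(yy, cov) paired_t(yy)
  } else {
    function(yy, cov) corr_t(yy, cov)
  }

  max_ext <- function(stat) {
    supra <- array(FALSE, d)
    supra[idx] <- stat > cdt
    if (!any(supra)) return(0L)
    max(tabulate(label_clusters(supra, connectivity)))
  }

  stat <- stat_fun(y, covariate)
  supra <- array(FALSE, d)
  supra[idx] <- stat > cdt
  lab <- label_clusters(supra, connectivity)
  n_cl <- max(lab)
  extents <- if (n_cl > 0) tabulate(lab, n_cl) else integer(0)

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      if (type == "paired") {
        flips <- sample(c(-1, 1), n, replace = TRUE)
        max_ext(stat_fun(y * flips, covariate))
      } else {
        max_ext(stat_fun(y, sample(covariate)))
      }
    }, 0L)
  })

  clusters <- data.frame(
    cluster = seq_len(n_cl), extent = extents,
    p_fwe = vapply(extents, function(e) (1 + sum(null_max >= e)) / (n_perm + 1),
                   0)
  )
  clusters <- clusters[order(-clusters$extent), , drop = FALSE]
  stat_map <- array(NA_real_, d)
  stat_map[idx] <- stat
  structure(list(clusters = clusters, label_map = lab, stat_map = stat_map,
                 null_max_extent = null_max, cdt = cdt, n_perm = n_perm,
                 type = type),
            class = "cluster_inference")
}
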