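# Edge-wise observations: stack the upper triangles of a list of
# difference matrices into an observations x edges matrix.
edge_observations <- function(diffs) {
  labs <- rownames(diffs[[1]])
  n <- nrow(diffs[[1]])
  ut <- upper.tri(diffs[[1]])
  for (d in diffs) {
    if (!identical(rownames(d), labs)) stopf("difference matrices disagree on labels")
  }
  y <- do.call(rbind, lapply(diffs, function(d) d[ut]))
  pairs <- which(ut, arr.ind = TRUE)
  list(y = y, from = labs[pairs[, 1]], to = labs[pairs[, 2]], labels = labs)
}

# Vectorized one-way (two-level) GLM F statistic per column of y.
# Zero residual variance: F is +Inf if the group means differ, 0 otherwise.
oneway_f <- function(y, g) {
  g <- as.integer(factor(g))
  n1 <- sum(g == 1L); n2 <- sum(g == 2L); n <- n1 + n2
  m1 <- colMeans(y[g == 1L, , drop = FALSE])
  m2 <- colMeans(y[g == 2L, , drop = FALSE])
  ssb <- (n1 * n2 / n) * (m1 - m2)^2
  ssw <- colSums(y^2) - n1 * m1^2 - n2 * m2^2
  ssw <- pmax(ssw, 0)
  f <- ifelse(ssw > 0, ssb / (ssw / (n - 2)),
              ifelse(ssb > 0, Inf, 0))
  list(f = f, df = c(1, n - 2))
}

#' Edge-wise GLM F statistics for a crossover connectivity design
#'
#' One F value per edge (upper triangle) from a general linear model on the
#' per-session difference matrices. For the `"treatment"` contrast the
#' observations are the `2n` difference matrices (psilocybin and saline
#' session of every subject) and the F test compares the two conditions,
#' df `(1, 2n - 2)`. For the `"interaction"` contrast the observations are
#' the `n` within-subject (psilocybin minus saline) differences and the F
#' test compares the two groups, df `(1, n - 2)`.
#'
#' @param diffs List of difference matrices ([diff_matrix()]), one per
#'   subject and session.
#' @param condition Character vector, `"psilocybin"`/`"saline"` per entry
#'   of `diffs`.
#' @param subject Subject id per entry of `diffs`; each subject must
#'   appear once per condition (the exchange blocks).
#' @param group Optional group label per entry (required for
#'   `"interaction"`).
#' @param contrast `"treatment"` or `"interaction"`.
#'
#' @return List: `f` (named vector, one per edge), `df`, `from`, `to`,
#'   `labels`, `infinite` (logical flag vector).
#' @export
edge_f_statistics <- function(diffs, condition, subject, group = NULL,
                              contrast = c("treatment", "interaction")) {
  contrast <- match.arg(contrast)
  obs <- edge_observations(diffs)
  tab <- table(subject, condition)
  if (any(tab != 1)) {
    stopf("each subject must contribute exactly one matrix per condition")
  }
  if (contrast == "treatment") {
    res <- oneway_f(obs$y, condition)
  } else {
    if (is.null(group)) stopf("interaction contrast needs group labels")
    d <- subject_differences(obs$y, condition, subject)
    sg <- vapply(names(d$subjects), function(s) group[match(s, subject)], "")
    if (min(table(sg)) < 2) stopf("need >= 2 subjects per group")
    res <- oneway_f(d$y, sg)
  }
  names(res$f) <- paste(obs$from, obs$to, sep = "-")
  list(f = res$f, df = res$df, from = obs$from, to = obs$to,
       labels = obs$labels, infinite = !is.finite(res$f) & res$f > 0)
}

# Per-subject psilocybin-minus-saline difference of edge observations.
subject_differences <- function(y, condition, subject) {
  subj <- unique(subject)
  d <- t(vapply(subj, function(s) {
    y[subject == s & condition == "psilocybin", ] -
      y[subject == s & condition == "saline", ]
  }, numeric(ncol(y))))
  list(y = d, subjects = stats::setNames(seq_along(subj), subj))
}

#' Connected components of the suprathreshold edge graph
#'
#' Edges whose F statistic exceeds the primary threshold form a graph;
#' its connected components are the candidate networks, with extent
#' measured as edge count.
#'
#' @param f Named F vector with `from`/`to` endpoints (as returned by
#'   [edge_f_statistics()]), or that list itself.
#' @param threshold Primary threshold `F_pt` (default 7.31, the upper 1%
#'   point of F(1, 40)).
#'
#' @return List of components, each `list(edges = data.frame(from, to, f),
#'   extent, nodes)`, ordered by decreasing extent. Empty list if no edge
#'   survives.
#' @export
extract_components <- function(f, threshold = 7.31) {
  if (is.list(f) && !is.null(f$f)) {
    from <- f$from; to <- f$to; fv <- f$f
  } else {
    stopf("f must be the result of edge_f_statistics()")
  }
  if (!is.finite(threshold)) stopf("threshold must be finite")
  keep <- which(fv > threshold)
  if (!length(keep)) return(list())
  ed <- data.frame(from = from[keep], to = to[keep], f = fv[keep],
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed[, 1:2], directed = FALSE)
  comp <- igraph::components(g)
  out <- lapply(seq_len(comp$no), function(k) {
    nodes <- names(comp$membership)[comp$membership == k]
    sel <- ed$from %in% nodes & ed$to %in% nodes
    list(edges = ed[sel, , drop = FALSE], extent = sum(sel), nodes = nodes)
  })
  out[order(-vapply(out, `[[`, 0, "extent"))]
}

#' Network-based statistic with exchange-block permutation inference
#'
#' Family-wise-error-controlling inference on connected suprathreshold
#' components. Edge-wise F statistics are thresholded at `f_pt`; each
#' observed component's extent (edge count) is compared with the null
#' distribution of the maximum component extent over permutations that
#' respect the paired crossover design: for the treatment contrast,
#' condition labels are swapped only within each subject's exchange block;
#' for the interaction contrast, group labels are permuted between
#' subjects while within-subject pairs stay intact. P-values use the
#' add-one (Phipson-Smyth) correction, so the smallest attainable value is
#' `1 / (n_perm + 1)`.
#'
#' @inheritParams edge_f_statistics
#' @param f_pt Primary threshold (default 7.31).
#' @param n_perm Number of permutations (default 5000).
#' @param alpha Component-level significance level (default 0.05).
#' @param seed RNG seed.
#'
#' @return List of class `nbs_result`: `components` (each with `p_fwe`),
#'   `null_max_extent`, `f`, `f_pt`, `df`, `n_perm`.
#' @export
nbs_permutation_test <- function(diffs, condition, subject, group = NULL,
                                 contrast = c("treatment", "interaction"),
                                 f_pt = 7.31, n_perm = 5000, alpha = 0.05,
                                 seed = 1) {
  contrast <- match.arg(contrast)
  if (!is_count(n_perm) || n_perm < 1) stopf("n_perm must be >= 1")
  if (1 / (n_perm + 1) > alpha) {
    warnf("n_perm = %d cannot resolve alpha = %g (p floor %.3g)",
          n_perm, alpha, 1 / (n_perm + 1))
  }
  obs <- edge_observations(diffs)
  stat <- edge_f_statistics(diffs, condition, subject, group, contrast)
  observed <- extract_components(stat, f_pt)

  # maximum component extent = most edges in any connected component;
  # every edge lies in the component of its first endpoint
  max_extent <- function(fv, from, to) {
    keep <- which(fv > f_pt)
    if (!length(keep)) return(0L)
    g <- igraph::graph_from_data_frame(
      data.frame(from = from[keep], to = to[keep]), directed = FALSE)
    memb <- igraph::components(g)$membership
    max(tabulate(memb[from[keep]]))
  }

  null_max <- with_seed(seed, {
    if (contrast == "treatment") {
      subj <- unique(subject)
      vapply(seq_len(n_perm), function(p) {
        flip <- sample(c(TRUE, FALSE), length(subj), replace = TRUE)
        cond <- condition
        for (s in subj[flip]) {
          sel <- subject == s
          cond[sel] <- rev(cond[sel])
        }
        fv <- oneway_f(obs$y, cond)$f
        max_extent(fv, obs$from, obs$to)
      }, 0L)
    } else {
      d <- subject_differences(obs$y, condition, subject)
      sg <- vapply(names(d$subjects), function(s) group[match(s, subject)], "")
      vapply(seq_len(n_perm), function(p) {
        fv <- oneway_f(d$y, sample(sg))$f
        max_extent(fv, obs$from, obs$to)
      }, 0L)
    }
  })

  components <- lapply(observed, function(cmp) {
    cmp$p_fwe <- (1 + sum(null_max >= cmp$extent)) / (n_perm + 1)
    cmp
  })
  structure(list(components = components, null_max_extent = null_max,
                 f = stat$f, from = stat$from, to = stat$to,
                 f_pt = f_pt, df = stat$df, n_perm = n_perm, alpha = alpha),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("NBS: %d component(s), F_pt = %.2f (df %d,%d), %d permutations\n",
              length(x$components), x$f_pt, x$df[1], x$df[2], x$n_perm))
  for (k in seq_along(x$components)) {
    cmp <- x$components[[k]]
    cat(sprintf("  component %d: extent %d edges, %d nodes, p_FWE = %.4g\n",
                k, cmp$extent, length(cmp$nodes), cmp$p_fwe))
  }
  invisible(x)
}
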