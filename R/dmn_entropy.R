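#' Mean DMN connectivity and within-DMN nodal strength
#'
#' Restricts a connectivity (or difference) matrix to the 12 DMN regions
#' and returns the mean over the 66 unordered DMN pairs plus, per region,
#' the mean of its 11 edges to the rest of the DMN. By construction the
#' mean DMN connectivity equals the mean of the 12 within-DMN strengths.
#'
#' @param conn Square matrix with region dimnames (Fisher-z connectivity
#'   from [fc_matrix()] or a [diff_matrix()]).
#' @param dmn Character vector of DMN labels (default [dmn_regions()]).
#'
#' @return List: `mean` (scalar), `strength` (named vector, one per DMN
#'   region).
#' @export
dmn_connectivity <- function(conn, dmn = dmn_regions()) {
  missing <- setdiff(dmn, rownames(conn))
  if (length(missing)) {
    stopf("DMN region(s) missing from matrix: %s",
          paste(missing, collapse = ", "))
  }
  sub <- conn[dmn, dmn]
  strength <- rowMeans(sub, na.rm = TRUE)  # diagonal is NA/excluded
  list(mean = mean(sub[upper.tri(sub)], na.rm = TRUE), strength = strength)
}

#' Sample entropy of a time series
#'
#' SampEn(m, r): the negative log conditional probability that template
#' vectors matching for `m` points also match for `m + 1`, self-matches
#' excluded. The series is mean-subtracted and variance-standardized, and
#' templates are compared with a standardized Euclidean distance (each
#' embedding coordinate divided by its across-template SD); vectors match
#' when the distance is at most `r * sqrt(m)`, keeping the tolerance
#' commensurate with the conventional per-coordinate `r` rule. Lower
#' values indicate a more regular (predictable) signal.
#'
#' @param x Numeric series, length at least `m + 2`, non-constant.
#' @param m Embedding dimension (default 3).
#' @param r Tolerance (default 0.2).
#'
#' @return SampEn value; `NA` (with a warning) when no template pairs
#'   match at length `m` or `m + 1`, or for a constant series.
#' @export
sample_entropy <- function(x, m = 3, r = 0.2) {
  if (m < 1 || m != round(m)) stopf("m must be a positive integer")
  if (r <= 0) stopf("r must be positive")
  n <- length(x)
  if (n < m + 2) stopf("series too short for m = %d (need >= %d)", m, m + 2)
  if (sd(x) == 0 || !is.finite(sd(x))) {
    warnf("constant series: sample entropy undefined")
    return(NA_real_)
  }
  x <- (x - mean(x)) / sd(x)
  count_pairs <- function(mm) {
    nt <- n - m  # both lengths use the same template count
    emb <- vapply(seq_len(mm), function(k) x[(k):(k + nt - 1)], numeric(nt))
    s <- apply(emb, 2, sd)
    s[s == 0] <- 1
    emb <- sweep(emb, 2, s, "/")
    d <- dist(emb)
    sum(d <= r * sqrt(mm))
  }
  b <- count_pairs(m)
  a <- count_pairs(m + 1)
  if (b == 0 || a == 0) {
    warnf("no matching templates within tolerance; sample entropy undefined")
    return(NA_real_)
  }
  -log(a / b)
}

#' Regional sample entropy
#'
#' Sample entropy per region for one epoch, plus the DMN mean (average of
#' the 12 DMN region values). Accepts either a `regions x T` matrix of
#' mean regional time courses, or a 4D voxel volume with a region-label
#' array, in which case voxel-wise entropy is averaged within each label
#' (mirroring voxel-wise entropy maps averaged per ROI). Voxel series are
#' mean-subtracted by the standardization inside [sample_entropy()].
#'
#' @param x `regions x T` matrix with region row names, or a 4D array.
#' @param labels For the 4D case: 3D integer array of region indices into
#'   `region_names` (0 or `NA` = outside mask).
#' @param region_names Region labels (default [region_labels()]).
#' @param m,r Sample-entropy parameters.
#' @param dmn DMN labels for the DMN mean.
#'
#' @return List: `regional` (named vector), `dmn_mean`. Empty regions are
#'   flagged `NA`.
#' @export
regional_entropy <- function(x, labels = NULL,
                             region_names = region_labels(),
                             m = 3, r = 0.2, dmn = dmn_regions()) {
  if (is.matrix(x)) {
    vals <- apply(x, 1, function(s) {
      tryCatch(suppressWarnings(sample_entropy(s, m, r)),
               error = function(e) NA_real_)
    })
  } else if (length(dim(x)) == 4) {
    if (is.null(labels)) stopf("labels array required for voxel input")
    d <- dim(x)
    lab <- as.integer(labels)
    xm <- matrix(x, prod(d[1:3]), d[4])
    vals <- vapply(seq_along(region_names), function(k) {
      vox <- which(lab == k)
      if (!length(vox)) return(NA_real_)
      mean(apply(xm[vox, , drop = FALSE], 1, function(s) {
        tryCatch(suppressWarnings(sample_entropy(s, m, r)),
                 error = function(e) NA_real_)
      }), na.rm = TRUE)
    }, 0)
    names(vals) <- region_names
  } else {
    stopf("x must be a regions x T matrix or a 4D array")
  }
  dmn_present <- intersect(dmn, names(vals))
  list(regional = vals,
       dmn_mean = if (length(dmn_present)) mean(vals[dmn_present]) else NA_real_)
}
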