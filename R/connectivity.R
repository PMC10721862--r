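# Fisher-z clip applied before atanh so perfectly correlated (e.g.
# duplicated) signals stay finite.
FISHER_CLIP <- 1 - 1e-7

#' Region-of-interest functional connectivity matrix
#'
#' Pairwise Pearson correlation between region time courses, Fisher
#' z-transformed (`atanh`) after clipping `|r|` at `1 - 1e-7`. Constant
#' regions cannot be correlated and are flagged missing (`NA` row/column)
#' with a warning. The diagonal is set to `NA`: self-connectivity is
#' excluded from all downstream statistics.
#'
#' @param ts `regions x T` matrix with region labels as row names.
#' @param epoch Optional epoch tag (`"TP1"`/`"TP2"`) stored as an attribute.
#'
#' @return Symmetric `R x R` Fisher-z matrix with `NA` diagonal, region
#'   dimnames, and attribute `epoch`.
#' @export
fc_matrix <- function(ts, epoch = NA_character_) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 4) stopf("need at least 4 frames")
  sds <- apply(ts, 1, sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warnf("constant region(s) flagged missing: %s",
          paste(rownames(ts)[const], collapse = ", "))
  }
  r <- suppressWarnings(cor(t(ts)))
  r[const, ] <- NA
  r[, const] <- NA
  z <- atanh(clip(r, -FISHER_CLIP, FISHER_CLIP))
  diag(z) <- NA
  attr(z, "epoch") <- epoch
  z
}

#' Post-minus-pre connectivity difference matrix
#'
#' Elementwise `TP2 - TP1` difference of two Fisher-z matrices from the
#' same session; antisymmetric under argument swap.
#'
#' @param tp2,tp1 Matrices from [fc_matrix()] with identical region labels.
#' @param session Optional session tag (`"psilocybin"`/`"saline"`).
#'
#' @return Difference matrix with attribute `session`.
#' @export
diff_matrix <- function(tp2, tp1, session = NA_character_) {
  if (!identical(dimnames(tp2), dimnames(tp1))) {
    stopf("region labels of the two epochs do not match")
  }
  d <- tp2 - tp1
  attr(d, "epoch") <- NULL
  attr(d, "session") <- session
  d
}

# Banded convolution matrix for a 1D Gaussian kernel. Rows are
# renormalized at the boundary (normalized convolution), so uniform
# fields pass through unchanged while interior impulses still conserve
# total intensity (their mass only reaches full-weight rows).
gauss_band <- function(n, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  m <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - half):(j + half)
    ok <- idx >= 1 & idx <= n
    m[idx[ok], j] <- k[ok]
  }
  m / rowSums(m)
}

#' Spatially smooth a 4D volume with an isotropic Gaussian kernel
#'
#' Per-frame separable Gaussian smoothing; the kernel standard deviation
#' in voxels is `fwhm / (2 sqrt(2 log 2) * voxel_size)`. `fwhm = 0`
#' returns the input unchanged.
#'
#' @param vol 4D array (`x, y, z, t`) or 3D array (single frame).
#' @param fwhm Kernel full width at half maximum in mm.
#' @param voxel_size Isotropic voxel size in mm.
#'
#' @return Smoothed array of the same shape.
#' @export
smooth_volume <- function(vol, fwhm, voxel_size) {
  if (voxel_size <= 0) stopf("voxel_size must be positive")
  if (fwhm < 0) stopf("fwhm must be >= 0")
  if (fwhm == 0) return(vol)
  d <- dim(vol)
  three <- length(d) == 3
  if (three) {
    d <- c(d, 1L)
    dim(vol) <- d
  }
  if (length(d) != 4) stopf("vol must be a 3D or 4D array")
  sigma <- fwhm / (2 * sqrt(2 * log(2)) * voxel_size)
  for (ax in 1:3) {
    b <- gauss_band(d[ax], sigma)
    perm <- c(ax, setdiff(1:4, ax))
    v <- aperm(vol, perm)
    dv <- dim(v)
    dim(v) <- c(dv[1], prod(dv[-1]))
    v <- b %*% v
    dim(v) <- dv
    vol <- aperm(v, order(perm))
  }
  if (three) dim(vol) <- d[1:3]
  vol
}

#' Voxel-wise global brain connectivity map
#'
#' For every voxel inside the gray-matter mask, the mean Fisher-z Pearson
#' correlation with all other in-mask voxels (self excluded). Constant
#' voxels are flagged missing and excluded from the averages of the
#' remaining voxels.
#'
#' @param vol 4D array (`x, y, z, t`), one epoch.
#' @param mask 3D logical array, same spatial dimensions.
#'
#' @return 3D array: mean Fisher-z per in-mask voxel, `NA` outside the
#'   mask and at flagged voxels.
#' @export
gbc_map <- function(vol, mask) {
  d <- dim(vol)
  if (length(d) != 4) stopf("vol must be 4D")
  if (!identical(dim(mask), d[1:3])) stopf("mask dimensions must match vol")
  if (d[4] < 4) stopf("epoch too short (need >= 4 frames)")
  idx <- which(mask)
  if (length(idx) < 2) stopf("need at least 2 mask voxels")
  x <- matrix(vol, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  sds <- apply(x, 1, sd)
  const <- sds == 0 | !is.finite(sds)
  z <- atanh(clip(suppressWarnings(cor(t(x))), -FISHER_CLIP, FISHER_CLIP))
  z[const, ] <- NA
  z[, const] <- NA
  diag(z) <- NA
  g <- rowMeans(z, na.rm = TRUE)
  g[const] <- NA
  out <- array(NA_real_, d[1:3])
  out[idx] <- g
  out
}
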