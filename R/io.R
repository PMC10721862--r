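# Tabular and NIfTI interchange for pipeline objects. TSV carries region
# time series and connectivity matrices (labeled rows), CSV the cohort
# table, NIfTI the voxel volumes.

#' Write / read region time series as TSV
#'
#' Regions in rows (labeled), frames in columns.
#'
#' @param ts `regions x T` matrix with row names.
#' @param path File path.
#' @return `read_roi_tsv` returns the matrix.
#' @export
write_roi_tsv <- function(ts, path) {
  write.table(ts, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_tsv
#' @export
read_roi_tsv <- function(path) {
  x <- read.delim(path, header = FALSE, row.names = 1)
  as.matrix(x)
}

#' Write / read a labeled connectivity matrix as TSV
#'
#' @param m Square matrix with region dimnames.
#' @param path File path.
#' @return `read_conn_tsv` returns the matrix.
#' @export
write_conn_tsv <- function(m, path) {
  write.table(m, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_conn_tsv
#' @export
read_conn_tsv <- function(path) {
  as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
}

#' Write / read a six-column motion trace as TSV
#'
#' @param motion `T x 6` matrix.
#' @param path File path.
#' @return `read_motion_tsv` returns the matrix.
#' @export
write_motion_tsv <- function(motion, path) {
  write.table(motion, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  as.matrix(read.delim(path))
}

#' Write / read a cohort table as CSV
#'
#' @param cohort A [generate_cohort()] table.
#' @param path File path.
#' @return `read_cohort_csv` returns the cohort `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write / read a volume as NIfTI
#'
#' Thin wrappers around `RNifti` for 3D/4D arrays (e.g. GBC maps, label
#' volumes, synthetic EPI grids).
#'
#' @param vol 3D or 4D array.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param voxel_size Isotropic voxel size in mm.
#' @return `read_volume` returns the array.
#' @export
write_volume <- function(vol, path, voxel_size = 0.3) {
  img <- RNifti::asNifti(vol, pixdim = rep(voxel_size, min(3, length(dim(vol)))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  arr
}
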