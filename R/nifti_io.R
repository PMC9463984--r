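#' Extract a subject's time-by-voxel matrix from a 4D NIfTI volume
#'
#' Reads a 4D series, checks it is spatially congruent with the mask, and
#' pulls the in-mask voxel time courses into a matrix with one row per TR
#' and one column per in-mask voxel, in the mask's voxel ordering.
#'
#' @param volume_file path to a 4D NIfTI file.
#' @param mask a [brain_mask] on the same grid.
#' @param subject_id label for the returned matrix.
#' @param tr_seconds repetition time metadata (default 1.5 s).
#' @return a [data_matrix] of dimension TRs x m.
#' @export
load_subject <- function(volume_file, mask, subject_id = NULL,
                         tr_seconds = 1.5) {
  stopifnot(inherits(mask, "brain_mask"))
  vol <- as.array(RNifti::readNifti(volume_file))
  d <- dim(vol)
  if (length(d) == 3L) {
    dim(vol) <- c(d, 1L)
    d <- dim(vol)
  }
  if (length(d) != 4L)
    stop("dimension error: expected a 4D volume, got ", length(d), "D")
  if (!all(d[1:3] == mask$dim))
    stop("dimension error: volume grid ", paste(d[1:3], collapse = "x"),
         " does not match mask grid ", paste(mask$dim, collapse = "x"))
  nt <- d[4]
  dim(vol) <- c(prod(d[1:3]), nt)
  values <- t(vol[mask$idx, , drop = FALSE])
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(volume_file))
  data_matrix(values, mask, subject_id = subject_id, tr_seconds = tr_seconds)
}

# write a TRs x m matrix as a 4D volume on the mask's grid (zeros outside)
write_volume_series <- function(values, mask, path) {
  stopifnot(is.matrix(values), ncol(values) == mask$m)
  nt <- nrow(values)
  vol <- array(0, c(prod(mask$dim), nt))
  vol[mask$idx, ] <- t(values)
  dim(vol) <- c(mask$dim, nt)
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' Write a mask as NIfTI
#'
#' @param mask a [brain_mask]; `path` output file (.nii for uncompressed).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "brain_mask"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask$inside), mask$dim)),
                     path)
  invisible(path)
}

#' Fold spatial maps back into 3D brain space
#'
#' Writes one layer's map matrix (atoms x voxels) as a 4D NIfTI stack, one
#' 3D volume per atom, with zeros outside the mask — the step that turns a
#' weight row back into a viewable functional brain network.
#'
#' @param maps numeric matrix (atoms x m) or a single length-m vector.
#' @param mask the [brain_mask] the map columns refer to.
#' @param path output NIfTI path (use `.nii` for byte-stable uncompressed
#'   output).
#' @return `path`, invisibly.
#' @export
maps_to_nifti <- function(maps, mask, path) {
  if (is.numeric(maps) && is.null(dim(maps))) maps <- matrix(maps, nrow = 1L)
  stopifnot(inherits(mask, "brain_mask"), is.matrix(maps))
  if (ncol(maps) != mask$m)
    stop("dimension error: maps have ", ncol(maps),
         " voxels but mask has ", mask$m)
  write_volume_series(maps, mask, path)
}
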