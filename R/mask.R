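#' Brain mask with a deterministic voxel ordering
#'
#' A `brain_mask` wraps a 3D logical array and fixes the linear ordering of
#' in-mask voxels used everywhere in the package: column-major order (first
#' array axis fastest), i.e. the order returned by `which()` on the logical
#' array. Column `k` of every time-by-voxel matrix built from this mask
#' therefore always refers to the same 3D coordinate, and spatial maps can
#' be folded back into the volume without ambiguity.
#'
#' @param inside a 3D logical (or 0/1 numeric) array; `TRUE`/nonzero marks
#'   in-mask voxels.
#' @return an object of class `brain_mask` with elements `dim` (3 integers),
#'   `inside` (logical array), `m` (number of in-mask voxels) and `idx`
#'   (linear indices of in-mask voxels, ascending).
#' @examples
#' a <- array(FALSE, c(4, 4, 4)); a[2:3, 2:3, 2:3] <- TRUE
#' mk <- brain_mask(a)
#' mk$m
#' @export
brain_mask <- function(inside) {
  if (is.numeric(inside)) inside <- inside != 0
  if (!is.logical(inside) || length(dim(inside)) != 3L)
    stop("`inside` must be a 3D logical array")
  inside[is.na(inside)] <- FALSE
  idx <- which(inside)
  if (length(idx) < 1L) stop("invalid mask: no in-mask voxels")
  structure(
    list(dim = dim(inside), inside = inside, m = length(idx), idx = idx),
    class = "brain_mask"
  )
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("<brain_mask> ", paste(x$dim, collapse = " x "),
      " grid, ", x$m, " in-mask voxels\n", sep = "")
  invisible(x)
}

#' Read a 3D mask volume from a NIfTI file
#'
#' Voxels with nonzero intensity are in-mask.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return a [brain_mask].
#' @export
read_mask <- function(path) {
  vol <- RNifti::readNifti(path)
  a <- as.array(vol)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1L, drop = TRUE]
  brain_mask(a != 0)
}

#' 3D coordinates of in-mask voxels
#'
#' Rows follow the mask's voxel ordering, so row `k` gives the coordinate of
#' column `k` of any data matrix built from this mask.
#'
#' @param mask a [brain_mask].
#' @return an `m` x 3 integer matrix of 1-based (i, j, k) coordinates.
#' @export
mask_coords <- function(mask) {
  stopifnot(inherits(mask, "brain_mask"))
  arrayInd(mask$idx, mask$dim)
}

#' Intersect brain masks
#'
#' A voxel is inside the result iff it is inside every input mask. Used to
#' build the group-wise common mask that guarantees voxel-level spatial
#' correspondence across subjects.
#'
#' @param masks a list of [brain_mask] objects sharing one grid shape.
#' @return a [brain_mask]; errors if the intersection is empty.
#' @export
intersect_masks <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  dims <- vapply(masks, function(m) m$dim, integer(3))
  if (!all(dims == dims[, 1L]))
    stop("dimension error: masks have different grid shapes")
  inside <- Reduce(`&`, lapply(masks, `[[`, "inside"))
  if (!any(inside)) stop("invalid mask: intersection of masks is empty")
  brain_mask(inside)
}

# fold a length-m vector into the 3D grid (zeros outside the mask)
unmask <- function(values, mask) {
  stopifnot(inherits(mask, "brain_mask"), length(values) == mask$m)
  a <- array(0, mask$dim)
  a[mask$idx] <- values
  a
}
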