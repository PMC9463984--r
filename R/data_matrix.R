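#' Time-by-voxel data matrix
#'
#' The working representation of one subject's (or the concatenated group's)
#' fMRI run: rows are time points (TRs), columns are in-mask voxels in the
#' mask's voxel ordering. Carries the mask, a subject label, the TR in
#' seconds (metadata only; never used in computation) and, for group
#' matrices, the row segments belonging to each subject.
#'
#' @param values numeric matrix, rows = TRs, columns = voxels.
#' @param mask the [brain_mask] whose ordering the columns follow.
#' @param subject_id subject label, or `"group"` for a concatenated matrix.
#' @param tr_seconds repetition time in seconds (default 1.5).
#' @param segments for group matrices, a named list of integer row ranges.
#' @return an object of class `data_matrix`.
#' @export
data_matrix <- function(values, mask, subject_id = "subject",
                        tr_seconds = 1.5, segments = NULL) {
  stopifnot(is.matrix(values), inherits(mask, "brain_mask"))
  if (ncol(values) != mask$m)
    stop("dimension error: matrix has ", ncol(values),
         " columns but mask has ", mask$m, " voxels")
  structure(
    list(values = values, mask = mask, subject_id = subject_id,
         tr_seconds = tr_seconds, segments = segments),
    class = "data_matrix"
  )
}

#' @export
print.data_matrix <- function(x, ...) {
  cat("<data_matrix> ", nrow(x$values), " TRs x ", ncol(x$values),
      " voxels  [", x$subject_id, "]\n", sep = "")
  if (!is.null(x$segments))
    cat("  ", length(x$segments), " subject segments\n", sep = "")
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

#' Z-score every voxel time course
#'
#' Centers and scales each column to mean 0 and unit variance using the
#' population convention (divide by `n`, not `n - 1`), so normalization is
#' idempotent and the group matrix feeds the model on a fixed scale.
#' Columns with zero variance cannot be z-scored; they are dropped with a
#' warning and their original indices are recorded in the result's
#' `dropped` element (the mask is pruned to stay aligned).
#'
#' @param dm a [data_matrix].
#' @return a [data_matrix] with normalized columns; element `dropped` holds
#'   the original column indices removed (integer(0) if none).
#' @export
normalize_columns <- function(dm) {
  stopifnot(inherits(dm, "data_matrix"))
  x <- dm$values
  n <- nrow(x)
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(x^2) - mu^2)
  bad <- which(sd_pop <= 0 | !is.finite(sd_pop))
  if (length(bad)) {
    warning("dropping ", length(bad), " constant voxel column(s): ",
            paste(utils::head(bad, 10L), collapse = ", "),
            if (length(bad) > 10L) ", ..." else "")
    keep <- setdiff(seq_len(ncol(x)), bad)
    inside <- dm$mask$inside
    inside[dm$mask$idx[bad]] <- FALSE
    dm$mask <- brain_mask(inside)
    x <- x[, keep, drop = FALSE]
    mu <- mu[keep]
    sd_pop <- sd_pop[keep]
  }
  dm$values <- sweep(sweep(x, 2L, mu, `-`), 2L, sd_pop, `/`)
  dm$dropped <- if (length(bad)) bad else integer(0)
  dm
}

#' Concatenate subjects into the group matrix
#'
#' Stacks the subjects' time-by-voxel matrices along time in input order,
#' recording each subject's row segment. The result is the (v*n) x m group
#' matrix whose rows — brain volumes — are the training samples of the
#' group-stage model.
#'
#' @param subjects list of [data_matrix] objects sharing one mask and TR
#'   count.
#' @return a group [data_matrix] with `segments` mapping subject ids to row
#'   ranges.
#' @export
build_group_matrix <- function(subjects) {
  stopifnot(is.list(subjects), length(subjects) >= 1L)
  m <- vapply(subjects, function(s) ncol(s$values), integer(1))
  v <- vapply(subjects, function(s) nrow(s$values), integer(1))
  if (length(unique(m)) != 1L)
    stop("dimension error: subjects have different voxel counts")
  if (length(unique(v)) != 1L)
    stop("dimension error: subjects have different TR counts")
  ids <- vapply(seq_along(subjects),
                function(i) as.character(subjects[[i]]$subject_id %||% i),
                character(1))
  values <- do.call(rbind, lapply(subjects, `[[`, "values"))
  bounds <- c(0L, cumsum(v))
  segments <- stats::setNames(
    lapply(seq_along(subjects),
           function(i) (bounds[i] + 1L):bounds[i + 1L]),
    ids)
  data_matrix(values, subjects[[1L]]$mask, subject_id = "group",
              tr_seconds = subjects[[1L]]$tr_seconds, segments = segments)
}

#' Extract one subject's rows from a group matrix
#'
#' @param group a group [data_matrix] built by [build_group_matrix()].
#' @param which subject id (character) or position (integer).
#' @return the subject's [data_matrix].
#' @export
subject_segment <- function(group, which) {
  stopifnot(inherits(group, "data_matrix"))
  if (is.null(group$segments)) stop("not a group matrix: no segments recorded")
  seg <- if (is.character(which)) group$segments[[which]]
         else group$segments[[which]]
  if (is.null(seg)) stop("unknown subject: ", which)
  id <- if (is.character(which)) which else names(group$segments)[which]
  data_matrix(group$values[seg, , drop = FALSE], group$mask,
              subject_id = id, tr_seconds = group$tr_seconds)
}

#' Write / read a data matrix as TSV
#'
#' Plain tab-separated text, one row per TR; no row or column names. The
#' mask must be carried separately (see [read_mask()]).
#'
#' @param dm a [data_matrix]; `path` a file path; `mask` a [brain_mask].
#' @return `write_data_matrix` returns `path` invisibly; `read_data_matrix`
#'   returns a [data_matrix].
#' @export
write_data_matrix <- function(dm, path) {
  utils::write.table(dm$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_data_matrix
#' @param subject_id,tr_seconds metadata for the reloaded matrix.
#' @export
read_data_matrix <- function(path, mask, subject_id = "subject",
                             tr_seconds = 1.5) {
  values <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(values) <- NULL
  data_matrix(values, mask, subject_id = subject_id, tr_seconds = tr_seconds)
}
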