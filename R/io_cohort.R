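# Volume stacks and cohort tables.
#
# A VolumeStack holds co-registered subject volumes on one shared grid as a
# 4-D array (x, y, z, subject) plus the common affine and ordered subject
# ids.  Grid equality is a hard precondition everywhere: volumes are never
# resampled or reoriented implicitly, because the downstream method assumes
# voxel-wise correspondence established by prior spatial normalisation.

AFFINE_TOL <- 1e-4

#' Construct a VolumeStack
#'
#' @param data 4-D numeric array (nx, ny, nz, n_subjects), or a list of 3-D
#'   arrays sharing one shape.
#' @param affine 4x4 voxel-to-world matrix common to all volumes.
#' @param subject_ids Character vector of unique ids, one per volume.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(data, affine = diag(4), subject_ids = NULL) {
  if (is.list(data)) {
    shapes <- vapply(data, function(v) paste(dim(v), collapse = "x"), "")
    if (length(unique(shapes)) > 1L)
      stop_grid_mismatch("volumes differ in grid shape")
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(dim(data[[1]]), length(data)))
  }
  if (length(dim(data)) != 4L) stop("data must be a 4-D array or list of 3-D arrays")
  n <- dim(data)[4]
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(n))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n) stop("subject_ids length must equal number of volumes")
  if (anyDuplicated(subject_ids)) stop_duplicate_subject("duplicate subject ids in stack")
  structure(list(data = data, affine = affine, subject_ids = subject_ids),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("VolumeStack: %d subjects on a %dx%dx%d grid\n", d[4], d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$data)

n_subjects <- function(stack) dim(stack$data)[4]
grid_shape <- function(stack) dim(stack$data)[1:3]

same_grid <- function(shape_a, affine_a, shape_b, affine_b) {
  identical(as.integer(shape_a), as.integer(shape_b)) &&
    max(abs(affine_a - affine_b)) <= AFFINE_TOL
}

check_stack_grid <- function(stack, shape, affine = NULL, what = "volume") {
  if (!identical(as.integer(grid_shape(stack)), as.integer(shape)))
    stop_grid_mismatch(sprintf("%s grid shape does not match stack", what))
  if (!is.null(affine) && max(abs(stack$affine - affine)) > AFFINE_TOL)
    stop_grid_mismatch(sprintf("%s affine does not match stack", what))
  invisible(TRUE)
}

#' Load a stack of NIfTI volumes
#'
#' Reads each path and assembles a [volume_stack()], enforcing that all
#' volumes share the same grid shape and affine (to 1e-4).  Fails rather
#' than silently resampling.
#'
#' @param paths Character vector of NIfTI file paths, in cohort order.
#' @param subject_ids Optional ids; default is the file base name without
#'   extension.
#' @return A `volume_stack`.
#' @export
load_stack <- function(paths, subject_ids = NULL) {
  if (length(paths) == 0L) stop("no paths given")
  vols <- lapply(paths, read_nifti)
  ref <- vols[[1]]
  for (i in seq_along(vols)) {
    if (!same_grid(dim(vols[[i]]$data), vols[[i]]$affine, dim(ref$data), ref$affine))
      stop_grid_mismatch(sprintf("grid mismatch between '%s' and '%s'",
                                 paths[i], paths[1]))
  }
  if (is.null(subject_ids))
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  volume_stack(lapply(vols, `[[`, "data"), affine = ref$affine,
               subject_ids = subject_ids)
}

#' Save every volume of a stack
#'
#' @param stack A `volume_stack`.
#' @param dir Output directory (created if needed).
#' @param gzip Compress as `.nii.gz`? Default `FALSE`.
#' @return Character vector of written paths, invisibly.
#' @export
save_stack <- function(stack, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  paths <- file.path(dir, paste0(stack$subject_ids, ext))
  for (i in seq_len(n_subjects(stack))) {
    write_nifti(stack$data[, , , i, drop = TRUE], paths[i], affine = stack$affine)
  }
  invisible(paths)
}

#' Read a cohort table
#'
#' Tab-separated with a header row; required columns `subject_id`, `group`,
#' `age`, `sex`.  Extra columns are preserved but ignored by the pipeline.
#'
#' @param path TSV file path.
#' @return A data.frame validated by [validate_cohort()].
#' @export
read_cohort <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort(tab)
}

#' Validate a cohort table
#'
#' @param tab data.frame with columns subject_id, group, age, sex.
#' @return The table, with `subject_id` coerced to character.
#' @export
validate_cohort <- function(tab) {
  need <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_parse(sprintf("cohort table lacks column(s): %s", paste(miss, collapse = ", ")))
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id))
    stop_duplicate_subject("duplicate subject_id in cohort table")
  if (anyNA(tab$group) || anyNA(tab$age))
    stop_parse("cohort table has missing group or age")
  if (!is.numeric(tab$age) || any(tab$age <= 0))
    stop_parse("age must be positive and numeric")
  tab
}

#' Write a cohort table as TSV
#'
#' @param tab Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a cohort table to a stack
#'
#' Reorders the table rows to the stack's subject order.  Every stack id
#' must occur exactly once in the table.
#'
#' @param stack A `volume_stack`.
#' @param tab Cohort data.frame.
#' @return The reordered table.
#' @export
align_cohort <- function(stack, tab) {
  tab <- validate_cohort(tab)
  idx <- match(stack$subject_ids, tab$subject_id)
  if (anyNA(idx)) {
    stop_missing_subject(sprintf("subject(s) missing from cohort table: %s",
      paste(stack$subject_ids[is.na(idx)], collapse = ", ")))
  }
  out <- tab[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flatten a stack to a subjects x voxels matrix
#'
#' @param stack A `volume_stack`.
#' @param mask Optional `mask_volume`; if given, only in-mask voxels are kept
#'   (fixed grid order, i fastest).
#' @return Numeric matrix, one row per subject.
#' @export
stack_matrix <- function(stack, mask = NULL) {
  n <- n_subjects(stack)
  m <- matrix(stack$data, nrow = prod(grid_shape(stack)), ncol = n)
  if (!is.null(mask)) {
    check_stack_grid(stack, dim(mask$data), what = "mask")
    m <- m[as.logical(mask$data), , drop = FALSE]
  }
  t(m)
}

#' Rebuild a stack from a subjects x voxels matrix
#'
#' Inverse of [stack_matrix()]: values outside the mask are taken from
#' `template` (default 0).
#'
#' @param mat Subjects x voxels matrix.
#' @param like Reference `volume_stack` providing grid, affine, ids.
#' @param mask Optional mask used when flattening.
#' @return A `volume_stack`.
#' @export
matrix_to_stack <- function(mat, like, mask = NULL) {
  shape <- grid_shape(like)
  n <- nrow(mat)
  full <- matrix(like$data, nrow = prod(shape), ncol = n_subjects(like))
  if (n != n_subjects(like)) stop("row count does not match reference stack")
  if (is.null(mask)) {
    full[] <- t(mat)
  } else {
    full[as.logical(mask$data), ] <- t(mat)
  }
  volume_stack(array(full, dim = c(shape, n)), affine = like$affine,
               subject_ids = like$subject_ids)
}
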