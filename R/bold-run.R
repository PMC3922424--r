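# Container for one subject's template-space 4D BOLD series plus the
# per-volume realignment parameters and (optionally) pre-extracted nuisance
# traces.

#' Construct a BOLD run
#'
#' @param data 4D numeric array (x, y, z, t) in template space.
#' @param tr_seconds repetition time (s).
#' @param voxel_mm voxel size (mm), length 1 or 3.
#' @param motion_params T x 6 matrix: 3 translations (mm) then 3 rotations
#'   (radians).
#' @param subject_id,site_id identifiers.
#' @param nuisance optional T x 3 matrix (columns `csf`, `wm`, `soft_tissue`)
#'   of nuisance time courses.
#' @param flipped whether the run has been mirrored across the midsagittal
#'   plane.
#' @return a `bold_run` object.
#' @export
bold_run <- function(data, tr_seconds, voxel_mm, motion_params,
                     subject_id = NA_character_, site_id = NA_character_,
                     nuisance = NULL, flipped = FALSE) {
  d <- dim(data)
  if (length(d) != 4) stop("data must be a 4D array (x, y, z, t)")
  if (d[4] < 2) stop("a run needs at least 2 volumes, got ", d[4])
  motion_params <- as.matrix(motion_params)
  if (nrow(motion_params) != d[4]) {
    stop("motion_params has ", nrow(motion_params),
         " rows but the run has ", d[4], " volumes")
  }
  if (ncol(motion_params) != 6) stop("motion_params must have 6 columns")
  if (!all(is.finite(data))) stop("non-finite voxel values in BOLD data")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == d[4], ncol(nuisance) == 3)
    colnames(nuisance) <- c("csf", "wm", "soft_tissue")
  }
  structure(
    list(data = data, tr_seconds = tr_seconds,
         voxel_mm = rep_len(voxel_mm, 3), motion_params = motion_params,
         subject_id = subject_id, site_id = site_id,
         nuisance = nuisance, flipped = flipped),
    class = "bold_run"
  )
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_run> ", x$subject_id, ": ",
      paste(d[1:3], collapse = "x"), " x ", d[4], " volumes, TR ",
      x$tr_seconds, " s", if (isTRUE(x$flipped)) " [flipped]", "\n", sep = "")
  invisible(x)
}

n_volumes <- function(run) dim(run$data)[4]

# Subset a run in time (used by scrubbing).
.subset_volumes <- function(run, keep) {
  run$data <- run$data[, , , keep, drop = FALSE]
  run$motion_params <- run$motion_params[keep, , drop = FALSE]
  if (!is.null(run$nuisance)) {
    run$nuisance <- run$nuisance[keep, , drop = FALSE]
  }
  run
}

# Voxels-by-time view without copying semantics the caller cares about.
.voxel_matrix <- function(run) {
  d <- dim(run$data)
  matrix(run$data, nrow = prod(d[1:3]), ncol = d[4])
}

.matrix_to_run <- function(run, m) {
  run$data <- array(m, dim = dim(run$data))
  run
}
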