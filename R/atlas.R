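# ROI lattice construction, midsagittal flip geometry, and time-course
# extraction. Coordinates are template mm with negative x = left hemisphere;
# voxel index i (1-based) maps to x = (i - (X + 1)/2) * voxel_mm, so an even
# x-dimension puts the mirror plane exactly between the two central columns
# and flipping is an exact index reversal.

.axis_coords <- function(n, vox) (seq_len(n) - (n + 1) / 2) * vox

.voxel_coords <- function(dim3, voxel_mm) {
  list(
    x = .axis_coords(dim3[1], voxel_mm[1]),
    y = .axis_coords(dim3[2], voxel_mm[2]),
    z = .axis_coords(dim3[3], voxel_mm[3])
  )
}

# Assign every TRUE voxel of `mask` to its nearest seed (squared mm distance).
# Seeds are sorted lexicographically by (x, y, z); ties go to the lowest seed
# id, which max.col(ties.method = "first") delivers because squared distances
# on a regular grid are exact in double precision.
.assign_nearest <- function(mask, coords, seed_idx) {
  stopifnot(nrow(seed_idx) > 0)
  sx <- coords$x[seed_idx[, 1]]
  sy <- coords$y[seed_idx[, 2]]
  sz <- coords$z[seed_idx[, 3]]
  ord <- order(sx, sy, sz)
  sx <- sx[ord]; sy <- sy[ord]; sz <- sz[ord]

  vox <- which(mask, arr.ind = TRUE)
  vx <- coords$x[vox[, 1]]
  vy <- coords$y[vox[, 2]]
  vz <- coords$z[vox[, 3]]

  lab <- integer(nrow(vox))
  chunk <- 4096L
  for (start in seq(1L, nrow(vox), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(vox))
    d <- outer(vx[idx], sx, "-")^2 +
      outer(vy[idx], sy, "-")^2 +
      outer(vz[idx], sz, "-")^2
    lab[idx] <- max.col(-d, ties.method = "first")
  }
  labels <- array(0L, dim = dim(mask))
  labels[vox] <- lab
  labels
}

.centroid_table <- function(labels, coords) {
  vox <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[vox]
  tibble(
    roi = sort(unique(lab)),
    x = as.numeric(tapply(coords$x[vox[, 1]], lab, mean)),
    y = as.numeric(tapply(coords$y[vox[, 2]], lab, mean)),
    z = as.numeric(tapply(coords$z[vox[, 3]], lab, mean)),
    n_voxels = as.integer(table(lab))
  )
}

#' Build an ROI lattice over a grey-matter mask
#'
#' Seeds a regular lattice at `spacing_mm` intervals inside the mask and the
#' closed axial range `z_range_mm`, then assigns every in-range mask voxel to
#' its nearest seed (Euclidean mm distance, ties to the lowest seed id after
#' sorting seeds lexicographically by x, y, z). Seeds that end up with no
#' voxels cannot occur (a seed always claims itself); labels are contiguous
#' from 1.
#'
#' @param grey_mask 3D logical or 0/1 array.
#' @param voxel_mm voxel size, length 1 or 3 (mm).
#' @param spacing_mm lattice spacing (mm), default 5 as in the standard
#'   whole-brain lattice.
#' @param z_range_mm closed interval of template z (mm) to cover; `NULL` for
#'   the whole grid. Default `c(-35, 70)`.
#' @return a `roi_atlas` object: integer label volume, centroid table,
#'   homologue map (`NA` where no mirror ROI exists), and grid metadata.
#' @export
build_lattice <- function(grey_mask, voxel_mm = 3, spacing_mm = 5,
                          z_range_mm = c(-35, 70)) {
  dim3 <- dim(grey_mask)
  stopifnot(length(dim3) == 3)
  voxel_mm <- rep_len(voxel_mm, 3)
  coords <- .voxel_coords(dim3, voxel_mm)
  mask <- array(as.logical(grey_mask), dim = dim3)
  if (!is.null(z_range_mm)) {
    keep_z <- coords$z >= z_range_mm[1] & coords$z <= z_range_mm[2]
    mask[, , !keep_z] <- FALSE
  }
  if (!any(mask)) stop("no grey-mask voxels inside the z range")

  step <- pmax(1L, as.integer(round(spacing_mm / voxel_mm)))
  on_lattice <- function(n, s) seq(1L, n, by = s)
  seed_mask <- array(FALSE, dim = dim3)
  seed_mask[on_lattice(dim3[1], step[1]),
            on_lattice(dim3[2], step[2]),
            on_lattice(dim3[3], step[3])] <- TRUE
  seed_idx <- which(seed_mask & mask, arr.ind = TRUE)
  if (nrow(seed_idx) == 0) stop("no lattice seed survives the mask/z range")

  labels <- .assign_nearest(mask, coords, seed_idx)
  new_roi_atlas(labels, voxel_mm, spacing_mm,
                z_range_mm %||% range(coords$z))
}

new_roi_atlas <- function(labels, voxel_mm, spacing_mm, z_range_mm,
                          homologue = NULL, hubs = NULL) {
  coords <- .voxel_coords(dim(labels), voxel_mm)
  centroids <- .centroid_table(labels, coords)
  n_rois <- max(labels)
  stopifnot(identical(centroids$roi, seq_len(n_rois)))
  if (is.null(homologue)) homologue <- .homologue_map(labels)
  structure(
    list(
      labels = labels, voxel_mm = voxel_mm, spacing_mm = spacing_mm,
      z_range_mm = z_range_mm, centroids = centroids, n_rois = n_rois,
      homologue = homologue, hubs = hubs
    ),
    class = "roi_atlas"
  )
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat("<roi_atlas> ", x$n_rois, " ROIs on a ",
      paste(dim(x$labels), collapse = "x"), " grid (",
      paste(x$voxel_mm, collapse = "x"), " mm voxels, spacing ",
      x$spacing_mm, " mm)\n", sep = "")
  if (!is.null(x$hubs)) {
    cat("  hubs: ", nrow(x$hubs), " (",
        sum(x$hubs$hemisphere == "L"), " L / ",
        sum(x$hubs$hemisphere == "R"), " R)\n", sep = "")
  }
  invisible(x)
}

# Mirror partner of each ROI: the ROI whose voxel set is exactly the
# x-reversed voxel set, or NA.
.homologue_map <- function(labels) {
  flipped <- flip_midsagittal(labels, override_odd = TRUE)
  n <- max(labels)
  hom <- rep(NA_integer_, n)
  for (r in seq_len(n)) {
    cand <- unique(flipped[labels == r])
    if (length(cand) == 1 && cand > 0) {
      if (all(labels[flipped == cand] == r)) hom[r] <- cand
    }
  }
  hom
}

#' Build an exactly mirror-symmetric synthetic atlas
#'
#' Constructs a lattice on the left half-grid and mirrors it across the
#' mid-plane, so every ROI has an exact contralateral homologue and flipping
#' the label field is an exact permutation of labels. Intended for synthetic
#' grids; requires an even x-dimension so the mirror plane falls between the
#' two central voxel columns.
#'
#' @param grid_dims integer length-3 grid size (x even).
#' @param voxel_mm voxel size (mm), length 1 or 3.
#' @param spacing_mm lattice spacing (mm).
#' @param hub_table optional hub definition table (see [read_hub_table()]);
#'   attached via [attach_hubs()].
#' @param grey_mask optional 3D mask; must itself be mirror-symmetric.
#' @return a `roi_atlas` with a complete homologue map.
#' @export
make_symmetric_atlas <- function(grid_dims, voxel_mm = 3, spacing_mm = 6,
                                 hub_table = NULL, grey_mask = NULL) {
  stopifnot(length(grid_dims) == 3)
  if (grid_dims[1] %% 2 != 0) {
    stop("grid x-dimension must be even (got ", grid_dims[1],
         "): the mirror plane must fall between voxel columns")
  }
  voxel_mm <- rep_len(voxel_mm, 3)
  if (is.null(grey_mask)) grey_mask <- array(TRUE, dim = grid_dims)
  stopifnot(identical(dim(grey_mask), as.integer(grid_dims)) ||
              identical(dim(grey_mask), grid_dims))
  grey_mask <- array(as.logical(grey_mask), dim = grid_dims)
  fl <- flip_midsagittal(grey_mask, override_odd = TRUE)
  if (!identical(fl, grey_mask)) stop("grey_mask is not mirror-symmetric")

  half <- grid_dims[1] / 2
  coords <- .voxel_coords(grid_dims, voxel_mm)
  left_mask <- grey_mask
  left_mask[(half + 1):grid_dims[1], , ] <- FALSE

  step <- pmax(1L, as.integer(round(spacing_mm / voxel_mm)))
  seed_mask <- array(FALSE, dim = grid_dims)
  seed_mask[seq(1L, half, by = step[1]),
            seq(1L, grid_dims[2], by = step[2]),
            seq(1L, grid_dims[3], by = step[3])] <- TRUE
  seed_idx <- which(seed_mask & left_mask, arr.ind = TRUE)
  if (nrow(seed_idx) == 0) stop("no lattice seed inside the left half-grid")

  left_labels <- .assign_nearest(left_mask, coords, seed_idx)
  n_left <- max(left_labels)
  labels <- left_labels
  rev_x <- rev(seq_len(grid_dims[1]))
  mirrored <- left_labels[rev_x, , , drop = FALSE]
  labels[mirrored > 0] <- mirrored[mirrored > 0] + n_left
  homologue <- c(seq_len(n_left) + n_left, seq_len(n_left))

  atlas <- new_roi_atlas(labels, voxel_mm, spacing_mm,
                         range(coords$z), homologue = homologue)
  if (!is.null(hub_table)) atlas <- attach_hubs(atlas, hub_table)
  atlas
}

#' Attach lateralization hubs to an atlas
#'
#' Maps each configured hub coordinate (template mm) to the lattice ROI whose
#' centroid is nearest in Euclidean mm distance; the mapping distance is
#' reported. A hub outside the grid, on the wrong side of the mid-plane for
#' its declared hemisphere, or colliding with another hub's ROI is rejected.
#'
#' @param atlas a `roi_atlas`.
#' @param hub_table tibble with columns `name`, `hemisphere` ("L"/"R"),
#'   `x`, `y`, `z` (mm), `network` ("left-lateralized"/"right-lateralized"),
#'   `is_language` (logical).
#' @param quiet suppress the per-hub mapping-distance message.
#' @return the atlas with a `hubs` tibble (adds the mapped `roi` id).
#' @export
attach_hubs <- function(atlas, hub_table, quiet = FALSE) {
  hub_table <- as_tibble(hub_table)
  req <- c("name", "hemisphere", "x", "y", "z", "network", "is_language")
  missing_cols <- setdiff(req, names(hub_table))
  if (length(missing_cols) > 0) {
    stop("hub table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  coords <- .voxel_coords(dim(atlas$labels), atlas$voxel_mm)
  lim <- lapply(coords, range)
  hv <- atlas$voxel_mm / 2
  out <- lim$x[1] - hv[1] > hub_table$x | hub_table$x > lim$x[2] + hv[1] |
    lim$y[1] - hv[2] > hub_table$y | hub_table$y > lim$y[2] + hv[2] |
    lim$z[1] - hv[3] > hub_table$z | hub_table$z > lim$z[2] + hv[3]
  if (any(out)) {
    stop("hub(s) outside the grid: ",
         paste(hub_table$name[out], collapse = ", "))
  }
  cen <- atlas$centroids
  d2 <- outer(hub_table$x, cen$x, "-")^2 +
    outer(hub_table$y, cen$y, "-")^2 +
    outer(hub_table$z, cen$z, "-")^2
  roi <- max.col(-d2, ties.method = "first")
  dist_mm <- sqrt(d2[cbind(seq_len(nrow(hub_table)), roi)])
  if (!quiet) {
    message("hub -> ROI mapping distances (mm): ",
            paste(sprintf("%s=%.1f", hub_table$name, dist_mm),
                  collapse = ", "))
  }
  if (anyDuplicated(roi)) {
    dup <- hub_table$name[duplicated(roi) | duplicated(roi, fromLast = TRUE)]
    stop("hubs map to the same ROI: ", paste(dup, collapse = ", "))
  }
  sign_ok <- ifelse(hub_table$hemisphere == "L",
                    cen$x[roi] < 0, cen$x[roi] > 0)
  if (!all(sign_ok)) {
    stop("hub hemisphere inconsistent with mapped centroid x sign: ",
         paste(hub_table$name[!sign_ok], collapse = ", "))
  }
  hubs <- hub_table
  hubs$roi <- roi
  hubs$map_dist_mm <- dist_mm
  atlas$hubs <- hubs
  atlas
}

#' Flip a volume, run, or label field across the midsagittal plane
#'
#' Reverses the x index: voxel (i, j, k) maps to (X + 1 - i, j, k) in every
#' volume. With an even x-dimension this is an exact involution; an odd
#' x-dimension is rejected unless `override_odd = TRUE` (real template grids
#' with a centre column symmetric about x = 0).
#'
#' @param x a 3D or 4D array, or a [bold_run()].
#' @param override_odd allow an odd x-dimension.
#' @return the same type, mirrored; a `bold_run` has its `flipped` flag
#'   toggled.
#' @export
flip_midsagittal <- function(x, override_odd = FALSE) {
  UseMethod("flip_midsagittal")
}

#' @export
flip_midsagittal.array <- function(x, override_odd = FALSE) {
  d <- dim(x)
  if (d[1] %% 2 != 0 && !override_odd) {
    stop("x-dimension is odd (", d[1], "); pass override_odd = TRUE ",
         "only for grids symmetric about a centre column")
  }
  rev_x <- rev(seq_len(d[1]))
  if (length(d) == 3) x[rev_x, , , drop = FALSE]
  else if (length(d) == 4) x[rev_x, , , , drop = FALSE]
  else stop("expected a 3D or 4D array")
}

#' @export
flip_midsagittal.bold_run <- function(x, override_odd = FALSE) {
  x$data <- flip_midsagittal.array(x$data, override_odd)
  x$flipped <- !x$flipped
  x
}

#' Extract mean ROI time courses
#'
#' Row r of the result is the per-volume mean of the BOLD signal over the
#' voxels of ROI r.
#'
#' @param bold a [bold_run()] on the atlas grid.
#' @param atlas a `roi_atlas` aligned to the run.
#' @return a `timecourse_matrix`: list with `values` (R x T), `roi_ids`,
#'   `subject_id`, `flipped`.
#' @export
extract_timecourses <- function(bold, atlas) {
  d <- dim(bold$data)
  if (!identical(d[1:3], dim(atlas$labels))) {
    stop("atlas grid ", paste(dim(atlas$labels), collapse = "x"),
         " does not match run grid ", paste(d[1:3], collapse = "x"))
  }
  lab <- as.vector(atlas$labels)
  sel <- lab > 0
  m <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
  counts <- tabulate(lab[sel], nbins = atlas$n_rois)
  if (any(counts == 0)) {
    stop("ROI(s) empty on this grid: ",
         paste(which(counts == 0), collapse = ", "))
  }
  values <- rowsum(m[sel, , drop = FALSE], lab[sel]) / counts
  structure(
    list(values = values, roi_ids = seq_len(atlas$n_rois),
         subject_id = bold$subject_id, flipped = isTRUE(bold$flipped)),
    class = "timecourse_matrix"
  )
}
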