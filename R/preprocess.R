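# BOLD preprocessing: nuisance extraction, confound regression, linear
# detrend + zero-phase bandpass, FD/DVARS motion scrubbing, and hub SNR.
# The pipeline applies no spatial smoothing and regresses neither the global
# mean nor grey-matter signal, to avoid contaminating signal near the
# midsagittal plane.

#' Extract mean nuisance time courses from restriction masks
#'
#' @param bold a [bold_run()].
#' @param masks named list of 3D logical masks; expected names `csf`, `wm`,
#'   `soft_tissue`.
#' @return list with one length-T series per mask plus the run's `motion`
#'   matrix.
#' @export
extract_nuisance <- function(bold, masks) {
  d <- dim(bold$data)
  m <- .voxel_matrix(bold)
  out <- lapply(names(masks), function(nm) {
    msk <- as.logical(masks[[nm]])
    if (!any(msk)) stop("nuisance mask '", nm, "' is empty")
    sel <- which(array(msk, dim = d[1:3]))
    colMeans(m[sel, , drop = FALSE])
  })
  names(out) <- names(masks)
  out$motion <- bold$motion_params
  out
}

#' Regress confounds from every voxel
#'
#' Replaces each voxel's series by the least-squares residuals of the model
#' \[intercept, CSF, WM, soft tissue, 6 motion parameters\]. A rank-deficient
#' design (e.g. duplicated constant columns) is handled by pivoted QR --
#' residuals are the unique projection onto the complement of the column
#' space -- and the dependent columns are reported in a warning.
#'
#' @param bold a [bold_run()] (must carry `nuisance`, or pass `nuisance`).
#' @param nuisance optional list/matrix of confound series as produced by
#'   [extract_nuisance()]; defaults to the run's own traces.
#' @return the run with residual voxel series.
#' @export
regress_confounds <- function(bold, nuisance = NULL) {
  nt <- n_volumes(bold)
  if (nt <= 10) stop("need more than 10 volumes to fit 10 regressors")
  if (is.null(nuisance)) {
    if (is.null(bold$nuisance)) stop("no nuisance traces available")
    nuis <- bold$nuisance
  } else if (is.list(nuisance) && !is.matrix(nuisance)) {
    nuis <- cbind(csf = nuisance$csf, wm = nuisance$wm,
                  soft_tissue = nuisance$soft_tissue)
  } else {
    nuis <- as.matrix(nuisance)
  }
  stopifnot(nrow(nuis) == nt)
  X <- cbind(intercept = 1, nuis, bold$motion_params)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("rank-deficient confound design; dependent column(s): ",
            paste(dropped, collapse = ", "))
  }
  resid <- t(qr.resid(qx, t(.voxel_matrix(bold))))
  .matrix_to_run(bold, resid)
}

#' Linear detrend and zero-phase bandpass filter
#'
#' Per voxel: removes the best-fit line, then applies a frequency-domain
#' band-pass that keeps Fourier bins with `low_hz <= f <= high_hz` (zero
#' phase by construction). Output length equals input length.
#'
#' @param bold a [bold_run()].
#' @param low_hz,high_hz corner frequencies (Hz); defaults 0.001 and 0.1.
#' @return the filtered run.
#' @export
bandpass_detrend <- function(bold, low_hz = 0.001, high_hz = 0.1) {
  nt <- n_volumes(bold)
  tr <- bold$tr_seconds
  if (tr <= 0) stop("tr_seconds must be positive")
  nyquist <- 1 / (2 * tr)
  if (high_hz >= nyquist) {
    stop("high_hz (", high_hz, " Hz) must be below the Nyquist frequency (",
         nyquist, " Hz) at TR = ", tr, " s")
  }
  m <- .voxel_matrix(bold)
  tt <- seq_len(nt)
  X <- cbind(1, tt)
  cf <- t(qr.coef(qr(X), t(m)))
  m <- m - cf %*% t(X)

  k <- 0:(nt - 1)
  f <- pmin(k, nt - k) / (nt * tr)
  keep <- f >= low_hz & f <= high_hz
  z <- mvfft(t(m))
  z[!keep, ] <- 0
  m <- t(Re(mvfft(z, inverse = TRUE)) / nt)
  .matrix_to_run(bold, m)
}

#' Framewise displacement from realignment parameters
#'
#' Default (`method = "power"`): FD(t) is the sum of absolute backward
#' differences of the six parameters, rotations first converted to arc
#' length on a sphere of `radius_mm`. `method = "rms"` gives the
#' root-mean-square of the six (converted) differences instead. FD(1) = 0.
#'
#' @param motion_params T x 6 matrix (translations mm, rotations radians).
#' @param radius_mm rotation lever arm (mm), default 50.
#' @param method "power" (sum of absolute values) or "rms".
#' @return length-T numeric (mm).
#' @export
framewise_displacement <- function(motion_params, radius_mm = 50,
                                   method = c("power", "rms")) {
  method <- match.arg(method)
  motion_params <- as.matrix(motion_params)
  if (nrow(motion_params) < 2) stop("need at least 2 volumes")
  bad <- which(!apply(is.finite(motion_params), 1, all))
  if (length(bad) > 0) {
    stop("non-finite realignment parameters at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  d <- diff(motion_params)
  d[, 4:6] <- d[, 4:6] * radius_mm
  fd <- switch(method,
               power = rowSums(abs(d)),
               rms = sqrt(rowSums(d^2)))
  c(0, fd)
}

#' DVARS: volume-to-volume root-mean-square signal change
#'
#' DVARS(t) is the RMS over in-mask voxels of the backward signal
#' difference, expressed as a percentage of the run's mean in-mask intensity
#' (or of `reference_mean`, for data whose mean has already been removed by
#' confound regression). DVARS(1) = 0.
#'
#' @param bold a [bold_run()] or voxel-by-time matrix.
#' @param mask 3D logical mask (ignored when `bold` is already a matrix of
#'   in-mask voxels).
#' @param reference_mean optional positive reference intensity.
#' @return length-T numeric (% signal change).
#' @export
dvars <- function(bold, mask = NULL, reference_mean = NULL) {
  if (inherits(bold, "bold_run")) {
    if (is.null(mask)) stop("a brain mask is required")
    msk <- as.logical(mask)
    if (!any(msk)) stop("brain mask is empty")
    m <- .voxel_matrix(bold)[which(msk), , drop = FALSE]
  } else {
    m <- as.matrix(bold)
  }
  ref <- reference_mean %||% mean(m)
  if (!is.finite(ref) || ref <= 0) {
    stop("mean in-mask intensity must be positive (got ", ref,
         "); pass reference_mean for demeaned data")
  }
  d <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  c(0, sqrt(colMeans(d^2))) / ref * 100
}

#' Motion scrubbing
#'
#' For every volume t whose FD or DVARS exceeds `threshold`, volumes t - 1
#' and t (the pair spanning the offending transition) are flagged; the kept
#' volumes are concatenated in order.
#'
#' @param bold a [bold_run()].
#' @param fd,dvars length-T series as from [framewise_displacement()] and
#'   [dvars()].
#' @param threshold excursion threshold for both parameters, default 0.2.
#' @return list with `run` (the scrubbed [bold_run()]) and `result`, a
#'   one-row tibble (`kept_mask` as a list column, `retention_fraction`,
#'   `mean_fd_pre`, `mean_fd_post`, `n_kept`).
#' @export
scrub <- function(bold, fd, dvars, threshold = 0.2) {
  nt <- n_volumes(bold)
  stopifnot(length(fd) == nt, length(dvars) == nt)
  bad <- which(fd > threshold | dvars > threshold)
  flagged <- unique(c(bad, bad - 1L))
  flagged <- flagged[flagged >= 1L]
  kept <- setdiff(seq_len(nt), flagged)
  if (length(kept) == 0) {
    stop("all ", nt, " volumes flagged for subject ", bold$subject_id,
         ": unusable run")
  }
  kept_mask <- seq_len(nt) %in% kept
  result <- tibble(
    subject_id = bold$subject_id,
    site_id = bold$site_id,
    n_volumes = nt,
    n_kept = length(kept),
    retention_fraction = length(kept) / nt,
    mean_fd_pre = mean(fd),
    mean_fd_post = mean(fd[kept]),
    kept_mask = list(kept_mask)
  )
  list(run = .subset_volumes(bold, kept), result = result)
}

#' Temporal signal-to-noise ratio of an ROI
#'
#' Mean over time of the ROI-mean signal divided by its standard deviation
#' over time, computed on images before nuisance regression and filtering.
#' A zero temporal standard deviation is reported as `Inf` with a warning.
#'
#' @param bold a [bold_run()] at the pre-regression stage.
#' @param roi_mask 3D logical mask of the ROI (or integer voxel indices).
#' @return scalar SNR.
#' @export
roi_snr <- function(bold, roi_mask) {
  sel <- if (is.logical(roi_mask) || is.array(roi_mask)) {
    which(as.logical(roi_mask))
  } else {
    as.integer(roi_mask)
  }
  if (length(sel) == 0) stop("ROI mask is empty")
  series <- colMeans(.voxel_matrix(bold)[sel, , drop = FALSE])
  s <- sd(series)
  if (s == 0) {
    warning("ROI has zero temporal variance; SNR is infinite")
    return(Inf)
  }
  mean(series) / s
}

#' Run the preprocessing chain on one run
#'
#' Linear detrend + bandpass, then confound regression, then FD/DVARS
#' scrubbing. Filtering first keeps scanner drift and other out-of-band
#' variance from biasing the confound betas (the original analysis ran the
#' filter/detrend concurrently with the regression, which has the same
#' effect). Hub SNR is computed on the incoming (pre-cleaning) images; the
#' DVARS reference intensity is the raw in-mask mean. No spatial smoothing
#' and no global-signal regression are performed at any point.
#'
#' @param bold a [bold_run()] with nuisance traces.
#' @param atlas a `roi_atlas` (labels > 0 define the brain mask; hubs, if
#'   attached, get per-hub SNR).
#' @param low_hz,high_hz bandpass corners (Hz).
#' @param scrub_threshold FD/DVARS excursion threshold.
#' @param fd_method see [framewise_displacement()].
#' @return list with `run` (preprocessed, scrubbed), `qc` (one-row tibble),
#'   and `hub_snr` (tibble, one row per hub; empty without hubs).
#' @export
preprocess_run <- function(bold, atlas, low_hz = 0.001, high_hz = 0.1,
                           scrub_threshold = 0.2,
                           fd_method = c("power", "rms")) {
  fd_method <- match.arg(fd_method)
  mask <- atlas$labels > 0
  ref_mean <- mean(.voxel_matrix(bold)[which(mask), ])

  hub_snr <- tibble(subject_id = character(), hub = character(),
                    snr = numeric())
  if (!is.null(atlas$hubs)) {
    snr <- map_dbl(atlas$hubs$roi, function(r) {
      roi_snr(bold, atlas$labels == r)
    })
    hub_snr <- tibble(subject_id = bold$subject_id,
                      hub = atlas$hubs$name, snr = snr)
  }

  clean <- bandpass_detrend(bold, low_hz, high_hz)
  clean <- regress_confounds(clean)
  fd <- framewise_displacement(bold$motion_params, method = fd_method)
  dv <- dvars(clean, mask, reference_mean = ref_mean)
  sc <- scrub(clean, fd, dv, threshold = scrub_threshold)

  qc <- sc$result
  qc$mean_dvars <- mean(dv)
  qc$snr_mean <- if (nrow(hub_snr) > 0) mean(hub_snr$snr) else NA_real_
  list(run = sc$run, qc = qc, hub_snr = hub_snr)
}
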