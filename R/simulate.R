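# Synthetic cohort generator: template-space BOLD runs with a known,
# injectable lateralization structure, spike-contaminated realignment traces,
# independent nuisance time courses, and phenotypes drawn within the printed
# demographic ranges of the multisite autism resting-state sample the
# pipeline targets.

#' Specify a synthetic cohort
#'
#' Defaults are the package's fixed study conditions: TR 2 s, 240 volumes
#' (8 min; most real scans are under 10 min), baseline hub coupling
#' z = 0.3, motion spike rates 0.05 (control) and 0.09 (autism) per volume
#' with 0.5 mm spikes (pre-scrub mean FD near 0.11 and 0.15 mm and
#' post-scrub retention near 82% and 74%), hub signal in a 0.001-0.014 Hz
#' band with sd 100 over a baseline intensity of 15000 with a +/-150 global
#' linear scanner drift (hub SNR near 90; baseline DVARS well under the
#' 0.2% scrubbing threshold once the drift is detrended away), and white
#' voxel noise with sd 10.
#'
#' @param n_control,n_autism group sizes.
#' @param n_sites number of acquisition sites (subjects assigned round-robin
#'   within group).
#' @param grid_dims length-3 grid (x even).
#' @param voxel_mm voxel size (mm).
#' @param spacing_mm atlas lattice spacing (mm).
#' @param tr_seconds repetition time (s).
#' @param n_volumes volumes per run.
#' @param base_edge_z baseline Fisher-z coupling for every ipsilateral hub
#'   pair (both hemispheric instances).
#' @param lateralization_effects tibble with columns `connection` (canonical
#'   name, see [canonical_connection()]), `dz_control`, `dz_autism`: extra
#'   Fisher-z coupling injected on the left-hemisphere instance of the named
#'   connection, per group. The homologous right-hemisphere pair keeps
#'   `base_edge_z`, so the expected lateralization index of the connection is
#'   +dz on a left-lateralized pair and -dz on a right-lateralized pair.
#' @param motion_spike_rate named per-volume spike probabilities,
#'   `c(control = , autism = )`.
#' @param spike_mm translation magnitude of a motion spike (mm).
#' @param noise_sd white voxel noise sd (signal units).
#' @param signal_sd sd of the band-limited latent ROI signal.
#' @param baseline mean voxel intensity.
#' @param drift_amplitude temporal sd of the global linear scanner drift
#'   (sign randomised per subject); inflates raw-image ROI variance as real
#'   scanner drift does, and is removed by the detrend step.
#' @param signal_band_hz frequency band of the latent signal.
#' @param seed integer master seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_control = 20, n_autism = 20, n_sites = 2,
                        grid_dims = c(24, 24, 16), voxel_mm = 3,
                        spacing_mm = 6, tr_seconds = 2, n_volumes = 240,
                        base_edge_z = 0.3,
                        lateralization_effects = NULL,
                        motion_spike_rate = c(control = 0.05, autism = 0.09),
                        spike_mm = 0.5, noise_sd = 10, signal_sd = 100,
                        baseline = 15000, drift_amplitude = 150,
                        signal_band_hz = c(0.001, 0.014),
                        seed = 1L) {
  if (is.null(lateralization_effects)) {
    lateralization_effects <- tibble(connection = character(),
                                     dz_control = numeric(),
                                     dz_autism = numeric())
  }
  lateralization_effects <- as_tibble(lateralization_effects)
  spec <- list(
    n_control = n_control, n_autism = n_autism, n_sites = n_sites,
    grid_dims = as.integer(grid_dims), voxel_mm = rep_len(voxel_mm, 3),
    spacing_mm = spacing_mm, tr_seconds = tr_seconds,
    n_volumes = as.integer(n_volumes), base_edge_z = base_edge_z,
    lateralization_effects = lateralization_effects,
    motion_spike_rate = motion_spike_rate, spike_mm = spike_mm,
    noise_sd = noise_sd, signal_sd = signal_sd, baseline = baseline,
    drift_amplitude = drift_amplitude,
    signal_band_hz = signal_band_hz, seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_control >= 0, spec$n_autism >= 0,
            length(spec$grid_dims) == 3, spec$n_volumes >= 2,
            spec$tr_seconds > 0)
  if (spec$grid_dims[1] %% 2 != 0) {
    stop("grid x-dimension must be even, got ", spec$grid_dims[1])
  }
  if (!all(is.finite(spec$lateralization_effects$dz_control)) ||
      !all(is.finite(spec$lateralization_effects$dz_autism))) {
    stop("lateralization effect sizes must be finite")
  }
  rates <- spec$motion_spike_rate
  if (!all(c("control", "autism") %in% names(rates)) ||
      any(rates < 0) || any(rates > 1)) {
    stop("motion_spike_rate must be named (control, autism) ",
         "probabilities in [0, 1]")
  }
  invisible(spec)
}

#' Canonical connection name
#'
#' Unordered hub pair encoded as the alphabetically sorted names joined by
#' `" ~ "`; used to address connections in effect specifications and result
#' tables.
#' @param a,b hub names (vectorised).
#' @export
canonical_connection <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = " ~ ")
}

#' Map a diagnosis to its analysis group
#'
#' `control` maps to "control"; `autism`, `asperger` and `pdd_nos` all map to
#' "autism" (the autism-spectrum group); strict-diagnosis subsetting is done
#' by the inclusion criteria, not here.
#' @param diagnosis character vector.
#' @export
dx_group <- function(diagnosis) {
  ifelse(diagnosis == "control", "control", "autism")
}

.sample_cat <- function(n, values, weights) {
  values[sample.int(length(values), n, replace = TRUE, prob = weights)]
}

#' Simulate a phenotype table
#'
#' Continuous measures are uniform within the printed demographic ranges of
#' the target sample (age, verbal/performance IQ, ADOS domain totals,
#' quantitative handedness magnitude); categorical shares (sex, handedness
#' category, diagnosis subtype, ADOS availability for controls) follow the
#' printed category counts. About 1.5% of subjects lack any handedness
#' measure; roughly a third have only the quantitative measure.
#'
#' @param spec a [cohort_spec()].
#' @return tibble, one row per subject.
#' @export
simulate_phenotypes <- function(spec) {
  groups <- c(rep("control", spec$n_control), rep("autism", spec$n_autism))
  n <- length(groups)
  if (n == 0) stop("empty cohort")
  site <- unlist(lapply(c(spec$n_control, spec$n_autism), function(k) {
    if (k == 0) character(0)
    else paste0("site", rep_len(seq_len(spec$n_sites), k))
  }))
  is_aut <- groups == "autism"

  diagnosis <- ifelse(is_aut,
                      .sample_cat(n, c("autism", "asperger", "pdd_nos"),
                                  c(0.63, 0.25, 0.12)),
                      "control")
  age <- ifelse(is_aut, runif(n, 7, 64), runif(n, 6.47, 56.2))
  sex <- ifelse(is_aut,
                .sample_cat(n, c("M", "F"), c(396, 51)),
                .sample_cat(n, c("M", "F"), c(426, 91)))
  verbal_iq <- round(ifelse(is_aut, runif(n, 50, 149), runif(n, 67, 147)))
  performance_iq <- round(ifelse(is_aut, runif(n, 59, 157),
                                 runif(n, 67, 155)))

  hand_cat <- ifelse(is_aut,
                     .sample_cat(n, c("R", "L", "A"), c(378, 58, 4)),
                     .sample_cat(n, c("R", "L", "A"), c(472, 34, 3)))
  hand_quant <- ifelse(hand_cat == "R", runif(n, 0.5, 100),
                       ifelse(hand_cat == "L", runif(n, -100, -0.5), 0))
  u <- runif(n)
  hand_cat[u < 0.10] <- NA                 # quantitative-only subjects
  hand_quant[u >= 0.10 & u < 0.70] <- NA   # categorical-only subjects
  both_missing <- u >= 0.985
  hand_cat[both_missing] <- NA
  hand_quant[both_missing] <- NA

  ados_social <- ifelse(is_aut, round(runif(n, 1, 14)), round(runif(n, 0, 2)))
  ados_communication <- ifelse(is_aut, round(runif(n, 1, 8)),
                               round(runif(n, 0, 2)))
  ados_missing <- !is_aut & runif(n) > 0.062
  ados_social[ados_missing] <- NA
  ados_communication[ados_missing] <- NA

  tibble(
    subject_id = sprintf("sub%04d", seq_len(n)),
    site_id = site,
    diagnosis = diagnosis,
    group = groups,
    age = age, sex = sex,
    handedness_cat = hand_cat, handedness_quant = hand_quant,
    verbal_iq = verbal_iq, performance_iq = performance_iq,
    ados_social = ados_social, ados_communication = ados_communication
  )
}

# Frequency-domain synthesis of band-limited unit-variance noise columns;
# the same mask is applied to every column so cross-correlations injected
# before filtering are preserved.
.bandlimited_noise <- function(nt, ncols, tr, band) {
  k <- 0:(nt - 1)
  f <- pmin(k, nt - k) / (nt * tr)
  keep <- f >= band[1] & f <= band[2]
  m <- sum(keep)
  if (m == 0) stop("signal band contains no Fourier bin at this T and TR")
  w <- matrix(rnorm(nt * ncols), nt, ncols)
  z <- mvfft(w)
  z[!keep, ] <- 0
  Re(mvfft(z, inverse = TRUE)) / nt * sqrt(nt / m)
}

# Latent ROI correlation matrix for one group: baseline coupling on every
# ipsilateral hub pair (both hemispheric instances) plus the group's injected
# effect on the left-hemisphere instance of each named connection.
.latent_correlation <- function(spec, atlas, group) {
  conns <- enumerate_connections(atlas$hubs, include_mixed = FALSE)
  eff <- spec$lateralization_effects
  dz_col <- if (group == "control") "dz_control" else "dz_autism"
  dz <- eff[[dz_col]][match(conns$connection, eff$connection)]
  dz[is.na(dz)] <- 0

  hom <- atlas$homologue
  left_a <- ifelse(conns$laterality_class == "left-lateralized",
                   conns$roi_a, hom[conns$roi_a])
  left_b <- ifelse(conns$laterality_class == "left-lateralized",
                   conns$roi_b, hom[conns$roi_b])
  right_a <- hom[left_a]
  right_b <- hom[left_b]

  pairs <- tibble(
    a = c(left_a, right_a), b = c(left_b, right_b),
    r = tanh(c(spec$base_edge_z + dz, rep(spec$base_edge_z, nrow(conns)))),
    connection = rep(conns$connection, 2)
  )
  rois <- sort(unique(c(pairs$a, pairs$b)))
  C <- diag(1, length(rois))
  ia <- match(pairs$a, rois); ib <- match(pairs$b, rois)
  for (i in seq_len(nrow(pairs))) {
    cur <- C[ia[i], ib[i]]
    if (cur != 0 && abs(cur - pairs$r[i]) > 1e-12) {
      stop("conflicting couplings requested for ROI pair of connection ",
           pairs$connection[i])
    }
    C[ia[i], ib[i]] <- pairs$r[i]
    C[ib[i], ia[i]] <- pairs$r[i]
  }
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    stop("requested couplings imply a non-positive-definite latent ",
         "covariance; offending connections: ",
         paste(unique(pairs$connection[abs(pairs$r) ==
                                         max(abs(pairs$r))]), collapse = ", "))
  }
  list(rois = rois, chol = ch, connections = conns)
}

.simulate_motion <- function(spec, rate) {
  nt <- spec$n_volumes
  t_sec <- (seq_len(nt) - 1) * spec$tr_seconds
  motion <- matrix(0, nt, 6)
  for (j in 1:6) {
    f <- runif(1, 0.005, 0.02)
    a <- 0.01 / (4 * f * spec$tr_seconds)   # mean |step| ~ 0.01 mm
    if (j > 3) a <- a / 50                  # rotations: 50 mm lever arm
    motion[, j] <- a * sin(2 * pi * f * t_sec + runif(1, 0, 2 * pi))
  }
  spikes <- which(runif(nt) < rate)
  spikes <- spikes[spikes > 1]
  for (s in spikes) {
    ax <- sample.int(3, 1)
    motion[s, ax] <- motion[s, ax] + sample(c(-1, 1), 1) * spec$spike_mm
  }
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  motion
}

#' Simulate one subject's BOLD run
#'
#' Hub (and every other lattice ROI) time courses are band-limited latent
#' Gaussian signals; pairwise latent correlations equal
#' `tanh(base_edge_z [+ dz])` as described in [cohort_spec()]. Each voxel is
#' baseline + its ROI's latent signal + independent white noise. Realignment
#' parameters are smooth sinusoidal drifts plus single-volume translation
#' spikes at the group's spike rate; CSF/WM/soft-tissue nuisance traces are
#' generated independently of the hub signals.
#'
#' @param spec a [cohort_spec()].
#' @param subject one row of a phenotype table (needs `subject_id`,
#'   `site_id`, `group`).
#' @param atlas a symmetric `roi_atlas` with hubs attached.
#' @param seed optional integer; if `NULL` the current RNG stream is used
#'   (as [simulate_cohort()] does).
#' @return a [bold_run()] with nuisance traces attached.
#' @export
simulate_subject <- function(spec, subject, atlas, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(atlas$hubs)) stop("atlas has no hubs attached")
  group <- subject$group %||% dx_group(subject$diagnosis)
  lat <- .latent_correlation(spec, atlas, group)

  nt <- spec$n_volumes
  n_rois <- atlas$n_rois
  w <- matrix(rnorm(nt * n_rois), nt, n_rois)
  w[, lat$rois] <- w[, lat$rois, drop = FALSE] %*% lat$chol
  latent <- .bandlimited_noise_apply(w, spec) * spec$signal_sd

  lab <- as.vector(atlas$labels)
  nv <- length(lab)
  data <- matrix(rnorm(nv * nt, sd = spec$noise_sd), nv, nt) + spec$baseline
  sel <- lab > 0
  data[sel, ] <- data[sel, ] + t(latent)[lab[sel], , drop = FALSE]
  if (spec$drift_amplitude > 0) {   # global scanner drift, detrended later
    ramp <- seq_len(nt) - (nt + 1) / 2
    ramp <- ramp / sd(ramp) * spec$drift_amplitude * sample(c(-1, 1), 1)
    data <- data + matrix(ramp, nv, nt, byrow = TRUE)
  }

  motion <- .simulate_motion(spec, spec$motion_spike_rate[[group]])
  nuis <- .bandlimited_noise(nt, 3, spec$tr_seconds, c(0.001, 0.05)) * 20
  colnames(nuis) <- c("csf", "wm", "soft_tissue")

  bold_run(array(data, dim = c(spec$grid_dims, nt)),
           tr_seconds = spec$tr_seconds, voxel_mm = spec$voxel_mm,
           motion_params = motion, subject_id = subject$subject_id,
           site_id = subject$site_id, nuisance = nuis)
}

# Band-limit pre-correlated white columns with the cohort's signal band.
.bandlimited_noise_apply <- function(w, spec) {
  nt <- nrow(w)
  k <- 0:(nt - 1)
  f <- pmin(k, nt - k) / (nt * spec$tr_seconds)
  keep <- f >= spec$signal_band_hz[1] & f <= spec$signal_band_hz[2]
  m <- sum(keep)
  if (m == 0) stop("signal band contains no Fourier bin at this T and TR")
  z <- mvfft(w)
  z[!keep, ] <- 0
  Re(mvfft(z, inverse = TRUE)) / nt * sqrt(nt / m)
}

#' Simulate a whole cohort
#'
#' Deterministic given `spec$seed`: phenotypes are drawn first, then subjects
#' in table order from one RNG stream.
#'
#' @param spec a [cohort_spec()].
#' @param atlas optional prebuilt symmetric atlas with hubs; by default one
#'   is built from the spec grid with [hub_table_synthetic20()] when the grid
#'   accommodates it, else a small auto-placed hub set.
#' @param callback optional `function(run, subject)` applied to each run as
#'   it is generated (streaming mode); its return values are collected in
#'   `$processed` and the runs themselves are discarded.
#' @return list with `phenotypes`, `atlas`, and `runs` (or `processed`).
#' @export
simulate_cohort <- function(spec, atlas = NULL, callback = NULL) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  if (is.null(atlas)) atlas <- default_cohort_atlas(spec)
  phen <- simulate_phenotypes(spec)
  out <- vector("list", nrow(phen))
  for (i in seq_len(nrow(phen))) {
    run <- simulate_subject(spec, phen[i, ], atlas)
    out[[i]] <- if (is.null(callback)) run else callback(run, phen[i, ])
  }
  res <- list(phenotypes = phen, atlas = atlas)
  if (is.null(callback)) res$runs <- out else res$processed <- out
  res
}

#' Default atlas for a cohort spec
#'
#' Builds the mirror-symmetric lattice for the spec's grid and attaches the
#' shipped synthetic 20-hub table when it fits inside the grid, otherwise a
#' small auto-placed hub set (2 left + 2 right).
#' @param spec a [cohort_spec()].
#' @export
default_cohort_atlas <- function(spec) {
  atlas <- make_symmetric_atlas(spec$grid_dims, spec$voxel_mm,
                                spec$spacing_mm)
  hubs <- hub_table_synthetic20()
  fits <- tryCatch({
    attach_hubs(atlas, hubs, quiet = TRUE)
  }, error = function(e) NULL)
  if (!is.null(fits)) return(fits)
  attach_hubs(atlas, synthetic_hub_table(atlas, 2, 2), quiet = TRUE)
}

#' The shipped synthetic 20-hub table
#'
#' Nine left-network and eleven right-network hubs with synthetic coordinates
#' on the default 24 x 24 x 16 (3 mm) test grid, named after the standard
#' lateralization-hub abbreviations. These are NOT real template coordinates
#' (the published hub coordinates live in prior work and are a user-supplied
#' config in real analyses); see `inst/extdata/hubs_template.csv` for the
#' expected columns.
#' @return tibble with columns name, hemisphere, x, y, z, network,
#'   is_language.
#' @export
hub_table_synthetic20 <- function() {
  path <- system.file("extdata", "hubs_synthetic_20.csv",
                      package = "hemiflip")
  read_hub_table(path)
}

#' Auto-place a small synthetic hub set on an atlas
#'
#' Picks well-separated ROI centroids, `n_left` in the left hemisphere and
#' `n_right` in the right (avoiding exact mirrors of the chosen left hubs);
#' the first `min(2, n_left)` left hubs are tagged as language hubs.
#' @param atlas a symmetric `roi_atlas`.
#' @param n_left,n_right hub counts per hemisphere.
#' @export
synthetic_hub_table <- function(atlas, n_left = 2, n_right = 2) {
  cen <- atlas$centroids
  pick_spread <- function(cand, k, exclude = integer(0)) {
    cand <- cand[!(cand$roi %in% exclude), ]
    if (nrow(cand) < k) stop("not enough ROIs to place ", k, " hubs")
    if (k == 0) return(integer(0))
    cand <- cand[order(cand$x, cand$y, cand$z), ]
    idx <- round(seq(1, nrow(cand), length.out = k))
    cand$roi[idx]
  }
  left <- pick_spread(cen[cen$x < 0, ], n_left)
  right <- pick_spread(cen[cen$x > 0, ], n_right,
                       exclude = atlas$homologue[left])
  rois <- c(left, right)
  lab <- function(prefix, n) {
    if (n == 0) character(0) else paste0(prefix, seq_len(n))
  }
  tibble(
    name = c(lab("L", n_left), lab("R", n_right)),
    hemisphere = rep(c("L", "R"), c(n_left, n_right)),
    x = cen$x[rois], y = cen$y[rois], z = cen$z[rois],
    network = rep(c("left-lateralized", "right-lateralized"),
                  c(n_left, n_right)),
    is_language = c(seq_len(n_left) <= min(2, n_left),
                    rep(FALSE, n_right))
  )
}
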