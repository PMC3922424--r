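# Fisher-z connectivity, the flip-based lateralization index, and the
# hub-connection sets. The lateralization index of a within-hemisphere ROI
# pair is the unflipped-minus-flipped Fisher-z correlation: positive on a
# left-hemisphere pair means left lateralization, and a right-lateralized
# right-hemisphere pair has a negative index by the same convention.

#' Fisher-z connectivity matrix from ROI time courses
#'
#' Pearson correlations between all ROI pairs, clipped to |r| <= 1 - 1e-12
#' and Fisher transformed (atanh). Zero-variance ROIs get missing rows and
#' columns (reported in a warning); the diagonal is undefined (NA).
#'
#' @param tc a `timecourse_matrix` from [extract_timecourses()], or a plain
#'   R x T matrix.
#' @return a `conn_matrix`: list with `z` (R x R), `roi_ids`, `subject_id`,
#'   `flipped`.
#' @export
fisher_connectivity <- function(tc) {
  if (inherits(tc, "timecourse_matrix")) {
    values <- tc$values
    subject_id <- tc$subject_id
    flipped <- tc$flipped
    roi_ids <- tc$roi_ids
  } else {
    values <- as.matrix(tc)
    subject_id <- NA_character_
    flipped <- FALSE
    roi_ids <- seq_len(nrow(values))
  }
  if (ncol(values) < 3) stop("need at least 3 volumes after scrubbing")
  sds <- apply(values, 1, sd)
  degenerate <- which(sds == 0)
  if (length(degenerate) > 0) {
    warning("zero-variance ROI(s): ",
            paste(roi_ids[degenerate], collapse = ", "),
            "; their correlations are reported missing")
  }
  r <- suppressWarnings(cor(t(values)))
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(r)
  diag(z) <- NA_real_
  structure(
    list(z = z, roi_ids = roi_ids, subject_id = subject_id,
         flipped = flipped),
    class = "conn_matrix"
  )
}

#' Enumerate hub connections
#'
#' All unordered ipsilateral (within-network) hub pairs: with the full hub
#' set of 9 left-lateralized and 11 right-lateralized hubs this gives
#' choose(9,2) = 36 left and choose(11,2) = 55 right connections, the left
#' set splitting into 15 language-involving and 21 non-language connections.
#' With `include_mixed = TRUE`, left-right hub pairs are added, evaluated
#' after mapping the right hub to its mirrored left-hemisphere ROI; mixed
#' connections serve pattern maps only and are excluded from group testing.
#'
#' @param hubs the `hubs` tibble of an atlas (needs `name`, `network`,
#'   `is_language`, `roi`) or a [bold_run()]-independent hub table already
#'   attached to an atlas.
#' @param atlas required when `include_mixed = TRUE` (for the homologue
#'   map).
#' @param include_mixed include contralateral pairs.
#' @return tibble: `connection`, `hub_a`, `hub_b`, `roi_a`, `roi_b`,
#'   `laterality_class`, `group`.
#' @export
enumerate_connections <- function(hubs, include_mixed = FALSE,
                                  atlas = NULL) {
  if (inherits(hubs, "roi_atlas")) {
    atlas <- hubs
    hubs <- atlas$hubs
  }
  if (is.null(hubs)) stop("no hubs attached to this atlas")
  pair_up <- function(idx) {
    if (length(idx) < 2) {
      return(tibble(a = integer(), b = integer()))
    }
    cmb <- utils::combn(idx, 2)
    tibble(a = cmb[1, ], b = cmb[2, ])
  }
  left <- which(hubs$network == "left-lateralized")
  right <- which(hubs$network == "right-lateralized")
  lp <- pair_up(left)
  rp <- pair_up(right)
  build <- function(p, cls) {
    if (nrow(p) == 0) return(NULL)
    lang <- hubs$is_language[p$a] | hubs$is_language[p$b]
    grp <- if (cls == "left-lateralized") {
      ifelse(lang, "left-language", "left-nonlanguage")
    } else {
      "right"
    }
    tibble(
      connection = canonical_connection(hubs$name[p$a], hubs$name[p$b]),
      hub_a = hubs$name[p$a], hub_b = hubs$name[p$b],
      roi_a = hubs$roi[p$a], roi_b = hubs$roi[p$b],
      laterality_class = cls, group = grp
    )
  }
  out <- bind_rows(build(lp, "left-lateralized"),
                   build(rp, "right-lateralized"))
  if (include_mixed) {
    if (is.null(atlas)) stop("include_mixed = TRUE needs the atlas")
    mix <- expand.grid(a = left, b = right)
    out <- bind_rows(out, tibble(
      connection = canonical_connection(hubs$name[mix$a], hubs$name[mix$b]),
      hub_a = hubs$name[mix$a], hub_b = hubs$name[mix$b],
      roi_a = hubs$roi[mix$a],
      roi_b = atlas$homologue[hubs$roi[mix$b]],
      laterality_class = "mixed", group = "mixed"
    ))
  }
  out
}

#' Per-connection lateralization index
#'
#' li(c) = z_unflipped\[a, b\] - z_flipped\[a, b\] for each connection.
#' Missing correlations (zero-variance ROIs) propagate to missing li.
#'
#' @param z_unflipped,z_flipped `conn_matrix` objects for the same subject,
#'   unflipped and flipped.
#' @param connections tibble from [enumerate_connections()].
#' @return tibble: `subject_id`, `connection`, `hub_a`, `hub_b`,
#'   `laterality_class`, `group`, `li`.
#' @export
lateralization_index <- function(z_unflipped, z_flipped, connections) {
  if (!is.na(z_unflipped$subject_id) && !is.na(z_flipped$subject_id) &&
      z_unflipped$subject_id != z_flipped$subject_id) {
    stop("unflipped and flipped matrices come from different subjects")
  }
  if (isTRUE(z_unflipped$flipped) == isTRUE(z_flipped$flipped)) {
    stop("the two matrices must differ in flip state ",
         "(one extracted from the mirrored run)")
  }
  idx <- cbind(connections$roi_a, connections$roi_b)
  li <- z_unflipped$z[idx] - z_flipped$z[idx]
  tibble(
    subject_id = z_unflipped$subject_id,
    connection = connections$connection,
    hub_a = connections$hub_a, hub_b = connections$hub_b,
    laterality_class = connections$laterality_class,
    group = connections$group,
    li = li
  )
}

#' Lateralization table for one preprocessed run
#'
#' Extracts ROI time courses from the run and from its midsagittal flip,
#' computes both Fisher-z matrices, and returns the per-connection
#' lateralization index.
#'
#' @param run a preprocessed, scrubbed [bold_run()].
#' @param atlas the symmetric `roi_atlas` with hubs.
#' @param connections optional connection table (defaults to the ipsilateral
#'   set of the atlas hubs).
#' @return tibble as from [lateralization_index()].
#' @export
subject_lateralization <- function(run, atlas, connections = NULL) {
  if (is.null(connections)) connections <- enumerate_connections(atlas)
  z_unf <- fisher_connectivity(extract_timecourses(run, atlas))
  z_fl <- fisher_connectivity(
    extract_timecourses(flip_midsagittal(run), atlas)
  )
  lateralization_index(z_unf, z_fl, connections)
}

#' Per-subject means over the three connection groups
#'
#' Averages li over 1) left-lateralized connections involving a language hub,
#' 2) left-lateralized connections not involving one, and 3) right-lateralized
#' connections (raw li; the sign convention for "degree of lateralization"
#' contrasts is applied by [paired_group_contrasts()]). Missing li values are
#' excluded from the means and counted.
#'
#' @param li_table tibble from [subject_lateralization()] rows.
#' @return tibble: `subject_id`, `left_language`, `left_nonlanguage`,
#'   `right`, `n_missing`.
#' @export
connection_group_means <- function(li_table) {
  li_table |>
    filter(.data$group %in%
             c("left-language", "left-nonlanguage", "right")) |>
    group_by(.data$subject_id) |>
    summarise(
      left_language = mean(.data$li[.data$group == "left-language"],
                           na.rm = TRUE),
      left_nonlanguage = mean(.data$li[.data$group == "left-nonlanguage"],
                              na.rm = TRUE),
      right = mean(.data$li[.data$group == "right"], na.rm = TRUE),
      n_missing = sum(is.na(.data$li)),
      .groups = "drop"
    ) |>
    mutate(dplyr::across(c("left_language", "left_nonlanguage", "right"),
                         function(x) ifelse(is.nan(x), NA_real_, x)))
}
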