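# Subject inclusion criteria. The base criteria keep subjects from sites
# contributing at least `min_site_n` usable subjects; the stricter
# restrictions (named presets B-H) add, singly or in tandem: scrubbing
# retention >= 50%, exclusion of sites possibly overlapping the samples the
# hub set was derived from, right-handed only, male only, strict autism
# diagnosis only, and per-group verbal-IQ matching windows (autism 80-130,
# control 70-120).

#' Define subject inclusion criteria
#'
#' @param retention_min minimum scrubbing retention fraction (e.g. 0.5), or
#'   `NULL` for no restriction.
#' @param exclude_sites character vector of site ids to drop (sample-overlap
#'   exclusion), or `NULL`.
#' @param right_handed_only keep only right-handed subjects (after
#'   [recode_handedness()]); subjects with no handedness measure are dropped
#'   under this restriction (they are retained everywhere else).
#' @param male_only keep only males.
#' @param strict_autism_only drop `asperger` / `pdd_nos` diagnoses.
#' @param verbal_iq_windows `NULL`, or a list with closed intervals
#'   `control` and `autism`; subjects missing verbal IQ are excluded when a
#'   window applies to their group.
#' @param min_site_n minimum usable subjects per site (base criterion),
#'   default 20.
#' @return an `inclusion_criteria` object.
#' @export
inclusion_criteria <- function(retention_min = NULL, exclude_sites = NULL,
                               right_handed_only = FALSE, male_only = FALSE,
                               strict_autism_only = FALSE,
                               verbal_iq_windows = NULL, min_site_n = 20) {
  structure(
    list(retention_min = retention_min, exclude_sites = exclude_sites,
         right_handed_only = right_handed_only, male_only = male_only,
         strict_autism_only = strict_autism_only,
         verbal_iq_windows = verbal_iq_windows, min_site_n = min_site_n),
    class = "inclusion_criteria"
  )
}

#' Named criteria presets A-H
#'
#' A is the base analysis; B-H add single restrictions or the retention +
#' site-overlap tandem: B = retention >= 50%; C = overlap-site exclusion;
#' D = B + C; E = right-handed only; F = male only; G = strict autism
#' diagnosis; H = verbal-IQ windows (autism 80-130, control 70-120).
#'
#' @param preset one of "A".."H".
#' @param exclude_sites site list used by presets C and D (the overlap set
#'   is dataset-specific and must be supplied).
#' @param min_site_n base per-site minimum, default 20.
#' @return an [inclusion_criteria()] object.
#' @export
criteria_preset <- function(preset = LETTERS[1:8], exclude_sites = NULL,
                            min_site_n = 20) {
  preset <- match.arg(preset)
  iq <- list(control = c(70, 120), autism = c(80, 130))
  args <- switch(preset,
    A = list(),
    B = list(retention_min = 0.5),
    C = list(exclude_sites = exclude_sites),
    D = list(retention_min = 0.5, exclude_sites = exclude_sites),
    E = list(right_handed_only = TRUE),
    F = list(male_only = TRUE),
    G = list(strict_autism_only = TRUE),
    H = list(verbal_iq_windows = iq)
  )
  args$min_site_n <- min_site_n
  do.call(inclusion_criteria, args)
}

#' Recode handedness from the quantitative measure
#'
#' Where the categorical measure is missing but the -100..+100 quantitative
#' measure is present: positive values become right-handed, negative values
#' left-handed, and zero ambidextrous.
#'
#' @param phenotypes phenotype tibble.
#' @return the tibble with `handedness_cat` filled in.
#' @export
recode_handedness <- function(phenotypes) {
  phenotypes |>
    mutate(handedness_cat = case_when(
      !is.na(.data$handedness_cat) ~ .data$handedness_cat,
      is.na(.data$handedness_quant) ~ NA_character_,
      .data$handedness_quant > 0 ~ "R",
      .data$handedness_quant < 0 ~ "L",
      TRUE ~ "A"
    ))
}

#' Apply inclusion criteria to a cohort
#'
#' Handedness recoding is applied first; then, in order: retention,
#' site-overlap exclusion, handedness, sex, diagnosis, verbal-IQ window, and
#' finally the base per-site minimum. Per-step exclusion counts are attached
#' as the `"exclusions"` attribute.
#'
#' @param phenotypes phenotype tibble (one row per subject).
#' @param qc QC tibble with `subject_id` and `retention_fraction`.
#' @param criteria an [inclusion_criteria()] or preset letter.
#' @return the included subset of `phenotypes` (joined with retention).
#' @export
apply_inclusion <- function(phenotypes, qc, criteria = "A") {
  if (is.character(criteria)) criteria <- criteria_preset(criteria)
  stopifnot(inherits(criteria, "inclusion_criteria"))
  df <- recode_handedness(phenotypes) |>
    left_join(select(qc, "subject_id", "retention_fraction"),
              by = "subject_id")
  steps <- list()
  note <- function(df, step) {
    steps[[length(steps) + 1]] <<- tibble(step = step, n_remaining = nrow(df))
    if (nrow(df) == 0) {
      stop("inclusion criteria exclude every subject at step: ", step)
    }
    df
  }
  df <- note(df, "base")
  if (!is.null(criteria$retention_min)) {
    df <- note(filter(df, !is.na(.data$retention_fraction) &
                        .data$retention_fraction >= criteria$retention_min),
               "retention")
  }
  if (!is.null(criteria$exclude_sites)) {
    df <- note(filter(df, !(.data$site_id %in% criteria$exclude_sites)),
               "overlap_sites")
  }
  if (isTRUE(criteria$right_handed_only)) {
    df <- note(filter(df, !is.na(.data$handedness_cat) &
                        .data$handedness_cat == "R"),
               "right_handed")
  }
  if (isTRUE(criteria$male_only)) {
    df <- note(filter(df, .data$sex == "M"), "male")
  }
  if (isTRUE(criteria$strict_autism_only)) {
    df <- note(filter(df, .data$diagnosis %in% c("control", "autism")),
               "strict_dx")
  }
  if (!is.null(criteria$verbal_iq_windows)) {
    w <- criteria$verbal_iq_windows
    df <- note(filter(df, ifelse(
      .data$group == "autism",
      !is.na(.data$verbal_iq) & .data$verbal_iq >= w$autism[1] &
        .data$verbal_iq <= w$autism[2],
      !is.na(.data$verbal_iq) & .data$verbal_iq >= w$control[1] &
        .data$verbal_iq <= w$control[2]
    )), "verbal_iq")
  }
  if (!is.null(criteria$min_site_n) && criteria$min_site_n > 0) {
    counts <- dplyr::count(df, .data$site_id)
    keep_sites <- counts$site_id[counts$n >= criteria$min_site_n]
    df <- note(filter(df, .data$site_id %in% keep_sites), "min_site_n")
  }
  attr(df, "exclusions") <- bind_rows(steps)
  df
}
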