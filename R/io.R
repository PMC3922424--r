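# File interfaces: 4D NIfTI volumes, 6-column plain-text realignment
# parameters, hub tables and tidy result CSVs.

#' Read a hub table CSV
#'
#' Expected columns: `name`, `hemisphere` (L/R), `x`, `y`, `z` (template
#' mm), `network` (left-lateralized/right-lateralized), `is_language`
#' (logical). `inst/extdata/hubs_template.csv` documents the format;
#' `inst/extdata/hubs_synthetic_20.csv` is a synthetic 20-hub example.
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_hub_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  df$is_language <- as.logical(df$is_language)
  df
}

#' Write a BOLD run to disk
#'
#' Writes the 4D series as NIfTI (voxel dimensions and TR in the header) and
#' the realignment parameters as a 6-column whitespace-delimited text file
#' (translations mm, rotations radians), plus the nuisance traces as CSV if
#' present.
#'
#' @param run a [bold_run()].
#' @param dir output directory (created if needed).
#' @param stem file stem; defaults to the subject id.
#' @return invisibly, the paths written.
#' @export
write_bold_run <- function(run, dir, stem = NULL) {
  stem <- stem %||% run$subject_id
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nii_path <- file.path(dir, paste0(stem, "_bold.nii.gz"))
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(run$voxel_mm, run$tr_seconds)
  RNifti::writeNifti(img, nii_path)
  rp_path <- file.path(dir, paste0("rp_", stem, ".txt"))
  utils::write.table(run$motion_params, rp_path, row.names = FALSE,
                     col.names = FALSE)
  paths <- c(bold = nii_path, motion = rp_path)
  if (!is.null(run$nuisance)) {
    np <- file.path(dir, paste0(stem, "_nuisance.csv"))
    readr::write_csv(as_tibble(run$nuisance), np)
    paths["nuisance"] <- np
  }
  invisible(paths)
}

#' Read a BOLD run from disk
#'
#' @param bold_path 4D NIfTI path.
#' @param motion_path 6-column whitespace-delimited realignment file.
#' @param tr_seconds repetition time; taken from the NIfTI header when
#'   `NULL`.
#' @param subject_id,site_id identifiers.
#' @param nuisance_path optional nuisance CSV (columns csf, wm,
#'   soft_tissue).
#' @return a [bold_run()].
#' @export
read_bold_run <- function(bold_path, motion_path, tr_seconds = NULL,
                          subject_id = NA_character_,
                          site_id = NA_character_, nuisance_path = NULL) {
  img <- RNifti::readNifti(bold_path)
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  data <- array(as.numeric(img), dim = dim(img))
  motion <- as.matrix(utils::read.table(motion_path))
  nuis <- NULL
  if (!is.null(nuisance_path)) {
    nuis <- as.matrix(readr::read_csv(nuisance_path,
                                      show_col_types = FALSE))
  }
  bold_run(data,
           tr_seconds = tr_seconds %||% (if (length(pd) >= 4) pd[4] else
             stop("TR not in header; pass tr_seconds")),
           voxel_mm = pd[1:3], motion_params = motion,
           subject_id = subject_id, site_id = site_id, nuisance = nuis)
}

#' Write a cohort to disk
#'
#' One NIfTI + realignment file per subject and a phenotype CSV, as produced
#' by [simulate_cohort()].
#'
#' @param cohort list with `runs` and `phenotypes`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (run in cohort$runs) write_bold_run(run, dir)
  readr::write_csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  invisible(dir)
}

#' Write study result tables
#'
#' Tidy CSVs (lateralization table, QC, one- and two-sample results,
#' contrasts, correlations) plus a JSON summary with the manifest.
#'
#' @param study a `hemiflip_study`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(lateralization = study$li,
                 qc = select(study$qc, -"kept_mask"),
                 one_sample = study$one_sample,
                 two_sample = study$two_sample,
                 contrasts = study$contrasts,
                 correlations = study$correlations)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    paths[nm] <- p
  }
  sm <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(manifest = study$manifest, glance = glance(study)),
    sm, auto_unbox = TRUE, digits = NA
  )
  paths["summary"] <- sm
  invisible(paths)
}
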