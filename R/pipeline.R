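# End-to-end orchestration: simulate (or load) -> preprocess -> extract ->
# lateralize -> test, from one config, with a QC table and a reproducibility
# manifest.

default_config <- function() {
  list(
    cohort = list(),
    preprocess = list(low_hz = 0.001, high_hz = 0.1, scrub_threshold = 0.2,
                      fd_method = "power"),
    criteria = "A",
    exclude_sites = NULL,
    min_site_n = 20,
    q = 0.05,
    include_mixed = FALSE,
    seed = 1L
  )
}

#' Load and normalise a study configuration
#'
#' @param config a list, or the path of a YAML file. Recognised fields:
#'   `cohort` (arguments of [cohort_spec()], including
#'   `lateralization_effects` as a list of `connection`/`dz_control`/
#'   `dz_autism` entries), `preprocess` (`low_hz`, `high_hz`,
#'   `scrub_threshold`, `fd_method`), `hubs` (path of a hub CSV; default the
#'   shipped synthetic 20-hub table when it fits the grid), `criteria`
#'   (preset letter), `exclude_sites`, `min_site_n`, `q`, `include_mixed`,
#'   `seed`. Every preprocessing parameter defaults to the standard analysis
#'   value (0.001-0.1 Hz band, 0.2 scrub threshold, q = 0.05).
#' @return a normalised config list.
#' @export
read_study_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  base <- default_config()
  for (nm in names(config)) {
    if (nm %in% c("cohort", "preprocess") && is.list(config[[nm]])) {
      base[[nm]] <- utils::modifyList(base[[nm]] %||% list(), config[[nm]])
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  if (!is.null(base$cohort$lateralization_effects) &&
      !is.data.frame(base$cohort$lateralization_effects)) {
    base$cohort$lateralization_effects <-
      bind_rows(lapply(base$cohort$lateralization_effects, as_tibble))
  }
  base
}

#' Run the full lateralization study
#'
#' Simulates (or accepts) a cohort, preprocesses every run (confound
#' regression, detrend + bandpass, FD/DVARS scrubbing), extracts hub
#' connectivity unflipped and flipped, forms the lateralization table, and
#' applies the connection-level statistics under the configured inclusion
#' criteria. Deterministic given the config seed.
#'
#' @param config list or YAML path, see [read_study_config()]. The `seed`
#'   argument overrides the config seed when given.
#' @param runs optional pre-built list of [bold_run()]s (with a matching
#'   `phenotypes` tibble and `atlas`), bypassing simulation.
#' @param phenotypes,atlas required when `runs` is supplied.
#' @param seed optional integer overriding the config seed.
#' @return a `hemiflip_study` object; see [tidy.hemiflip_study()].
#' @export
run_study <- function(config = NULL, runs = NULL, phenotypes = NULL,
                      atlas = NULL, seed = NULL) {
  cfg <- read_study_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  pp <- cfg$preprocess

  if (is.null(runs)) {
    cohort_args <- cfg$cohort
    cohort_args$seed <- cfg$seed
    spec <- do.call(cohort_spec, cohort_args)
    if (is.null(atlas)) {
      atlas <- if (!is.null(cfg$hubs)) {
        make_symmetric_atlas(spec$grid_dims, spec$voxel_mm, spec$spacing_mm,
                             hub_table = read_hub_table(cfg$hubs))
      } else {
        default_cohort_atlas(spec)
      }
    }
    connections <- enumerate_connections(atlas,
                                         include_mixed = cfg$include_mixed)
    sim <- simulate_cohort(spec, atlas = atlas, callback = function(run, s) {
      pr <- preprocess_run(run, atlas, pp$low_hz, pp$high_hz,
                           pp$scrub_threshold, pp$fd_method)
      list(li = subject_lateralization(pr$run, atlas, connections),
           qc = pr$qc, hub_snr = pr$hub_snr)
    })
    phenotypes <- sim$phenotypes
    processed <- sim$processed
  } else {
    stopifnot(!is.null(phenotypes), !is.null(atlas))
    connections <- enumerate_connections(atlas,
                                         include_mixed = cfg$include_mixed)
    processed <- lapply(runs, function(run) {
      pr <- preprocess_run(run, atlas, pp$low_hz, pp$high_hz,
                           pp$scrub_threshold, pp$fd_method)
      list(li = subject_lateralization(pr$run, atlas, connections),
           qc = pr$qc, hub_snr = pr$hub_snr)
    })
  }

  li <- map_dfr(processed, "li")
  qc <- map_dfr(processed, "qc")
  hub_snr <- map_dfr(processed, "hub_snr")

  analyze_lateralization(li, phenotypes, qc,
                         criteria = cfg$criteria,
                         exclude_sites = cfg$exclude_sites,
                         min_site_n = cfg$min_site_n,
                         q = cfg$q, atlas = atlas,
                         connections = connections,
                         hub_snr = hub_snr, config = cfg)
}

#' Statistical analysis of a lateralization table
#'
#' The analysis half of [run_study()]: applies inclusion criteria, then the
#' one-sample pattern tests, the two-sample group comparison with BH-FDR,
#' the paired connection-group contrasts, and severity/age/handedness
#' correlations for the FDR-significant connections.
#'
#' @param li lateralization table (all subjects).
#' @param phenotypes phenotype tibble.
#' @param qc QC tibble with retention fractions.
#' @param criteria preset letter or [inclusion_criteria()].
#' @param exclude_sites site list for presets C/D.
#' @param min_site_n base per-site minimum.
#' @param q FDR level.
#' @param atlas,connections,hub_snr,config carried into the result object.
#' @return a `hemiflip_study` object.
#' @export
analyze_lateralization <- function(li, phenotypes, qc, criteria = "A",
                                   exclude_sites = NULL, min_site_n = 20,
                                   q = 0.05, atlas = NULL,
                                   connections = NULL, hub_snr = NULL,
                                   config = NULL) {
  if (is.character(criteria)) {
    criteria <- criteria_preset(criteria, exclude_sites = exclude_sites,
                                min_site_n = min_site_n)
  }
  included <- apply_inclusion(phenotypes, qc, criteria)
  groups <- select(included, "subject_id", "group")
  li_inc <- filter(li, .data$subject_id %in% included$subject_id)
  li_ipsi <- filter(li_inc, .data$laterality_class != "mixed")

  one_sample <- one_sample_lateralization(li_ipsi, groups, q = q)
  two_sample <- two_sample_group_test(li_ipsi, groups, q = q)
  triples <- connection_group_means(li_ipsi)
  contrasts <- paired_group_contrasts(triples, groups)
  flagged <- two_sample$connection[!is.na(two_sample$fdr_significant) &
                                     two_sample$fdr_significant]
  correlations <- phenotype_correlations(li_inc, included, flagged)

  manifest <- list(
    package_version = as.character(packageVersion("hemiflip")),
    r_version = R.version.string,
    config_hash = if (!is.null(config)) rlang::hash(config) else NA,
    n_subjects_total = nrow(phenotypes),
    n_subjects_included = nrow(included),
    n_connections = if (!is.null(connections)) {
      sum(connections$laterality_class != "mixed")
    } else {
      length(unique(li_ipsi$connection))
    },
    q = q
  )

  structure(
    list(li = li, qc = qc, hub_snr = hub_snr, phenotypes = phenotypes,
         included = included, criteria = criteria,
         connections = connections,
         one_sample = one_sample, two_sample = two_sample,
         group_means = triples, contrasts = contrasts,
         correlations = correlations, q = q, atlas = atlas,
         config = config, manifest = manifest),
    class = "hemiflip_study"
  )
}

#' @export
print.hemiflip_study <- function(x, ...) {
  m <- x$manifest
  n_sig <- sum(x$two_sample$fdr_significant, na.rm = TRUE)
  cat("<hemiflip_study>\n")
  cat("  subjects: ", m$n_subjects_included, " included of ",
      m$n_subjects_total, "\n", sep = "")
  cat("  connections tested: ", m$n_connections,
      "; FDR-significant group differences (q < ", x$q, "): ", n_sig,
      "\n", sep = "")
  if (n_sig > 0) {
    sig <- filter(x$two_sample, .data$fdr_significant)
    cat("  ", paste(sprintf("%s (t = %.2f, P = %.2g)", sig$connection,
                            sig$t, sig$p), collapse = "\n  "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Human-readable study report
#'
#' Tabular analogue of the group-pattern grids: per-connection group
#' lateralization patterns with one-sample significance, the group
#' difference table with FDR flags, and (optionally) a comparison of
#' inclusion-criteria presets.
#'
#' @param study a `hemiflip_study`.
#' @param presets optional character vector of preset letters to compare
#'   (reruns the analysis per preset on the stored tables).
#' @return a `hemiflip_report`: list of tibbles `patterns`, `differences`,
#'   `criteria_comparison`.
#' @export
study_report <- function(study, presets = NULL) {
  patterns <- study$one_sample |>
    mutate(marker = case_when(
      is.na(.data$fdr_significant) ~ "",
      .data$fdr_significant ~ "*",
      TRUE ~ ""
    )) |>
    select("group_dx", "connection", "laterality_class", "group",
           "mean_li" = "estimate", "t", "p", "fdr_significant", "marker")
  differences <- study$two_sample |>
    mutate(marker = ifelse(!is.na(.data$fdr_significant) &
                             .data$fdr_significant, "*", "")) |>
    select("connection", "laterality_class", "group", "estimate", "t",
           "df", "p", "fdr_significant", "marker", "direction")
  comparison <- NULL
  if (!is.null(presets)) {
    comparison <- compare_criteria(study$li, study$phenotypes, study$qc,
                                   presets = presets,
                                   exclude_sites =
                                     study$config$exclude_sites %||% NULL,
                                   min_site_n =
                                     study$criteria$min_site_n %||% 20,
                                   q = study$q)
  }
  structure(list(patterns = patterns, differences = differences,
                 criteria_comparison = comparison),
            class = "hemiflip_report")
}

#' @export
print.hemiflip_report <- function(x, ...) {
  cat("Group differences (", nrow(x$differences), " connections):\n",
      sep = "")
  print(x$differences, n = 20)
  if (!is.null(x$criteria_comparison)) {
    cat("\nInclusion-criteria comparison:\n")
    print(x$criteria_comparison)
  }
  invisible(x)
}

#' Compare inclusion-criteria presets
#'
#' Reruns the two-sample group comparison under each preset and summarises
#' included-subject counts and FDR-significant connections.
#'
#' @param li lateralization table.
#' @param phenotypes phenotype tibble.
#' @param qc QC tibble.
#' @param presets preset letters, default A-H.
#' @param exclude_sites,min_site_n,q as in [analyze_lateralization()].
#' @return tibble, one row per preset.
#' @export
compare_criteria <- function(li, phenotypes, qc, presets = LETTERS[1:8],
                             exclude_sites = NULL, min_site_n = 20,
                             q = 0.05) {
  map_dfr(presets, function(p) {
    res <- tryCatch({
      st <- analyze_lateralization(li, phenotypes, qc, criteria = p,
                                   exclude_sites = exclude_sites,
                                   min_site_n = min_site_n, q = q)
      sig <- filter(st$two_sample, !is.na(.data$fdr_significant) &
                      .data$fdr_significant)
      tibble(preset = p,
             n_included = nrow(st$included),
             n_autism = sum(st$included$group == "autism"),
             n_significant = nrow(sig),
             significant = paste(sig$connection, collapse = "; "))
    }, error = function(e) {
      tibble(preset = p, n_included = 0L, n_autism = 0L,
             n_significant = NA_integer_,
             significant = paste("error:", conditionMessage(e)))
    })
    res
  })
}
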