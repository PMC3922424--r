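# broom-style accessors and ggplot2 displays for fitted study objects.

#' Tidy a fitted lateralization study
#'
#' @param x a `hemiflip_study`.
#' @param table which result table: `"two_sample"` (default; per-connection
#'   group differences), `"one_sample"` (per-group lateralization patterns),
#'   `"contrasts"` (paired connection-group contrasts), `"correlations"`
#'   (phenotype correlations), or `"qc"`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.hemiflip_study <- function(x, table = c("two_sample", "one_sample",
                                             "contrasts", "correlations",
                                             "qc"), ...) {
  table <- match.arg(table)
  out <- x[[switch(table, two_sample = "two_sample",
                   one_sample = "one_sample", contrasts = "contrasts",
                   correlations = "correlations", qc = "qc")]]
  as_tibble(out)
}

#' One-row study summary
#'
#' @param x a `hemiflip_study`.
#' @param ... unused.
#' @return a one-row tibble: subject counts, mean retention, connections
#'   tested, FDR-significant count, q level.
#' @export
glance.hemiflip_study <- function(x, ...) {
  tibble(
    n_subjects = x$manifest$n_subjects_total,
    n_included = x$manifest$n_subjects_included,
    n_control = sum(x$included$group == "control"),
    n_autism = sum(x$included$group == "autism"),
    mean_retention = mean(x$qc$retention_fraction),
    n_connections = x$manifest$n_connections,
    n_fdr_significant = sum(x$two_sample$fdr_significant, na.rm = TRUE),
    q = x$q
  )
}

#' Plot a fitted lateralization study
#'
#' `type = "differences"` draws the connection grid of group-difference t
#' statistics (asterisks mark FDR significance); `type = "patterns"` the
#' per-group mean lateralization grids; `type = "qc"` retention against mean
#' pre-scrub FD per subject.
#'
#' @param object a `hemiflip_study`.
#' @param type one of "differences", "patterns", "qc".
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hemiflip_study <- function(object, type = c("differences",
                                                     "patterns", "qc"),
                                    ...) {
  type <- match.arg(type)
  if (type == "qc") {
    df <- left_join(object$qc,
                    select(object$phenotypes, "subject_id", "group"),
                    by = "subject_id")
    return(
      ggplot(df, aes(x = .data$mean_fd_pre, y = .data$retention_fraction,
                     colour = .data$group)) +
        geom_point() +
        labs(x = "mean FD before scrubbing (mm)",
             y = "retention fraction", colour = NULL,
             title = "Motion scrubbing QC") +
        theme_minimal()
    )
  }
  if (type == "patterns") {
    df <- object$one_sample |>
      mutate(star = ifelse(!is.na(.data$fdr_significant) &
                             .data$fdr_significant, "*", ""))
    return(
      ggplot(df, aes(x = .data$hub_a, y = .data$hub_b,
                     fill = .data$estimate)) +
        geom_tile() +
        geom_text(aes(label = .data$star), size = 3) +
        facet_wrap(~group_dx) +
        scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
        labs(x = NULL, y = NULL, fill = "mean LI",
             title = "Group lateralization patterns") +
        theme_minimal()
    )
  }
  df <- object$two_sample |>
    mutate(star = ifelse(!is.na(.data$fdr_significant) &
                           .data$fdr_significant, "*", ""))
  ggplot(df, aes(x = .data$hub_a, y = .data$hub_b, fill = .data$t)) +
    geom_tile() +
    geom_text(aes(label = .data$star), size = 3) +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = NULL, y = NULL, fill = "t (control - autism)",
         title = "Group differences in lateralization") +
    theme_minimal()
}
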