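# Connection-level statistics: per-hub one-sample lateralization patterns,
# two-sample group comparisons with BH-FDR over the ipsilateral connection
# family, paired contrasts between the three connection groups, and
# phenotype (severity / age / handedness) correlations. Reported P values
# are uncorrected and two-sided; FDR significance is a separate flag.

#' Benjamini-Hochberg rejection flags
#'
#' Step-up FDR control at level `q`. Missing p-values are excluded from the
#' family and returned as `NA` flags.
#'
#' @param pvalues numeric vector in \[0, 1\] (NA allowed).
#' @param q FDR level, default 0.05.
#' @return logical vector of the same length.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) return(logical(0))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH") <= q
  out
}

.safe_one_t <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) {
    return(tibble(n = n, estimate = if (n > 0) mean(x) else NA_real_,
                  t = NA_real_, df = NA_real_, p = NA_real_,
                  note = "untested: fewer than 3 subjects"))
  }
  if (sd(x) == 0) {
    return(tibble(n = n, estimate = mean(x), t = NA_real_, df = NA_real_,
                  p = NA_real_, note = "degenerate: zero variance"))
  }
  ht <- t.test(x)
  tibble(n = n, estimate = unname(ht$estimate), t = unname(ht$statistic),
         df = unname(ht$parameter), p = ht$p.value, note = NA_character_)
}

#' Per-connection one-sample lateralization tests
#'
#' For each diagnostic group separately, a two-sided one-sample t-test of li
#' against zero per connection, with BH-FDR within the group's connection
#' family.
#'
#' @param li_table lateralization table ([subject_lateralization()] rows).
#' @param groups tibble with `subject_id` and `group`.
#' @param q FDR level.
#' @return tibble, one row per group x connection.
#' @export
one_sample_lateralization <- function(li_table, groups, q = 0.05) {
  df <- li_table |>
    left_join(select(groups, "subject_id", "group_dx" = "group"),
              by = "subject_id") |>
    filter(!is.na(.data$group_dx))
  out <- df |>
    group_by(.data$group_dx, .data$connection, .data$hub_a, .data$hub_b,
             .data$laterality_class, .data$group) |>
    summarise(res = list(.safe_one_t(.data$li)), .groups = "drop") |>
    tidyr::unnest("res")
  out |>
    group_by(.data$group_dx) |>
    mutate(fdr_significant = fdr_bh(.data$p, q)) |>
    ungroup()
}

.safe_two_t <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    return(tibble(n_control = n1, n_autism = n2, estimate = NA_real_,
                  t = NA_real_, df = NA_real_, p = NA_real_,
                  note = "untested: a group has fewer than 2 subjects"))
  }
  if (sd(c(x - mean(x), y - mean(y))) == 0) {
    return(tibble(n_control = n1, n_autism = n2,
                  estimate = mean(x) - mean(y), t = NA_real_, df = NA_real_,
                  p = NA_real_, note = "degenerate: zero variance"))
  }
  ht <- t.test(x, y, var.equal = var_equal)
  tibble(n_control = n1, n_autism = n2, estimate = mean(x) - mean(y),
         t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, note = NA_character_)
}

#' Per-connection two-sample group comparison
#'
#' Two-sided t-tests of control minus autism li per connection (pooled
#' variance by default, so df = n1 + n2 - 2 minus per-connection missing
#' subjects), with BH-FDR jointly over the whole tested ipsilateral family.
#' A positive t on a left-lateralized connection means reduced left
#' lateralization in the autism group.
#'
#' @param li_table lateralization table.
#' @param groups tibble with `subject_id` and `group` ("control"/"autism").
#' @param q FDR level.
#' @param var_equal pooled-variance t (default); `FALSE` for Welch.
#' @return tibble, one row per connection, with `fdr_significant`.
#' @export
two_sample_group_test <- function(li_table, groups, q = 0.05,
                                  var_equal = TRUE) {
  df <- li_table |>
    left_join(select(groups, "subject_id", "group_dx" = "group"),
              by = "subject_id") |>
    filter(.data$group_dx %in% c("control", "autism"))
  if (length(unique(df$group_dx)) < 2) {
    stop("both a control and an autism group are required")
  }
  out <- df |>
    group_by(.data$connection, .data$hub_a, .data$hub_b,
             .data$laterality_class, .data$group) |>
    summarise(res = list(.safe_two_t(
      .data$li[.data$group_dx == "control"],
      .data$li[.data$group_dx == "autism"],
      var_equal = var_equal
    )), .groups = "drop") |>
    tidyr::unnest("res")
  out$fdr_significant <- fdr_bh(out$p, q)
  out$direction <- case_when(
    is.na(out$estimate) | out$estimate == 0 ~ NA_character_,
    out$estimate > 0 ~ "reduced in autism",
    TRUE ~ "increased in autism"
  )
  out
}

#' Paired contrasts between the three connection groups
#'
#' Within each diagnostic group, paired two-sided t-tests on a common
#' "degree of lateralization" scale: left-language vs left-nonlanguage,
#' left-language vs -right, and left-nonlanguage vs -right (the right-network
#' mean is negated so that a more right-lateralized network scores higher on
#' its own hemisphere's scale).
#'
#' @param triples output of [connection_group_means()].
#' @param groups tibble with `subject_id` and `group`.
#' @return tibble, one row per group x contrast.
#' @export
paired_group_contrasts <- function(triples, groups) {
  df <- triples |>
    left_join(select(groups, "subject_id", "group_dx" = "group"),
              by = "subject_id") |>
    filter(!is.na(.data$group_dx))
  contrasts <- list(
    c("left_language", "left_nonlanguage"),
    c("left_language", "neg_right"),
    c("left_nonlanguage", "neg_right")
  )
  df$neg_right <- -df$right
  map_dfr(split(df, df$group_dx), function(g) {
    map_dfr(contrasts, function(ct) {
      a <- g[[ct[1]]]; b <- g[[ct[2]]]
      keep <- !is.na(a) & !is.na(b)
      a <- a[keep]; b <- b[keep]
      n <- length(a)
      if (n < 3) {
        return(tibble(group_dx = g$group_dx[1],
                      contrast = paste(ct, collapse = " vs "),
                      n = n, mean_diff = NA_real_, t = NA_real_,
                      df = NA_real_, p = NA_real_,
                      note = "untested: fewer than 3 subjects"))
      }
      if (sd(a - b) == 0) {
        return(tibble(group_dx = g$group_dx[1],
                      contrast = paste(ct, collapse = " vs "),
                      n = n, mean_diff = mean(a - b), t = NA_real_,
                      df = NA_real_, p = NA_real_,
                      note = "degenerate: zero variance"))
      }
      ht <- t.test(a, b, paired = TRUE)
      tibble(group_dx = g$group_dx[1],
             contrast = paste(ct, collapse = " vs "),
             n = n, mean_diff = mean(a - b), t = unname(ht$statistic),
             df = unname(ht$parameter), p = ht$p.value,
             note = NA_character_)
    })
  })
}

#' Severity score
#'
#' Autism symptom severity as the sum of the ADOS social and communication
#' domain totals.
#' @param ados_social,ados_communication numeric vectors.
#' @export
severity <- function(ados_social, ados_communication) {
  ados_social + ados_communication
}

.safe_cor <- function(x, y, method) {
  keep <- !is.na(x) & !is.na(y)
  n <- sum(keep)
  if (n < 3) {
    return(tibble(estimate = NA_real_, p = NA_real_, n = n,
                  note = "untested: fewer than 3 complete pairs"))
  }
  if (sd(x[keep]) == 0 || sd(y[keep]) == 0) {
    return(tibble(estimate = NA_real_, p = NA_real_, n = n,
                  note = "degenerate: zero variance"))
  }
  ht <- suppressWarnings(cor.test(x[keep], y[keep], method = method,
                                  exact = FALSE))
  tibble(estimate = unname(ht$estimate), p = ht$p.value, n = n,
         note = NA_character_)
}

#' Phenotype correlations for connections of interest
#'
#' For each named connection (typically those flagged by
#' [two_sample_group_test()]): Pearson correlation of li with severity (ADOS
#' social + communication) in the autism group, and optionally over autism
#' plus the controls with ADOS scores; Spearman correlations of li with age
#' and with quantitative handedness, per group (rank-based because their
#' residuals are not normal).
#'
#' @param li_table lateralization table.
#' @param phenotypes phenotype tibble.
#' @param connections_of_interest character vector of canonical connection
#'   names.
#' @param include_controls also report severity correlations with controls
#'   (that have ADOS) pooled in.
#' @return tibble, one row per connection x variable x group x method.
#' @export
phenotype_correlations <- function(li_table, phenotypes,
                                   connections_of_interest,
                                   include_controls = TRUE) {
  if (length(connections_of_interest) == 0) {
    return(tibble(connection = character(), variable = character(),
                  group_dx = character(), method = character(),
                  estimate = numeric(), p = numeric(), n = integer(),
                  note = character()))
  }
  phen <- phenotypes |>
    mutate(severity = severity(.data$ados_social,
                               .data$ados_communication)) |>
    select("subject_id", subject_group = "group", "age",
           "handedness_quant", "severity")
  df <- li_table |>
    filter(.data$connection %in% connections_of_interest) |>
    left_join(phen, by = "subject_id")

  per_conn <- function(cn) {
    g <- filter(df, .data$connection == cn)
    aut <- filter(g, .data$subject_group == "autism")
    rows <- list(
      mutate(.safe_cor(aut$li, aut$severity, "pearson"),
             variable = "severity", group_dx = "autism",
             method = "pearson")
    )
    if (include_controls) {
      rows <- c(rows, list(
        mutate(.safe_cor(g$li, g$severity, "pearson"),
               variable = "severity", group_dx = "autism+control",
               method = "pearson")
      ))
    }
    for (grp in c("control", "autism")) {
      gg <- filter(g, .data$subject_group == grp)
      rows <- c(rows, list(
        mutate(.safe_cor(gg$li, gg$age, "spearman"),
               variable = "age", group_dx = grp, method = "spearman"),
        mutate(.safe_cor(gg$li, gg$handedness_quant, "spearman"),
               variable = "handedness", group_dx = grp,
               method = "spearman")
      ))
    }
    mutate(bind_rows(rows), connection = cn)
  }
  map_dfr(connections_of_interest, per_conn) |>
    select("connection", "variable", "group_dx", "method",
           "estimate", "p", "n", "note")
}
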