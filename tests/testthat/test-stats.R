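test_that("BH flags match the hand step-up on stated examples", {
  expect_identical(fdr_bh(0.001), TRUE)
  expect_identical(fdr_bh(c(0.04, 0.04, 0.04)), rep(TRUE, 3))
  expect_identical(fdr_bh(rep(1, 4)), rep(FALSE, 4))
  expect_identical(fdr_bh(numeric(0)), logical(0))
  expect_identical(fdr_bh(c(0.01, NA, 0.9)), c(TRUE, NA, FALSE))
  expect_error(fdr_bh(c(0.2, 1.4)), "0, 1")
})

test_that("BH agrees with an exhaustive step-up recomputation", {
  grid <- seq(0, 1, by = 0.05)
  for (p1 in grid) {
    expect_identical(fdr_bh(p1), bh_oracle(p1))
    for (p2 in grid) {
      expect_identical(fdr_bh(c(p1, p2)), bh_oracle(c(p1, p2)))
    }
  }
  set.seed(59)
  fine <- seq(0, 1, by = 0.01)
  for (i in 1:400) {
    p <- sample(fine, sample(3:6, 1), replace = TRUE)
    expect_identical(fdr_bh(p), bh_oracle(p))
  }
})

make_phenotypes <- function() {
  tibble::tibble(
    subject_id = sprintf("p%02d", 1:12),
    site_id = rep(c("siteA", "siteB"), each = 6),
    diagnosis = c(rep("control", 6),
                  "autism", "autism", "asperger", "pdd_nos", "autism",
                  "autism"),
    group = rep(c("control", "autism"), each = 6),
    age = rep(20, 12),
    sex = c("M", "M", "F", "M", "F", "M", "M", "M", "M", "F", "M", "M"),
    handedness_cat = c("R", "L", NA, "R", "R", NA, "R", "R", "L", "R", NA,
                       "R"),
    handedness_quant = c(80, -60, 30, NA, 50, NA, 70, 90, -80, 20, -10,
                         60),
    verbal_iq = c(110, 65, 125, 100, 119, 121, 79, 85, 120, 131, 100, 130),
    performance_iq = rep(100, 12),
    ados_social = c(rep(NA, 6), 7, 5, 9, 4, 6, 8),
    ados_communication = c(rep(NA, 6), 5, 3, 4, 2, 5, 6)
  )
}

make_qc <- function() {
  tibble::tibble(subject_id = sprintf("p%02d", 1:12),
                 retention_fraction = c(0.9, 0.49, 0.8, 1, 0.7, 0.5,
                                        0.95, 0.4, 0.6, 0.85, 0.75, 0.55))
}

test_that("inclusion presets reproduce hand-computed subsets", {
  ph <- make_phenotypes(); qc <- make_qc()
  base <- apply_inclusion(ph, qc, criteria_preset("A", min_site_n = 1))
  expect_equal(nrow(base), 12)

  # B: retention >= 0.5 drops p02 (0.49) and p08 (0.40)
  b <- apply_inclusion(ph, qc, criteria_preset("B", min_site_n = 1))
  expect_setequal(b$subject_id, setdiff(ph$subject_id, c("p02", "p08")))

  # E: right-handed only; p03 recodes +30 -> R, p11 recodes -10 -> L;
  # p06 has no measure and is dropped; left-handers p02, p09 dropped
  e <- apply_inclusion(ph, qc, criteria_preset("E", min_site_n = 1))
  expect_setequal(e$subject_id,
                  c("p01", "p03", "p04", "p05", "p07", "p08", "p10", "p12"))

  # F: males only
  f <- apply_inclusion(ph, qc, criteria_preset("F", min_site_n = 1))
  expect_setequal(f$subject_id,
                  ph$subject_id[ph$sex == "M"])

  # G: strict autism diagnosis drops the asperger and pdd_nos subjects
  g <- apply_inclusion(ph, qc, criteria_preset("G", min_site_n = 1))
  expect_setequal(g$subject_id, setdiff(ph$subject_id, c("p09", "p10")))

  # H: verbal IQ windows: autism 80-130 drops p07 (79) and p10 (131);
  # control 70-120 drops p02 (65), p03 (125), p12 (130 is autism: kept)
  h <- apply_inclusion(ph, qc, criteria_preset("H", min_site_n = 1))
  expect_setequal(h$subject_id,
                  setdiff(ph$subject_id, c("p02", "p03", "p06", "p07",
                                           "p10")))
  expect_false("p07" %in% h$subject_id)   # autism with verbal IQ 79

  # C/D: overlap-site exclusion
  cc <- apply_inclusion(ph, qc, criteria_preset("C", exclude_sites = "siteA",
                                                min_site_n = 1))
  expect_setequal(cc$subject_id, ph$subject_id[ph$site_id == "siteB"])
  d <- apply_inclusion(ph, qc, criteria_preset("D", exclude_sites = "siteA",
                                               min_site_n = 1))
  expect_setequal(d$subject_id, setdiff(cc$subject_id, c("p08")))

  # base site minimum: siteA has 6 subjects, so min_site_n = 6 keeps all,
  # min_site_n = 7 empties the sample and errors
  s6 <- apply_inclusion(ph, qc, inclusion_criteria(min_site_n = 6))
  expect_equal(nrow(s6), 12)
  expect_error(apply_inclusion(ph, qc, inclusion_criteria(min_site_n = 7)),
               "min_site_n")
})

test_that("added restrictions never increase the included count", {
  ph <- make_phenotypes(); qc <- make_qc()
  n_of <- function(p) nrow(apply_inclusion(
    ph, qc, criteria_preset(p, exclude_sites = "siteA", min_site_n = 1)))
  nA <- n_of("A")
  for (p in c("B", "C", "E", "F", "G", "H")) expect_lte(n_of(p), nA)
  expect_lte(n_of("D"), n_of("B"))
  expect_lte(n_of("D"), n_of("C"))
})

test_that("one-sample lateralization tests behave at the edges", {
  atlas <- small_atlas()
  conns <- enumerate_connections(atlas)
  set.seed(61)
  sim <- li_table_sim(conns, n_control = 10, n_autism = 0)
  sim$li$li <- 0.5                        # zero variance
  res <- one_sample_lateralization(sim$li, sim$groups)
  expect_true(all(res$note == "degenerate: zero variance"))
  expect_true(all(is.na(res$t)))

  set.seed(62)
  sim2 <- li_table_sim(conns, n_control = 50, n_autism = 0, li_sd = 0.1,
                       effects = tibble::tibble(connection = "L1 ~ L2",
                                                group = "control",
                                                shift = 0.3))
  res2 <- one_sample_lateralization(sim2$li, sim2$groups)
  planted <- res2[res2$connection == "L1 ~ L2", ]
  expect_lt(planted$p, 1e-6)              # power ~ 1 at ncp = 21
  expect_true(planted$fdr_significant)
  expect_equal(planted$df, 49)
})

test_that("two-sample group tests detect planted group differences", {
  atlas <- atlas20()
  conns <- enumerate_connections(atlas)
  set.seed(63)
  sim <- li_table_sim(conns, n_control = 100, n_autism = 100, li_sd = 0.2,
                      effects = tibble::tibble(connection = "PC ~ We",
                                               group = "autism",
                                               shift = -0.3))
  res <- two_sample_group_test(sim$li, sim$groups)
  expect_equal(nrow(res), 91)
  planted <- res[res$connection == "PC ~ We", ]
  expect_true(planted$fdr_significant)
  expect_equal(planted$df, 198)
  expect_equal(planted$direction, "reduced in autism")
  expect_gt(planted$estimate, 0.2)

  # identical groups give t = 0 everywhere
  sim0 <- li_table_sim(conns, n_control = 5, n_autism = 5)
  sim0$li <- dplyr::mutate(
    sim0$li,
    li = rep(rnorm(91), times = 10)  # same per-connection value per subject
  )
  res0 <- two_sample_group_test(sim0$li, sim0$groups)
  expect_true(all(is.na(res0$t)))          # zero variance is degenerate
  sim1 <- li_table_sim(conns, n_control = 5, n_autism = 5, li_sd = 0.2)
  half <- sim1$li[sim1$li$subject_id %in% sprintf("s%03d", 1:5), ]
  mirrored <- half
  mirrored$subject_id <- sprintf("s%03d", 6:10)[
    match(mirrored$subject_id, sprintf("s%03d", 1:5))]
  res1 <- two_sample_group_test(dplyr::bind_rows(half, mirrored),
                                sim1$groups)
  expect_true(all(abs(res1$t) < 1e-12))
  expect_error(two_sample_group_test(half, sim1$groups[1:5, ]), "group")
})

test_that("null two-sample rejections stay at the nominal level", {
  atlas <- small_atlas()
  conns <- enumerate_connections(atlas)
  set.seed(64)
  n_rej <- 0; n_tot <- 0; n_fdr <- 0
  for (i in 1:100) {
    sim <- li_table_sim(conns, n_control = 30, n_autism = 30)
    res <- two_sample_group_test(sim$li, sim$groups)
    n_rej <- n_rej + sum(res$p <= 0.05)
    n_fdr <- n_fdr + sum(res$fdr_significant)
    n_tot <- n_tot + nrow(res)
  }
  ci <- qbinom(c(0.005, 0.995), n_tot, 0.05) / n_tot
  expect_gte(n_rej / n_tot, ci[1])
  expect_lte(n_rej / n_tot, ci[2])
  expect_lte(n_fdr / n_tot, 0.05)         # BH false discoveries are rare
})

test_that("paired contrasts compare the three connection groups", {
  set.seed(65)
  n <- 400
  triples <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:n),
    left_language = rnorm(n, 0.1, 0.2) + 0.1,   # shifted by +0.1
    left_nonlanguage = rnorm(n, 0.1, 0.2),
    right = -rnorm(n, 0.1, 0.2)                  # right-lateralized
  )
  groups <- tibble::tibble(subject_id = triples$subject_id,
                           group = "control")
  res <- paired_group_contrasts(triples, groups)
  ll_ln <- res[res$contrast == "left_language vs left_nonlanguage", ]
  expect_lt(ll_ln$p, 0.001)
  expect_gt(ll_ln$mean_diff, 0)

  # swapping the columns flips the contrast sign
  swapped <- dplyr::rename(triples, left_language = "left_nonlanguage",
                           left_nonlanguage = "left_language")
  res_sw <- paired_group_contrasts(swapped, groups)
  expect_equal(res_sw$t[res_sw$contrast ==
                          "left_language vs left_nonlanguage"],
               -ll_ln$t)

  # identical columns give t = 0 (degenerate, zero variance)
  same <- tibble::tibble(subject_id = triples$subject_id,
                         left_language = triples$left_language,
                         left_nonlanguage = triples$left_language,
                         right = triples$right)
  res_same <- paired_group_contrasts(same, groups)
  expect_true(is.na(res_same$t[res_same$contrast ==
                                 "left_language vs left_nonlanguage"]))
})

test_that("phenotype correlations recover a planted severity effect", {
  expect_equal(severity(7, 5), 12)
  atlas <- small_atlas()
  conns <- enumerate_connections(atlas)
  set.seed(66)
  n <- 120
  ph <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:(2 * n)),
    group = rep(c("control", "autism"), each = n),
    age = runif(2 * n, 8, 40),
    handedness_quant = runif(2 * n, -100, 100),
    ados_social = c(rep(NA, n), round(runif(n, 1, 14))),
    ados_communication = c(rep(NA, n), round(runif(n, 1, 8)))
  )
  sev <- severity(ph$ados_social, ph$ados_communication)
  li <- conns[rep(1:nrow(conns), times = 2 * n), ]
  li$subject_id <- rep(ph$subject_id, each = nrow(conns))
  li$li <- rnorm(nrow(li), sd = 0.25)
  sev0 <- ifelse(is.na(sev), 0, sev)
  sel <- li$connection == "L1 ~ L2"
  li$li[sel] <- li$li[sel] -
    0.05 * sev0[match(li$subject_id[sel], ph$subject_id)]
  res <- phenotype_correlations(li, ph, "L1 ~ L2")
  sev_aut <- res[res$variable == "severity" & res$group_dx == "autism", ]
  expect_lt(sev_aut$estimate, -0.5)
  expect_lt(sev_aut$p, 0.001)
  expect_equal(sev_aut$n, n)
  age_rows <- res[res$variable == "age", ]
  expect_true(all(abs(age_rows$estimate) < 0.3))
  expect_identical(res[res$variable == "handedness", ]$method[1],
                   "spearman")
  # no connections of interest: empty but well-formed
  empty <- phenotype_correlations(li, ph, character(0))
  expect_equal(nrow(empty), 0)
})
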