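table1_cohort <- function() {
  counts <- c("t(4;11)" = 1, "t(6;11)" = 2, "t(9;11)" = 16, "t(10;11)" = 6,
              "t(11;19)" = 5, "other t(11q23)" = 3, "t(15;17)" = 14,
              "inv(16)" = 13, "t(8;21)" = 24, "normal karyotype" = 4,
              "other" = 14)
  tibble::tibble(sample_id = sprintf("S%03d", seq_len(sum(counts))),
                 subtype = rep(names(counts), counts))
}

test_that("cohort percentages are reported to two decimals", {
  out <- cohort_summary(table1_cohort())$categorical
  pct <- function(level) out$percent[out$level == level]
  expect_equal(pct("t(8;21)"), 23.53)
  expect_equal(pct("t(9;11)"), 15.69)
  expect_equal(pct("t(15;17)"), 13.73)
  expect_equal(pct("inv(16)"), 12.75)
  expect_equal(sum(out$n), 102)

  single <- cohort_summary(tibble::tibble(sample_id = "S1", subtype = "t(8;21)"))
  expect_equal(single$categorical$percent, 100)
  expect_error(cohort_summary(table1_cohort()[0, ]), "empty")
})

test_that("numeric characteristics are summarized by median and range,
           stratified by tissue", {
  samples <- tibble::tibble(
    sample_id = paste0("S", 1:4), subtype = "A",
    tissue = c("bone_marrow", "bone_marrow", "peripheral_blood",
               "peripheral_blood"),
    blast_percent = c(60, 80, 85, 95), age = c(2, 4, 6, 8)
  )
  num <- cohort_summary(samples)$numeric
  bm <- num[num$characteristic == "blast_percent" & num$stratum == "bone_marrow", ]
  expect_equal(bm$median, 70)
  expect_equal(c(bm$min, bm$max), c(60, 80))
})

test_that("the detection filter keeps miRNAs seen in at least min_samples and
           pools the rest", {
  ab <- tidyr::expand_grid(sample_id = paste0("S", 1:5),
                           mirna = c("m1", "m2", "m3")) |>
    dplyr::mutate(
      detected = dplyr::case_when(
        mirna == "m1" ~ sample_id %in% c("S1", "S2", "S3"),  # exactly 3
        mirna == "m2" ~ sample_id %in% c("S1", "S2"),        # only 2
        TRUE ~ TRUE
      ),
      value = dplyr::if_else(detected, 2, NA_real_)
    )
  out <- detection_filter(ab, min_samples = 3)
  expect_setequal(out$retained, c("m1", "m3"))
  expect_true("all_others" %in% out$abundance$mirna)
  rest <- dplyr::filter(out$abundance, mirna == "all_others", sample_id == "S1")
  expect_equal(rest$value, 2)
  # min_samples = 1 retains everything detected anywhere
  expect_setequal(detection_filter(ab, min_samples = 1)$retained,
                  c("m1", "m2", "m3"))
})

test_that("the Mann-Whitney p matches exact enumeration and its conventions", {
  expect_equal(mwu_test(c(1, 2), c(3, 4)), 2 / 6, tolerance = 1e-12)
  expect_equal(mwu_test(c(5, 1, 3), c(5, 1, 3)), 1)   # identical multisets
  expect_error(mwu_test(numeric(0), 1:3), "non-empty")
  # symmetric and invariant under strictly monotone transforms
  set.seed(3)
  for (i in 1:10) {
    x <- runif(sample(2:6, 1))
    y <- runif(sample(2:6, 1))
    expect_equal(mwu_test(x, y), mwu_test(y, x))
    expect_equal(mwu_test(x, y), mwu_test(exp(3 * x), exp(3 * y)))
    expect_equal(mwu_test(x, y), oracle_mwu_exact(x, y), tolerance = 1e-12)
  }
})

test_that("fold changes are ratios of medians with reciprocal symmetry", {
  expect_equal(group_fold_change(c(19.69, 19.69, 19.69), c(1, 1, 1))$fc, 19.69)
  expect_equal(group_fold_change(1:5, 1:5)$fc, 1)
  set.seed(4)
  a <- rlnorm(7)
  b <- rlnorm(5)
  expect_equal(group_fold_change(a, b)$fc * group_fold_change(b, a)$fc, 1)
  zero <- group_fold_change(c(1, 2), c(0, 0), floor = 0.01)
  expect_true(zero$flagged)
  expect_equal(zero$fc, 150)
  expect_equal(group_fold_change(c(2, 4), c(1, 9), estimator = "mean")$fc, 0.6)
})

test_that("the subtype report applies the 1.8-fold arrow and star rules", {
  # two miRNAs: m1 changes 2.2-fold in A (arrowed), m2 only 1.5-fold
  set.seed(5)
  samples <- tibble::tibble(sample_id = paste0("S", 1:12),
                            subtype = rep(c("A", "B"), each = 6))
  ab <- tidyr::expand_grid(sample_id = samples$sample_id,
                           mirna = c("m1", "m2")) |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::mutate(
      value = dplyr::case_when(
        mirna == "m1" & subtype == "A" ~ 2.2 + runif(dplyr::n(), 0, 1e-4),
        mirna == "m2" & subtype == "A" ~ 1.5 + runif(dplyr::n(), 0, 1e-4),
        TRUE ~ 1 + runif(dplyr::n(), 0, 1e-4)
      ),
      detected = TRUE
    ) |>
    dplyr::select(-subtype)
  rep <- subtype_report(ab, samples, list(AvB = list(a = "A", b = "B")))
  expect_equal(unique(rep$mirna), "m1")   # m2 has no arrow anywhere
  expect_equal(rep$arrow, "up")
  expect_equal(rep$stars, "**")           # exact MWU p = 2/choose(12,6) ~ 0.0022
  # downregulation arrows and the unrestricted report
  rep_all <- subtype_report(ab, samples, list(BvA = list(a = "B", b = "A")),
                            restrict = FALSE)
  expect_equal(rep_all$arrow[rep_all$mirna == "m1"], "down")
  expect_equal(nrow(rep_all), 2)
  expect_error(
    subtype_report(ab, samples, list(bad = list(a = "C", b = "rest"))),
    "unknown subtype"
  )
})

test_that("a planted signature is reported while unplanted miRNAs stay out", {
  cfg <- sim_config(
    n_mirnas = 60, n_samples_per_group = c(A = 20, B = 20),
    planted_fc = tibble::tibble(mirna = sprintf("miR-%03d", 1:5),
                                subtype = "A", fc = 3),
    noise_cv = 0.2, frac_absent = 0, seed = 21
  )
  coh <- simulate_cohort(cfg)
  ab <- quantify_cohort(coh$spots, quant_config(), calibration_expected(cfg),
                        absolute = FALSE)
  rep <- subtype_report(ab, coh$samples, list(AvB = list(a = "A", b = "B")))
  planted <- sprintf("miR-%03d", 1:5)
  expect_true(all(planted %in% rep$mirna[rep$arrow == "up"]))
  false_rate <- mean(setdiff(sprintf("miR-%03d", 1:60), planted) %in% rep$mirna)
  expect_lte(false_rate, 0.05)
})

test_that("null cohorts star at about the nominal rate", {
  set.seed(31)
  n_mir <- 400
  samples <- tibble::tibble(sample_id = paste0("S", 1:24),
                            subtype = rep(c("A", "B"), each = 12))
  ab <- tidyr::expand_grid(sample_id = samples$sample_id,
                           mirna = paste0("m", seq_len(n_mir))) |>
    dplyr::mutate(value = rlnorm(dplyr::n()), detected = TRUE)
  rep <- subtype_report(ab, samples, list(AvB = list(a = "A", b = "B")),
                        restrict = FALSE)
  star_rate <- mean(rep$stars != "")
  # binomial 99.9% band around alpha = 0.05 at 400 tests
  expect_lt(abs(star_rate - 0.05), 3.3 * sqrt(0.05 * 0.95 / n_mir))
})

test_that("delta-CT arithmetic and the 2^-CT transform", {
  out <- delta_ct(c(20, 29.9), c(20, 25))
  expect_equal(out$delta_ct, c(0, 4.9))
  expect_equal(out$level[2], 2^(-29.9))
  expect_equal(out$level[2], 1.0e-9, tolerance = 0.03)
  # a delta-CT one cycle lower means twice the expression
  expect_equal(delta_ct(19, 20)$level / delta_ct(20, 20)$level, 2)
})
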