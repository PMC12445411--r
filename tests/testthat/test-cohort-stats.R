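# Cohort statistics: summaries, gated tests, correlations, the report.

test_that("summary statistics follow the stated conventions", {
  s <- summarize_metric(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$iqr, 2)       # Q3 - Q1 = 4 - 2 with linear interpolation
  expect_equal(s$mean, 3)

  cst <- summarize_metric(rep(7.5, 20))
  expect_equal(cst$sd, 0)
  expect_equal(cst$iqr, 0)
  expect_equal(cst$normal_range_low, 7.5)
  expect_equal(cst$normal_range_high, 7.5)
  expect_equal(cst$ci_low, 7.5)
  expect_equal(cst$ci_high, 7.5)
  expect_false(cst$normal)     # constant fails the normality gate

  expect_error(summarize_metric(1), "at least 2")
})

test_that("bootstrap CI of the median is seeded and deterministic", {
  x <- rnorm(80, 3, 1)
  s1 <- summarize_metric(x, boot_seed = 9)
  s2 <- summarize_metric(x, boot_seed = 9)
  expect_identical(s1, s2)
  expect_true(s1$ci_low <= s1$median && s1$median <= s1$ci_high)
  expect_true(s1$normal_range_low <= s1$median &&
                s1$median <= s1$normal_range_high)
})

test_that("group comparison gates on normality and detects the null", {
  set.seed(3)
  a <- rnorm(40, 5, 1)
  same <- compare_groups(a, a)
  expect_gte(same$p_value, 0.99)
  expect_equal(same$direction, 0)
  expect_true(same$normal)
  expect_match(same$test, "t-test")

  sk <- exp(rnorm(60))
  gate <- compare_groups(sk, sk * 1.01)
  expect_match(gate$test, "Mann-Whitney")

  # paired self-comparison against a noise-free shift
  sh <- compare_groups(a, a + 0.4, paired = TRUE)
  expect_lt(sh$p_value, 1e-6)
  expect_equal(sh$direction, -1)
  expect_error(compare_groups(a, a[-1], paired = TRUE), "equal length")
  expect_error(compare_groups(1:2, 1:5), "at least 3")
})

test_that("paper-like female/male rest-MBF separation is reliably detected", {
  # power frozen from a 1,000-replicate simulation of normal groups with
  # means 0.68/0.56, SDs 0.13/0.17 and n 54/84: Mann-Whitney is significant
  # at alpha = 0.001 in about 83% of replicates and essentially always at
  # alpha = 0.05
  set.seed(17)
  p <- replicate(200, {
    f <- rnorm(54, 0.68, 0.13)
    m <- rnorm(84, 0.56, 0.17)
    suppressWarnings(wilcox.test(f, m, exact = FALSE)$p.value)
  })
  expect_gte(mean(p < 0.001), 0.70)
  expect_gte(mean(p < 0.05), 0.95)
})

test_that("age correlation is gate-selected and behaves at the null", {
  ages <- seq(20, 79, length.out = 60)
  dec <- correlate_age(100 - ages + 0 * ages, ages, method = "spearman")
  expect_equal(dec$r, -1)
  expect_error(correlate_age(rep(1, 60), ages), "constant")
  expect_error(correlate_age(1:5, 1:5), "at least 10")

  set.seed(23)
  rs <- replicate(1000, {
    cor(rnorm(138), runif(138, 19, 79), method = "spearman")
  })
  expect_lt(abs(mean(rs)), 0.01)
  expect_lt(mean(abs(rs) > 0.35), 0.01)
})

test_that("simulated cohorts show the stress-only age decline", {
  ok <- replicate(20, {
    co <- make_cohort(cohort_spec(), seed = sample.int(2^30, 1))
    s <- correlate_age(co$smbf_endo_global, co$age)
    r <- correlate_age(co$rmbf_endo_global, co$age)
    (s$r < 0 && s$p_value < 0.05) && r$p_value >= 0.05
  })
  expect_gte(mean(ok), 0.80)
})

test_that("condition comparison selects Friedman for non-normal data", {
  set.seed(4)
  m <- cbind(basal = exp(rnorm(40)), mid = exp(rnorm(40)) * 0.25,
             apical = exp(rnorm(40)))
  res <- compare_conditions(m)
  expect_identical(res$test, "Friedman")
  expect_lt(res$p_value, 0.01)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_value))
})

test_that("the report reproduces hand-computed cells on a toy cohort", {
  toy <- tibble::tibble(
    subject_id = c("A", "B"), sex = factor(c("female", "female"),
                                           levels = c("female", "male")),
    age = c(40, 50),
    hr_rest = c(60, 64), sbp_rest = c(110, 120),
    hr_stress = c(90, 96), sbp_stress = c(115, 125),
    qc_excluded = FALSE,
    rmbf_wall_global = c(0.6, 0.7), smbf_wall_global = c(2.0, 2.6),
    rmbf_endo_global = c(0.66, 0.77), rmbf_epi_global = c(0.54, 0.63),
    smbf_endo_global = c(1.9, 2.47), smbf_epi_global = c(2.1, 2.73))
  metrics <- cohort_metrics(toy)
  expect_equal(metrics$rpp_rest, c(6600, 7680))
  expect_equal(metrics$rmbf_c, c(0.6 / 0.66, 0.7 / 0.768), tolerance = 1e-12)
  expect_equal(metrics$mpr_global, c(2.0 / 0.6, 2.6 / 0.7))
  expect_equal(metrics$rgrad_global, c(0.66 / 0.54, 0.77 / 0.63))

  rep <- build_report(metrics)
  d <- rep$tables$demographics
  expect_equal(d$mean_all[d$parameter == "age"], 45)
  expect_equal(d$sd_all[d$parameter == "age"], sd(c(40, 50)))
  g <- rep$tables$global_mbf
  expect_equal(g$median_all[g$parameter == "rmbf_wall_global"], 0.65)
  expect_equal(g$mean_all[g$parameter == "mpr_global"],
               mean(c(2.0 / 0.6, 2.6 / 0.7)))
  # single-sex stratum: comparison not applicable, no crash
  expect_true(all(is.na(g$p_sex)))
  expect_equal(rep$n_used, 2)
})

test_that("the report is order-invariant and seed-deterministic", {
  co <- cohort_metrics(make_cohort(cohort_spec(n_subjects = 30), seed = 12))
  r1 <- build_report(co, boot_seed = 5)
  r2 <- build_report(co[rev(seq_len(nrow(co))), ], boot_seed = 5)
  expect_identical(r1$tables, r2$tables)
  r3 <- build_report(co, boot_seed = 5)
  expect_identical(r1$tables, r3$tables)
})

test_that("QC-excluded subjects are dropped and counted", {
  co <- cohort_metrics(make_cohort(cohort_spec(n_subjects = 20), seed = 8))
  co$qc_excluded[c(3, 11)] <- TRUE
  rep <- build_report(co)
  expect_equal(rep$n_used, 18)
  expect_equal(rep$n_excluded, 2)
  expect_equal(rep$tables$layer_mbf$n_all[1], 18)
  co$qc_excluded <- TRUE
  expect_error(build_report(co), "fewer than 2")
})

test_that("normality gate drives summary presentation and test choice together", {
  set.seed(31)
  norm_s <- rnorm(60, 10, 2)
  skew_s <- exp(rnorm(60))
  s_norm <- summarize_metric(norm_s)
  s_skew <- summarize_metric(skew_s)
  expect_true(s_norm$normal)
  expect_false(s_skew$normal)
  expect_match(compare_groups(norm_s, rnorm(60, 10, 2))$test, "t-test")
  expect_match(compare_groups(skew_s, exp(rnorm(60)))$test, "Mann-Whitney")
})

test_that("paper-structured cohorts show no MPR sex difference when none is simulated", {
  # equalize MPR across sexes: stress mean = rest mean * common reserve
  spec <- cohort_spec(mbf_mean = list(rest = c(female = 0.68, male = 0.56),
                                      stress = c(female = 0.68, male = 0.56) * 3.6),
                      mbf_sd = list(rest = c(female = 0.13, male = 0.17),
                                    stress = c(female = 0.40, male = 0.47)))
  ok <- replicate(20, {
    co <- cohort_metrics(make_cohort(spec, seed = sample.int(2^30, 1)))
    compare_groups(co$mpr_global[co$sex == "female"],
                   co$mpr_global[co$sex == "male"])$p_value >= 0.05
  })
  expect_gte(mean(ok), 0.80)
})
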