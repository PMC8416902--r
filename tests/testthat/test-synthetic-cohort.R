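test_that("configuration errors are caught early", {
  d <- separated_design()
  expect_error(cohort_config(defs = d$defs, eventset = d$eventset,
                             subtypes = list(subtype_spec(d$seq_a, 1)),
                             control_sd = 0, seed = 1),
               "control_sd")
  expect_error(cohort_config(defs = d$defs, eventset = d$eventset,
                             subtypes = list(subtype_spec(d$seq_a, 1)),
                             noise_sd = 0, seed = 1),
               "noise_sd")
  expect_error(cohort_config(defs = d$defs, eventset = d$eventset,
                             subtypes = list(), seed = 1),
               "at least one subtype")
  expect_error(cohort_config(defs = d$defs, eventset = d$eventset,
                             subtypes = list(subtype_spec(d$seq_a, 0.6),
                                             subtype_spec(d$seq_b, 0.6)),
                             seed = 1),
               "sum to 1")
  expect_error(cohort_config(defs = d$defs, eventset = d$eventset,
                             subtypes = list(subtype_spec(d$seq_a, 1)),
                             severity_thresholds = c(5, 3), seed = 1),
               "strictly increasing")
  expect_error(subtype_spec(d$seq_a, 1.2), "fraction")
})

test_that("subtype-linked demographic shifts apply to the right subjects", {
  d <- separated_design()
  shifts <- data.frame(age = c(0, 10), bmi = c(-2, 2))
  cfg <- cohort_config(n_subjects = 1200, n_controls = 10, defs = d$defs,
                       eventset = d$eventset,
                       subtypes = list(subtype_spec(d$seq_a, 0.5),
                                       subtype_spec(d$seq_b, 0.5)),
                       demographic_shifts = shifts, seed = 19)
  coh <- generate_patient_cohort(cfg)
  m_age <- tapply(coh$demographics$age, coh$truth_subtype, mean)
  m_bmi <- tapply(coh$demographics$bmi, coh$truth_subtype, mean)
  expect_gt(m_age[["2"]] - m_age[["1"]], 8)
  expect_gt(m_bmi[["2"]] - m_bmi[["1"]], 3)
  expect_error(cohort_config(defs = d$defs, eventset = d$eventset,
                             subtypes = list(subtype_spec(d$seq_a, 1)),
                             demographic_shifts = data.frame(age = 1),
                             seed = 1),
               "demographic_shifts")
})

test_that("control group sampling matches the configured moments", {
  d <- separated_design()
  cfg <- cohort_config(n_subjects = 10, n_controls = 10000, defs = d$defs,
                       eventset = d$eventset,
                       subtypes = list(subtype_spec(d$seq_a, 1)),
                       control_mean = 4, control_sd = 1, seed = 7)
  ctrl <- generate_control_group(cfg)
  expect_equal(dim(ctrl), c(10000L, 10L))
  expect_true(all(abs(colMeans(ctrl) - 4) < 0.05))
  expect_true(all(abs(apply(ctrl, 2, sd) - 1) < 0.05))
})

test_that("identical seed and config give byte-identical cohorts", {
  a <- separated_cohort(seed = 21)
  b <- separated_cohort(seed = 21)
  expect_identical(a$cohort$raw_values, b$cohort$raw_values)
  expect_identical(a$cohort$demographics, b$cohort$demographics)
  expect_identical(a$cohort$truth_subtype, b$cohort$truth_subtype)
  expect_identical(generate_control_group(a$config),
                   generate_control_group(b$config))
})

test_that("subtype draws follow the configured fractions", {
  x <- separated_cohort(seed = 31, n_subjects = 2000)
  n1 <- sum(x$cohort$truth_subtype == 1)
  expect_true(abs(n1 - 1000) <= 70)        # 3 sigma of Binomial(2000, .5)
  # larger-sample calibration at unequal fractions
  d <- separated_design()
  cfg <- cohort_config(n_subjects = 5000, n_controls = 20, defs = d$defs,
                       eventset = d$eventset,
                       subtypes = list(subtype_spec(d$seq_a, 0.15),
                                       subtype_spec(d$seq_b, 0.85)), seed = 8)
  coh <- generate_patient_cohort(cfg)
  p1 <- mean(coh$truth_subtype == 1)
  expect_true(abs(p1 - 0.15) < 3 * sqrt(0.15 * 0.85 / 5000))
})

test_that("stages are uniform over 0..S and all stages occur", {
  panel <- koa_biomarker_panel()
  es <- event_set_from_defs(panel)
  cfg <- cohort_config(n_subjects = 3300, n_controls = 20, defs = panel,
                       eventset = es,
                       subtypes = default_subtype_specs(es, seed = 2), seed = 2)
  coh <- generate_patient_cohort(cfg)
  expect_setequal(unique(coh$truth_stage), 0:32)
  expect_gt(stats::chisq.test(table(coh$truth_stage))$p.value, 1e-6)
})

test_that("z-scores equal the trajectory at the truth stage in the noiseless limit", {
  d <- separated_design()
  cfg <- cohort_config(n_subjects = 40, n_controls = 10, defs = d$defs,
                       eventset = d$eventset,
                       subtypes = list(subtype_spec(d$seq_a, 0.4),
                                       subtype_spec(d$seq_b, 0.6)),
                       noise_sd = 1e-9, seed = 13)
  coh <- generate_patient_cohort(cfg)
  trajs <- list(expected_trajectory(d$seq_a, d$eventset),
                expected_trajectory(d$seq_b, d$eventset))
  for (j in seq_len(40)) {
    mu <- trajs[[coh$truth_subtype[j]]][coh$truth_stage[j] + 1L, ]
    expect_equal(unname(coh$z_values[j, ]), unname(mu), tolerance = 1e-6)
  }
})

test_that("severity grade thresholds the stage monotonically", {
  expect_equal(severity_from_stage(0, c(4, 12, 22, 29)), 0L)
  expect_equal(severity_from_stage(32, c(4, 12, 22, 29)), 4L)
  expect_equal(severity_from_stage(15, c(4, 12, 22, 29)), 2L)
  g <- severity_from_stage(0:32, c(4, 12, 22, 29))
  expect_true(all(diff(g) >= 0))
  expect_error(severity_from_stage(3, c(5, 2)), "strictly increasing")
  # label noise moves grades by at most one level
  withr::with_seed(4, {
    gn <- severity_from_stage(rep(15L, 500), c(4, 12, 22, 29), flip_prob = 0.3)
    expect_true(all(abs(gn - 2L) <= 1))
    expect_true(any(gn != 2L))
  })
})

test_that("grades in a generated cohort are consistent with the truth stage", {
  x <- separated_cohort(seed = 17, n_subjects = 300)
  expect_equal(x$cohort$severity_grade,
               severity_from_stage(x$cohort$truth_stage,
                                   x$config$severity_thresholds))
  expect_false(any(is.na(x$cohort$raw_values)))
  expect_true(all(x$cohort$truth_stage >= 0 &
                    x$cohort$truth_stage <= x$design$eventset$S))
})

test_that("noiseless subjects are staged and subtyped perfectly", {
  d <- separated_design()
  cfg <- cohort_config(n_subjects = 120, n_controls = 10, defs = d$defs,
                       eventset = d$eventset,
                       subtypes = list(subtype_spec(d$seq_a, 0.5),
                                       subtype_spec(d$seq_b, 0.5)),
                       noise_sd = 1e-7, seed = 23)
  coh <- generate_patient_cohort(cfg)
  model <- oasustain:::new_progression_model(list(d$seq_a, d$seq_b),
                                             c(0.5, 0.5), 1, d$eventset)
  post <- assign_subjects(coh$z_values, model)
  # stages identify every subject; subtypes identify all except stage 0 and S,
  # where the two reversed trajectories coincide
  expect_equal(post$ml_stage, coh$truth_stage)
  interior <- coh$truth_stage > 0 & coh$truth_stage < d$eventset$S
  expect_equal(post$ml_subtype[interior], coh$truth_subtype[interior])
})
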