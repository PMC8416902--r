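test_that("control statistics use sample mean and n-1 standard deviation", {
  tab <- data.frame(a = c(0, 2), b = c(3, 5))
  st <- compute_control_stats(tab)
  expect_equal(st$mean, c(1, 4))
  expect_equal(st$sd, c(sqrt(2), sqrt(2)))

  tab2 <- data.frame(x = c(3, 4, 5, 6, 7))
  st2 <- compute_control_stats(tab2)
  expect_equal(st2$mean, 5)
  expect_equal(st2$sd, sqrt(2.5), tolerance = 1e-12)
  expect_equal(round(st2$sd, 4), 1.5811)
})

test_that("degenerate control columns are rejected by name", {
  tab <- data.frame(ok = c(1, 2, 3), flat = c(1, 1, 1))
  expect_error(compute_control_stats(tab), "flat")
  expect_error(compute_control_stats(tab[1, , drop = FALSE]), "at least 2")
  tab$ok[2] <- NA
  expect_error(compute_control_stats(tab), "missing")
})

test_that("z-scoring centers, scales, and flips decreasing biomarkers", {
  defs <- biomarker_defs(c("up", "down"), c(1, -1), list(c(1, 2), c(1, 2)))
  st <- structure(data.frame(name = c("up", "down"), mean = c(10, 4),
                             sd = c(2, 0.5)),
                  class = c("control_stats", "data.frame"))
  raw <- data.frame(up = c(10, 14), down = c(4, 3))
  Z <- to_zscores(raw, st, defs)
  expect_equal(Z[1, ], c(up = 0, down = 0))        # x = mean -> 0 either way
  expect_equal(Z[2, "up"], c(up = 2))              # mean + 2 sd -> +2
  expect_equal(Z[2, "down"], c(down = 2))          # JSW-like: mean - 2 sd -> +2
  expect_error(to_zscores(raw[, c("down", "up")], st, defs), "match")
})

test_that("z-scoring inverts the synthetic raw construction exactly", {
  d <- separated_design()
  defs <- biomarker_defs(d$defs$name, rep(c(1, -1), 5), d$defs$candidate_events)
  cfg <- cohort_config(n_subjects = 50, n_controls = 10, defs = defs,
                       eventset = event_set_from_defs(defs),
                       subtypes = list(subtype_spec(d$seq_a, 1)),
                       control_mean = seq(2, 20, by = 2),
                       control_sd = seq(0.5, 5, by = 0.5), seed = 3)
  cohort <- generate_patient_cohort(cfg)
  true_stats <- structure(data.frame(name = defs$name, mean = cfg$control_mean,
                                     sd = cfg$control_sd),
                          class = c("control_stats", "data.frame"))
  Z <- to_zscores(cohort$raw_values, true_stats, defs)
  expect_equal(unname(Z), unname(cohort$z_values), tolerance = 1e-9)
})

test_that("event retention requires min_count subjects strictly above threshold", {
  defs <- biomarker_defs("bm1", 1, list(c(1, 5)))
  # 12 subjects above z=1; exactly 9 above z=5 -> the z=5 event is dropped
  Z <- matrix(c(rep(1.5, 3), rep(5.5, 9), rep(-1, 8)), ncol = 1)
  colnames(Z) <- "bm1"
  es <- build_event_set(Z, defs, min_count = 10)
  expect_equal(es$events$z, 1)
  expect_equal(es$S, 1L)
  # one more subject above 5 retains it, and ties at the threshold don't count
  Z10 <- rbind(Z, 5.5)
  expect_equal(build_event_set(Z10, defs, min_count = 10)$events$z, c(1, 5))
  Ztie <- rbind(Z, 5.0)
  expect_equal(build_event_set(Ztie, defs, min_count = 10)$events$z, 1)
})

test_that("max-z input follows the largest retained event mapping", {
  expect_equal(max_z_for(c(1, 2, 3, 5)), c(2, 3, 5, 7))
  expect_error(max_z_for(4), "must be one of")
  defs <- biomarker_defs("bm1", 1, list(c(1, 2, 3, 5)))
  Z <- matrix(rep(6, 30), ncol = 1, dimnames = list(NULL, "bm1"))
  es <- build_event_set(Z, defs, min_count = 10)
  expect_equal(unname(es$max_z["bm1"]), 7)         # largest retained 5 -> 7
  Z3 <- matrix(rep(4, 30), ncol = 1, dimnames = list(NULL, "bm1"))
  expect_equal(unname(build_event_set(Z3, defs, min_count = 10)$max_z["bm1"]), 5)
})

test_that("raising min_count never adds events, and empty biomarkers error", {
  defs <- make_defs(3, events = c(1, 2, 3))
  Z <- random_z(80, event_set_from_defs(defs), seed = 11, scale = 2)
  counts <- c()
  prev <- Inf
  for (mc in c(1, 5, 10, 20)) {
    es <- tryCatch(build_event_set(Z, defs, min_count = mc),
                   error = function(e) NULL)
    s <- if (is.null(es)) 0L else es$S
    expect_lte(s, prev)
    prev <- s
  }
  Zlow <- matrix(rep(-2, 60), ncol = 3,
                 dimnames = list(NULL, defs$name))
  expect_error(build_event_set(Zlow, defs, min_count = 10), "bm1")
})

test_that("backward deletion drops a pure-noise biomarker first", {
  d <- separated_design()
  small_defs <- biomarker_defs(paste0("bm", 1:4), 1, rep(list(3), 4))
  small_es <- event_set_from_defs(small_defs)
  cfg <- cohort_config(n_subjects = 150, n_controls = 50, defs = small_defs,
                       eventset = small_es,
                       subtypes = list(subtype_spec(c(1:4), 1)), seed = 5)
  cohort <- generate_patient_cohort(cfg)
  Z <- to_zscores(cohort$raw_values,
                  compute_control_stats(generate_control_group(cfg)),
                  small_defs)
  # append a biomarker that carries no progression signal
  noise <- withr::with_seed(9, stats::rnorm(150, mean = 1.2, sd = 2))
  Zn <- cbind(Z, junk = noise)
  defs_n <- biomarker_defs(c(small_defs$name, "junk"), 1,
                           c(small_defs$candidate_events, list(3)))
  res <- backward_delete_biomarkers(Zn, defs_n, min_count = 5,
                                    n_starts = 3, seed = 2)
  expect_true("junk" %in% res$removed)
  expect_equal(res$removed[1], "junk")
  expect_false("junk" %in% res$selected$name)
})

test_that("backward deletion needs two biomarkers and keeps informative sets", {
  defs <- make_defs(1, events = 3)
  expect_error(backward_delete_biomarkers(matrix(1, 5, 1), defs), "at least 2")
  # with a criterion that always worsens on deletion, nothing is removed
  res <- backward_delete_biomarkers(
    matrix(stats::rnorm(40), 10, 4,
           dimnames = list(NULL, paste0("bm", 1:4))),
    make_defs(4),
    criterion = function(Z, defs) ncol(Z))  # more biomarkers always better
  expect_equal(res$removed, character(0))
  expect_equal(nrow(res$selected), 4L)
})
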