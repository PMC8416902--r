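#' Synthetic knee-OA cohorts with known ground truth
#'
#' The generator emulates the statistical structure of a cross-sectional
#' knee-osteoarthritis study: a disease-free control group on the raw
#' biomarker scale, and a patient cohort in which each knee has a latent
#' subtype (with known mixing fractions), a latent stage drawn uniformly over
#' 0..S, biomarker z-scores that follow the subtype's piecewise-linear event
#' trajectory plus unit-scale Gaussian noise, independent demographics, and
#' an ordinal severity grade (a KL-grade analog) derived from the stage by
#' fixed thresholds. Because raw values are reconstructed as
#' `control_mean + direction * z * control_sd`, downstream z-scoring recovers
#' the generating z-scores.
#'
#' @name synthetic_cohort
NULL

#' Ground-truth subtype specification
#'
#' @param sequence a valid event sequence for the config's event set.
#' @param fraction the subtype's mixing proportion in `[0, 1]`.
#' @return A `subtype_spec` list.
#' @export
subtype_spec <- function(sequence, fraction) {
  if (fraction < 0 || fraction > 1) stop_("fraction must lie in [0, 1]")
  structure(list(sequence = sequence, fraction = fraction),
            class = "subtype_spec")
}

#' Distinct random ground-truth subtypes
#'
#' Convenience constructor drawing distinct uniformly random valid sequences.
#'
#' @param eventset an `event_set`.
#' @param fractions mixing proportions summing to 1; default the three
#'   knee-OA subtype proportions 15/61/24%.
#' @param seed integer seed.
#' @return A list of [subtype_spec()]s.
#' @export
default_subtype_specs <- function(eventset, fractions = c(0.15, 0.61, 0.24),
                                  seed = 1) {
  seqs <- with_seed_(seed, {
    out <- list()
    while (length(out) < length(fractions)) {
      s <- random_sequence(eventset)
      if (!any(vapply(out, identical, logical(1), y = s))) out <- c(out, list(s))
    }
    out
  })
  Map(subtype_spec, seqs, as.list(fractions))
}

#' Cohort generator configuration
#'
#' Defaults reproduce the study conditions the package is validated under:
#' the 13-biomarker panel with 32 z-score events, 678 knees, three subtypes
#' at 15/61/24%, uniform stages, unit z-scale noise, and grade thresholds
#' that give a typical radiographic severity mix (roughly 6% grade
#' 0/1, then 33/42/18% for grades 2-4 under a uniform stage prior).
#'
#' @param n_subjects,n_controls positive counts.
#' @param defs a [biomarker_defs()] panel.
#' @param eventset ground-truth `event_set`; default all candidate events of
#'   `defs`.
#' @param subtypes list of [subtype_spec()]; fractions must sum to 1.
#'   Default: three distinct random sequences at 15/61/24%.
#' @param noise_sd z-scale noise standard deviation (> 0), default 1.
#' @param control_mean,control_sd per-biomarker raw-scale location and scale
#'   (scalars recycled; `control_sd > 0`).
#' @param severity_thresholds strictly increasing stage cutpoints mapping
#'   stage to grades 0..4 via `grade = findInterval(stage, thresholds)`.
#' @param grade_flip_prob probability a grade is perturbed to an adjacent
#'   grade (label noise), default 0.
#' @param demographic_shifts optional per-subtype mean shifts for power
#'   studies: a matrix (subtypes x 2) or data frame with columns `age` and
#'   `bmi`, added to the corresponding subjects' draws. `NULL` (default)
#'   keeps demographics independent of subtype.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 678, n_controls = 200,
                          defs = koa_biomarker_panel(),
                          eventset = event_set_from_defs(defs),
                          subtypes = default_subtype_specs(eventset, seed = seed),
                          noise_sd = 1,
                          control_mean = 0, control_sd = 1,
                          severity_thresholds = NULL,
                          grade_flip_prob = 0,
                          demographic_shifts = NULL, seed = 1) {
  B <- nrow(defs)
  if (length(control_mean) == 1L) control_mean <- rep(control_mean, B)
  if (length(control_sd) == 1L) control_sd <- rep(control_sd, B)
  if (n_subjects < 1 || n_controls < 1) stop_("counts must be positive")
  if (noise_sd <= 0) stop_("noise_sd must be positive")
  if (any(control_sd <= 0)) stop_("control_sd must be positive for every biomarker")
  if (length(subtypes) == 0L) stop_("at least one subtype required")
  fr <- vapply(subtypes, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-12) stop_("subtype fractions must sum to 1")
  for (sp in subtypes) validate_sequence(sp$sequence, eventset)
  if (!is.null(demographic_shifts)) {
    demographic_shifts <- as.data.frame(demographic_shifts)
    if (nrow(demographic_shifts) != length(subtypes) ||
        !all(c("age", "bmi") %in% names(demographic_shifts))) {
      stop_("demographic_shifts needs one row per subtype and columns age, bmi")
    }
  }
  S <- eventset$S
  if (is.null(severity_thresholds)) {
    # grades 0,1 each ~1 stage; remaining stages split ~33/42/18% as 2/3/4
    severity_thresholds <- unique(pmin(c(1, 2, ceiling(0.40 * S),
                                         ceiling(0.82 * S)), S))
  }
  if (is.unsorted(severity_thresholds, strictly = TRUE) ||
      any(severity_thresholds < 0) || any(severity_thresholds > S)) {
    stop_("severity_thresholds must be strictly increasing within [0, S]")
  }
  structure(list(n_subjects = n_subjects, n_controls = n_controls,
                 defs = defs, eventset = eventset, subtypes = subtypes,
                 noise_sd = noise_sd, control_mean = control_mean,
                 control_sd = control_sd,
                 severity_thresholds = severity_thresholds,
                 grade_flip_prob = grade_flip_prob,
                 demographic_shifts = demographic_shifts,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate the raw-scale control group
#'
#' Each biomarker column is Gaussian with the configured raw-scale mean and
#' standard deviation; deterministic given the config's seed.
#'
#' @param config a [cohort_config()].
#' @return A data frame of `n_controls` rows x biomarker columns.
#' @export
generate_control_group <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  B <- nrow(config$defs)
  X <- with_seed_(child_seed(config$seed, 1L), {
    vapply(seq_len(B), function(i) {
      stats::rnorm(config$n_controls, config$control_mean[i], config$control_sd[i])
    }, numeric(config$n_controls))
  })
  X <- as.data.frame(X)
  names(X) <- config$defs$name
  X
}

#' Map a stage to an ordinal severity grade
#'
#' `grade = findInterval(stage, thresholds)`; monotone non-decreasing in
#' stage when `flip_prob = 0`. With `flip_prob > 0`, the grade moves to an
#' adjacent grade with that probability (clamped to 0..4).
#'
#' @param stage integer stage(s) in 0..S.
#' @param thresholds strictly increasing cutpoints (at most 4, giving grades
#'   0..4).
#' @param flip_prob adjacent-grade label-noise probability.
#' @return Integer grade(s) 0..4.
#' @examples
#' severity_from_stage(15, c(4, 12, 22, 29)) # 2
#' @export
severity_from_stage <- function(stage, thresholds, flip_prob = 0) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop_("thresholds must be strictly increasing")
  }
  if (any(stage < 0)) stop_("stage must be non-negative")
  g <- findInterval(stage, thresholds)
  if (flip_prob > 0) {
    flip <- stats::runif(length(g)) < flip_prob
    dir <- sample(c(-1L, 1L), length(g), replace = TRUE)
    g[flip] <- pmin(pmax(g[flip] + dir[flip], 0L), length(thresholds))
  }
  as.integer(g)
}

#' Generate a patient cohort with known subtype and stage labels
#'
#' Each subject draws a subtype from the configured fractions and a stage
#' uniformly on \{0..S\}; its z-scores are the subtype trajectory at that
#' stage plus `Normal(0, noise_sd)` noise; raw values reconstruct the raw
#' scale as `control_mean + direction * z * control_sd`. Demographics (age,
#' sex, BMI, injury) are drawn independently of subtype; the severity grade
#' thresholds the true stage (before noise) with optional label noise.
#'
#' @param config a [cohort_config()].
#' @return A `synthetic_cohort`: `raw_values` (data frame), `demographics`
#'   (data frame: age, sex, bmi, injury), `severity_grade`, `truth_subtype`,
#'   `truth_stage`, `z_values` (the noisy generating z-scores), and the
#'   `config`.
#' @export
generate_patient_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  es <- config$eventset
  n <- config$n_subjects
  S <- es$S
  fr <- vapply(config$subtypes, `[[`, numeric(1), "fraction")
  trajs <- lapply(config$subtypes, function(sp) expected_trajectory(sp$sequence, es))
  with_seed_(child_seed(config$seed, 2L), {
    subtype <- sample.int(length(fr), n, replace = TRUE, prob = fr)
    stage <- sample.int(S + 1L, n, replace = TRUE) - 1L
    mu <- t(vapply(seq_len(n), function(j) trajs[[subtype[j]]][stage[j] + 1L, ],
                   numeric(ncol(trajs[[1]]))))
    Zn <- mu + matrix(stats::rnorm(n * ncol(mu), 0, config$noise_sd), n)
    colnames(Zn) <- config$defs$name
    raw <- sweep(sweep(Zn, 2L, config$defs$direction * config$control_sd, "*"),
                 2L, config$control_mean, "+")
    demo <- data.frame(
      age = stats::rnorm(n, 62, 9),
      sex = stats::rbinom(n, 1L, 0.55),
      bmi = stats::rnorm(n, 29, 4.7),
      injury = stats::rbinom(n, 1L, 0.2065)
    )
    if (!is.null(config$demographic_shifts)) {
      demo$age <- demo$age + config$demographic_shifts$age[subtype]
      demo$bmi <- demo$bmi + config$demographic_shifts$bmi[subtype]
    }
    grade <- severity_from_stage(stage, config$severity_thresholds,
                                 config$grade_flip_prob)
    structure(list(raw_values = as.data.frame(raw), demographics = demo,
                   severity_grade = grade, truth_subtype = subtype,
                   truth_stage = stage, z_values = Zn, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$raw_values), "subjects,",
      ncol(x$raw_values), "biomarkers,",
      length(x$config$subtypes), "ground-truth subtype(s)\n")
  cat("  grade mix:", paste(names(table(x$severity_grade)),
                            table(x$severity_grade), sep = ":", collapse = "  "), "\n")
  invisible(x)
}
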