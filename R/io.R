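#' File formats and serialization
#'
#' Plain-text interchange for the pipeline: cohorts and control groups as
#' CSV (comma-separated, UTF-8, header row, "." decimal), biomarker
#' definitions as CSV with semicolon-joined candidate events, fitted models
#' as JSON, and positional-variance matrices as CSV.
#'
#' @name cli_io
NULL

IO_FORMAT_VERSION <- "1"

#' Write / read a synthetic cohort
#'
#' One row per subject: biomarker columns, demographics, severity grade, and
#' the ground-truth subtype and stage. A JSON sidecar (`<path>.json`) stores
#' the generator seed and key config scalars.
#'
#' @param cohort a `synthetic_cohort`.
#' @param path CSV output path.
#' @return `write_cohort_csv()`: the path, invisibly. `read_cohort_csv()`:
#'   a list with `biomarkers` (data frame), `demographics`, `severity_grade`,
#'   `truth_subtype`, `truth_stage`.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  df <- cbind(cohort$raw_values, cohort$demographics,
              data.frame(severity_grade = cohort$severity_grade,
                         truth_subtype = cohort$truth_subtype,
                         truth_stage = cohort$truth_stage))
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(format_version = IO_FORMAT_VERSION,
                  seed = cohort$config$seed,
                  n_subjects = cohort$config$n_subjects,
                  n_controls = cohort$config$n_controls,
                  noise_sd = cohort$config$noise_sd,
                  severity_thresholds = cohort$config$severity_thresholds,
                  fractions = vapply(cohort$config$subtypes, `[[`,
                                     numeric(1), "fraction"),
                  biomarkers = cohort$config$defs$name)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param biomarker_names which columns are biomarkers; default: everything
#'   before the demographic columns.
#' @export
read_cohort_csv <- function(path, biomarker_names = NULL) {
  if (!file.exists(path)) stop_("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop_("empty cohort file: ", path)
  known <- c("age", "sex", "bmi", "injury", "severity_grade",
             "truth_subtype", "truth_stage")
  if (is.null(biomarker_names)) {
    biomarker_names <- setdiff(names(df), known)
  }
  missing <- setdiff(biomarker_names, names(df))
  if (length(missing)) stop_("missing biomarker column(s): ",
                             paste(missing, collapse = ", "))
  bio <- df[, biomarker_names, drop = FALSE]
  for (nm in biomarker_names) {
    if (!is.numeric(bio[[nm]])) {
      stop_("non-numeric biomarker cell(s) in column '", nm, "'")
    }
  }
  list(biomarkers = bio,
       demographics = df[, intersect(c("age", "sex", "bmi", "injury"),
                                     names(df)), drop = FALSE],
       severity_grade = df$severity_grade,
       truth_subtype = df$truth_subtype,
       truth_stage = df$truth_stage)
}

#' Write / read biomarker definitions
#'
#' CSV with columns `name`, `direction`, `candidate_events` (semicolon
#' joined, e.g. `"1;2;3"`).
#'
#' @param defs a [biomarker_defs()] object.
#' @param path CSV path.
#' @export
write_biomarker_defs <- function(defs, path) {
  stopifnot(inherits(defs, "biomarker_defs"))
  df <- data.frame(name = defs$name, direction = defs$direction,
                   candidate_events = vapply(defs$candidate_events,
                                             paste, character(1),
                                             collapse = ";"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_biomarker_defs
#' @export
read_biomarker_defs <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop_("empty biomarker definition file: ", path)
  req <- c("name", "direction", "candidate_events")
  missing <- setdiff(req, names(df))
  if (length(missing)) stop_("missing column(s): ", paste(missing, collapse = ", "))
  if (!all(df$direction %in% c(-1, 1))) {
    bad <- which(!df$direction %in% c(-1, 1))[1]
    stop_("unknown direction value in row ", bad, " ('", df$name[bad], "')")
  }
  cand <- lapply(strsplit(as.character(df$candidate_events), ";"), as.numeric)
  biomarker_defs(df$name, df$direction, cand)
}

#' Serialize a fitted progression model to JSON
#'
#' Writes sequences, fractions, sigma and the event set; reading back yields
#' an identical model (fractions to 1e-12). When a `sequence_posterior` is
#' supplied, each subtype's positional-variance matrix is also written as a
#' CSV heatmap table next to the JSON (`<path>.pv<k>.csv`).
#'
#' @param model a `progression_model`.
#' @param path JSON output path.
#' @param posterior optional `sequence_posterior`.
#' @export
write_model_json <- function(model, path, posterior = NULL) {
  stopifnot(inherits(model, "progression_model"))
  es <- model$eventset
  obj <- list(format_version = IO_FORMAT_VERSION,
              sequences = model$sequences,
              fractions = model$fractions,
              sigma = model$sigma,
              loglik = model$loglik,
              eventset = list(biomarker = es$events$biomarker,
                              z = es$events$z,
                              max_z = as.list(es$max_z),
                              direction = es$defs$direction,
                              defs_name = es$defs$name,
                              candidate_events = es$defs$candidate_events))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  if (!is.null(posterior)) {
    for (k in seq_along(posterior$subtypes)) {
      pv <- posterior$subtypes[[k]]$positional_variance
      stopifnot(all(abs(rowSums(pv) - 1) < 1e-9))
      lab <- paste0(es$events$biomarker, "_z", es$events$z)
      pvdf <- as.data.frame(pv)
      names(pvdf) <- paste0("position", seq_len(ncol(pv)))
      pvdf <- cbind(data.frame(event = lab), pvdf)
      utils::write.csv(pvdf, paste0(path, ".pv", k, ".csv"), row.names = FALSE)
    }
  }
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_("cannot parse model JSON: ",
                                            conditionMessage(e)))
  if (!identical(as.character(obj$format_version), IO_FORMAT_VERSION)) {
    stop_("model file format version mismatch: ",
          obj$format_version %||% "<absent>")
  }
  cand <- obj$eventset$candidate_events
  if (is.matrix(cand)) cand <- lapply(seq_len(nrow(cand)), function(i) cand[i, ])
  if (!is.list(cand)) cand <- as.list(cand)
  defs <- biomarker_defs(obj$eventset$defs_name, obj$eventset$direction, cand)
  events <- data.frame(biomarker = obj$eventset$biomarker, z = obj$eventset$z,
                       stringsAsFactors = FALSE)
  max_z <- unlist(obj$eventset$max_z)
  es <- new_event_set(events, max_z, defs)
  seqs <- obj$sequences
  if (is.matrix(seqs)) seqs <- lapply(seq_len(nrow(seqs)), function(i) seqs[i, ])
  seqs <- lapply(seqs, as.integer)
  new_progression_model(seqs, as.numeric(obj$fractions),
                        as.numeric(obj$sigma), es,
                        loglik = as.numeric(obj$loglik))
}
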