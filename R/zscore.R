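#' Control-referenced z-scoring
#'
#' Raw biomarker measurements are expressed as z-scores relative to a
#' disease-free control group, so that a z of 0 means "typical of controls"
#' and the z-scale is comparable across biomarkers. Biomarkers that decrease
#' with severity (joint space width, cartilage thickness) are sign-flipped so
#' that every z-score increases as the disease progresses.
#'
#' @name zscore_preprocess
NULL

#' Per-biomarker control statistics
#'
#' Sample mean and standard deviation (denominator n-1) of each biomarker
#' column in the control table.
#'
#' @param control_table data frame or matrix of controls x biomarkers, no
#'   missing values, at least 2 rows.
#' @return A `control_stats` object: data frame with `name`, `mean`, `sd`.
#' @export
compute_control_stats <- function(control_table) {
  X <- as.matrix(control_table)
  if (nrow(X) < 2L) stop_("need at least 2 control subjects")
  if (any(!is.finite(X))) stop_("control table contains missing or non-finite values")
  mu <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  bad <- names(sds)[sds == 0]
  if (length(bad)) {
    stop_("zero variance in control group for biomarker(s): ",
          paste(bad, collapse = ", "))
  }
  structure(data.frame(name = colnames(X), mean = unname(mu), sd = unname(sds),
                       stringsAsFactors = FALSE),
            class = c("control_stats", "data.frame"))
}

#' Direction-adjusted z-scores
#'
#' `z = direction * (x - mean) / sd`, so a JSW-like biomarker (direction -1)
#' two control standard deviations *below* the control mean scores z = +2.
#'
#' @param raw_table subjects x biomarkers data frame or matrix.
#' @param stats a [compute_control_stats()] result.
#' @param defs a [biomarker_defs()] object; columns of `raw_table` must match
#'   `defs$name` (order included).
#' @return Numeric matrix of z-scores with the biomarker columns.
#' @export
to_zscores <- function(raw_table, stats, defs) {
  X <- as.matrix(raw_table)
  if (!identical(colnames(X), defs$name) || !identical(stats$name, defs$name)) {
    stop_("columns of raw_table, stats and defs must match (same names, same order)")
  }
  if (any(!is.finite(X))) stop_("raw table contains missing or non-finite values")
  Z <- sweep(sweep(X, 2L, stats$mean, "-"), 2L, stats$sd, "/")
  Z <- sweep(Z, 2L, defs$direction, "*")
  Z
}

#' Build the z-score event set from data
#'
#' Retains, for each biomarker, the candidate z-score events that at least
#' `min_count` subjects strictly exceed; low-occupancy events are dropped to
#' keep the model identifiable. Each biomarker's maximum z is then set from
#' its largest retained event by the mapping 1->2, 2->3, 3->5, 5->7.
#'
#' @param Z direction-adjusted z-score matrix (see [to_zscores()]).
#' @param defs a [biomarker_defs()] object.
#' @param candidate_z global candidate thresholds; a biomarker's candidates
#'   are intersected with this set.
#' @param min_count minimum number of subjects strictly above a threshold for
#'   the event to be retained (default 10).
#' @return An `event_set`.
#' @export
build_event_set <- function(Z, defs, candidate_z = c(1, 2, 3, 5), min_count = 10) {
  if (min_count < 1) stop_("min_count must be >= 1")
  if (!identical(colnames(Z), defs$name)) stop_("Z columns must match defs")
  rows <- list()
  max_z <- numeric(nrow(defs))
  names(max_z) <- defs$name
  for (i in seq_len(nrow(defs))) {
    cand <- intersect(defs$candidate_events[[i]], candidate_z)
    keep <- cand[vapply(cand, function(thr) sum(Z[, i] > thr) >= min_count, logical(1))]
    if (length(keep) == 0L) {
      stop_("no z-score event retained for biomarker '", defs$name[i],
            "'; remove it from the panel first")
    }
    rows[[i]] <- data.frame(biomarker = defs$name[i], z = keep,
                            stringsAsFactors = FALSE)
    max_z[i] <- max_z_for(max(keep))
  }
  events <- do.call(rbind, rows)
  rownames(events) <- NULL
  new_event_set(events, max_z, defs)
}

#' Backward deletion of biomarkers
#'
#' Starting from the full panel, repeatedly removes the biomarker whose
#' removal most improves a per-biomarker-normalized fit criterion, stopping
#' when no removal improves it. The default criterion is the mean held-out
#' log-likelihood *per biomarker* from a seeded 3-fold cross-validated
#' single-subtype fit; raw likelihoods are not comparable across panels of
#' different size, so the per-biomarker normalization makes the deletion
#' well-posed.
#'
#' @param Z z-score matrix.
#' @param defs a [biomarker_defs()] object.
#' @param criterion function(Z_sub, defs_sub) -> scalar score, higher is
#'   better; `NULL` for the default CV criterion.
#' @param min_count event-occupancy threshold passed to [build_event_set()].
#' @param n_starts,seed fitting controls for the default criterion.
#' @return List with `selected` (a `biomarker_defs` subset), `removed`
#'   (names, in deletion order) and `trace` (criterion after each step).
#' @export
backward_delete_biomarkers <- function(Z, defs, criterion = NULL,
                                       min_count = 10, n_starts = 5, seed = 1) {
  if (nrow(defs) < 2L) stop_("need at least 2 biomarkers")
  if (is.null(criterion)) {
    criterion <- function(Zs, ds) {
      cv_loglik_per_biomarker(Zs, ds, min_count = min_count,
                              n_starts = n_starts, seed = seed)
    }
  }
  current <- seq_len(nrow(defs))
  removed <- character(0)
  score <- criterion(Z[, current, drop = FALSE], defs_subset(defs, current))
  trace <- score
  while (length(current) > 1L) {
    cand_scores <- vapply(seq_along(current), function(k) {
      keep <- current[-k]
      tryCatch(
        criterion(Z[, keep, drop = FALSE], defs_subset(defs, keep)),
        error = function(e) {
          stop_("criterion failed after removing '", defs$name[current[k]],
                "': ", conditionMessage(e))
        })
    }, numeric(1))
    best <- which.max(cand_scores)
    if (cand_scores[best] <= score) break
    removed <- c(removed, defs$name[current[best]])
    current <- current[-best]
    score <- cand_scores[best]
    trace <- c(trace, score)
  }
  list(selected = defs_subset(defs, current), removed = removed, trace = trace)
}

defs_subset <- function(defs, idx) {
  out <- defs[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("biomarker_defs", "data.frame")
  out
}

# Default backward-deletion criterion: 3-fold CV held-out log-likelihood of a
# single-subtype fit, divided by the number of biomarkers.
cv_loglik_per_biomarker <- function(Z, defs, min_count, n_starts, seed) {
  es <- build_event_set(Z, defs, min_count = min_count)
  n <- nrow(Z)
  folds <- with_seed_(seed, sample(rep_len(1:3, n)))
  held <- 0
  for (f in 1:3) {
    train <- Z[folds != f, , drop = FALSE]
    test <- Z[folds == f, , drop = FALSE]
    m <- fit_sustain(train, es, c = 1, n_starts = n_starts,
                     seed = child_seed(seed, f))
    held <- held + dataset_loglik(test, m)
  }
  held / (n * ncol(Z))
}
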