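#' Subtype and stage assignment
#'
#' Once a subtypes-progression model is fitted, each subject gets a posterior
#' over subtypes (proportional to mixing fraction times stage-marginalized
#' likelihood) and, within each subtype, a posterior over stages 0..S. The
#' subtype-marginalized stage posterior mixes the per-subtype stage vectors
#' by the subtype probabilities.
#'
#' @name staging_assignment
NULL

#' Per-subject subtype and stage posteriors
#'
#' @param Z z-score matrix.
#' @param model a fitted `progression_model`.
#' @return A `subject_posteriors` object: `subtype_probs` (n x c),
#'   `stage_probs` (list of c matrices n x (S+1)), `stage_marginal`
#'   (n x (S+1)), and the maximum-a-posteriori `ml_subtype` / `ml_stage`
#'   (stage ties break toward the lower stage; 0-based stages).
#' @export
assign_subjects <- function(Z, model) {
  Z <- as.matrix(Z)
  stopifnot(inherits(model, "progression_model"))
  if (ncol(Z) != ncol(expected_trajectory(model$sequences[[1]], model$eventset))) {
    stop_("Z has a different biomarker count than the model's event set")
  }
  e <- responsibilities(Z, model)
  cP <- e$R
  stage_probs <- lapply(model$sequences, function(s) {
    stage_posterior(Z, s, model$eventset, model$sigma)
  })
  marg <- Reduce(`+`, Map(function(P, k) P * cP[, k], stage_probs,
                          seq_along(stage_probs)))
  # normalization asserted for every subject
  stopifnot(all(abs(rowSums(cP) - 1) < 1e-9),
            all(abs(rowSums(marg) - 1) < 1e-9))
  structure(list(
    subtype_probs = cP,
    stage_probs = stage_probs,
    stage_marginal = marg,
    ml_subtype = max.col(cP, ties.method = "first"),
    ml_stage = apply_ml_stage(stage_probs, cP)
  ), class = "subject_posteriors")
}

# ML stage under the ML subtype; which.max takes the first (lowest) stage on ties.
apply_ml_stage <- function(stage_probs, subtype_probs) {
  ml_sub <- max.col(subtype_probs, ties.method = "first")
  vapply(seq_len(nrow(subtype_probs)), function(j) {
    which.max(stage_probs[[ml_sub[j]]][j, ]) - 1L
  }, integer(1))
}

#' The strong-assignment rule
#'
#' A subject is strongly assigned when its maximum subtype probability is at
#' least `ratio` (default 1.5) times each of the other subtype probabilities.
#' With a single subtype the rule is trivially true (a message is emitted).
#'
#' @param subtype_probs probability vector over subtypes.
#' @param ratio dominance ratio, default 1.5.
#' @return Logical scalar.
#' @examples
#' is_strong_assignment(c(0.6, 0.3, 0.1))    # TRUE
#' is_strong_assignment(c(0.4, 0.35, 0.25))  # FALSE
#' @export
is_strong_assignment <- function(subtype_probs, ratio = 1.5) {
  p <- as.numeric(subtype_probs)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) stop_("not a probability vector")
  if (length(p) == 1L) {
    message("single subtype: strong assignment is trivially true")
    return(TRUE)
  }
  i <- which.max(p)
  all(p[i] >= ratio * p[-i])
}

#' Stage distribution by severity group
#'
#' Per group, the mean of the subjects' subtype-marginalized stage posterior
#' vectors — the tabular analog of plotting, for each KL grade, the
#' probability of belonging to each stage.
#'
#' @param posteriors a `subject_posteriors` object.
#' @param group_labels one label per subject (e.g. KL grade).
#' @return A groups x (S+1) matrix; each row sums to 1. An empty group (a
#'   factor level with no subjects) yields a row of `NaN` with a warning.
#' @export
stage_distribution_by_group <- function(posteriors, group_labels) {
  M <- posteriors$stage_marginal
  if (length(group_labels) != nrow(M)) stop_("one label per subject required")
  g <- as.factor(group_labels)
  out <- matrix(NaN, nlevels(g), ncol(M),
                dimnames = list(levels(g), colnames(M)))
  for (lv in levels(g)) {
    idx <- which(g == lv)
    if (length(idx) == 0L) {
      warning("empty group '", lv, "': row of NaN")
      next
    }
    out[lv, ] <- colMeans(M[idx, , drop = FALSE])
  }
  out
}

#' Strong-assignment rate by severity group
#'
#' Proportion of subjects in each group passing [is_strong_assignment()].
#'
#' @inheritParams stage_distribution_by_group
#' @param ratio dominance ratio, default 1.5.
#' @return Named numeric vector of per-group proportions in `[0, 1]`.
#' @export
strong_assignment_rate_by_group <- function(posteriors, group_labels,
                                            ratio = 1.5) {
  P <- posteriors$subtype_probs
  if (length(group_labels) != nrow(P)) stop_("one label per subject required")
  strong <- vapply(seq_len(nrow(P)), function(j) {
    suppressMessages(is_strong_assignment(P[j, ], ratio))
  }, logical(1))
  g <- as.factor(group_labels)
  out <- vapply(levels(g), function(lv) {
    idx <- which(g == lv)
    if (length(idx) == 0L) {
      warning("empty group '", lv, "': NaN rate")
      return(NaN)
    }
    mean(strong[idx])
  }, numeric(1))
  names(out) <- levels(g)
  out
}
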