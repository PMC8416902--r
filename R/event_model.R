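#' The linear z-score event-based model
#'
#' Under a given event sequence, each biomarker's expected z-score follows a
#' piecewise-linear trajectory over the discrete stages 0..S: it starts at 0,
#' passes through each of its z-score events at the stage where that event
#' occurs, and continues linearly towards its maximum z at stage S. A subject
#' at stage k is modelled as the stage-k trajectory value plus independent
#' Gaussian noise per biomarker. The stage itself is latent, with a discrete
#' uniform prior over \{0, ..., S\}, and is marginalized out of the subject
#' likelihood.
#'
#' @name event_model
NULL

#' Expected biomarker trajectories for a sequence
#'
#' For biomarker i with events z1 < ... < zm placed at positions
#' p1 < ... < pm of the sequence, the trajectory linearly interpolates the
#' knots (0,0), (p1,z1), ..., (pm,zm), (S, max_z); the final knot is dropped
#' when pm = S. Trajectories are evaluated at the integer stages 0..S.
#'
#' @param seq a valid event sequence (see [validate_sequence()]).
#' @param eventset an `event_set`.
#' @return A numeric matrix with S+1 rows (stages 0..S) and one column per
#'   biomarker; non-decreasing down each column, 0 in row 1.
#' @export
expected_trajectory <- function(seq, eventset) {
  validate_sequence(seq, eventset)
  S <- eventset$S
  bm <- eventset$events$biomarker
  biomarkers <- unique(bm)
  stages <- 0:S
  out <- matrix(0, nrow = S + 1L, ncol = length(biomarkers),
                dimnames = list(NULL, biomarkers))
  pos_of <- integer(S)
  pos_of[seq] <- seq_len(S)              # pos_of[event id] = position
  for (j in seq_along(biomarkers)) {
    idx <- which(bm == biomarkers[j])
    kx <- c(0, pos_of[idx])
    ky <- c(0, eventset$events$z[idx])
    if (kx[length(kx)] < S) {
      kx <- c(kx, S)
      ky <- c(ky, eventset$max_z[[biomarkers[j]]])
    }
    out[, j] <- stats::approx(kx, ky, xout = stages, method = "linear")$y
  }
  out
}

# Stage log-likelihood matrix: L[j, k+1] = log N(x_j | trajectory at stage k).
# The single matrix product here is the package's computational hot spot.
stage_loglik_matrix <- function(Z, traj, sigma) {
  B <- ncol(Z)
  if (length(sigma) == 1L) sigma <- rep(sigma, B)
  if (any(sigma <= 0)) stop_("sigma must be positive")
  Zs <- sweep(Z, 2L, sigma, "/")
  Ts <- sweep(traj, 2L, sigma, "/")
  const <- -0.5 * B * log(2 * pi) - sum(log(sigma))
  sse <- matrix(rowSums(Zs^2), nrow(Z), nrow(traj)) +
    matrix(rowSums(Ts^2), nrow(Z), nrow(traj), byrow = TRUE) -
    2 * tcrossprod(Zs, Ts)
  const - 0.5 * pmax(sse, 0)
}

#' Subject log-likelihood at a fixed stage
#'
#' Sum over biomarkers of the log Gaussian density of the observed z-scores
#' around the stage-k expected trajectory, with per-biomarker noise scale.
#'
#' @param x numeric vector of direction-adjusted z-scores (one per biomarker).
#' @param seq a valid event sequence.
#' @param eventset an `event_set`.
#' @param stage integer in 0..S.
#' @param sigma positive noise scale, scalar or per-biomarker. Default 1:
#'   inputs are control-referenced z-scores.
#' @return Scalar log density.
#' @export
subject_loglik_at_stage <- function(x, seq, eventset, stage, sigma = 1) {
  if (stage < 0 || stage > eventset$S) stop_("stage must lie in 0..S")
  if (!all(is.finite(x))) stop_("x must be finite")
  traj <- expected_trajectory(seq, eventset)
  L <- stage_loglik_matrix(matrix(x, nrow = 1L), traj[stage + 1L, , drop = FALSE], sigma)
  as.numeric(L)
}

#' Stage-marginalized subject log-likelihood
#'
#' The likelihood of one subject under a single sequence, with the latent
#' stage integrated out under its discrete uniform prior:
#' (1/(S+1)) * sum_k exp(loglik at stage k), accumulated in log space.
#'
#' @inheritParams subject_loglik_at_stage
#' @param Z matrix of subjects x biomarkers z-scores (a vector is taken as
#'   one subject).
#' @return Numeric vector of per-subject log marginal likelihoods.
#' @export
subject_marginal_loglik <- function(Z, seq, eventset, sigma = 1) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  if (!all(is.finite(Z))) stop_("Z must be finite")
  traj <- expected_trajectory(seq, eventset)
  L <- stage_loglik_matrix(Z, traj, sigma)
  row_logsumexp(L) - log(eventset$S + 1)
}

#' Posterior over stages for one subject
#'
#' Normalized per-stage densities under the uniform stage prior.
#'
#' @inheritParams subject_marginal_loglik
#' @return A matrix of subjects x (S+1) stage probabilities; rows sum to 1.
#' @export
stage_posterior <- function(Z, seq, eventset, sigma = 1) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  traj <- expected_trajectory(seq, eventset)
  L <- stage_loglik_matrix(Z, traj, sigma)
  P <- exp(L - row_logsumexp(L))
  P <- P / rowSums(P)
  colnames(P) <- paste0("stage", 0:eventset$S)
  stopifnot(all(abs(rowSums(P) - 1) < 1e-12))
  P
}

#' Dataset log-likelihood under a progression model
#'
#' Sum over subjects of the log mixture likelihood
#' log sum_c f_c * subject_marginal_lik(x, seq_c).
#'
#' @param Z subjects x biomarkers z-score matrix.
#' @param model a `progression_model` (see [fit_sustain()]).
#' @return Scalar log-likelihood.
#' @export
dataset_loglik <- function(Z, model) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  if (nrow(Z) == 0L) stop_("empty dataset")
  stopifnot(inherits(model, "progression_model"))
  if (abs(sum(model$fractions) - 1) > 1e-8) stop_("fractions must sum to 1")
  ll <- per_subtype_logliks(Z, model)
  sum(row_logsumexp(sweep(ll, 2L, log(model$fractions), "+")))
}

# n x c matrix of per-subtype marginal log-likelihoods
per_subtype_logliks <- function(Z, model) {
  vapply(model$sequences,
         function(s) subject_marginal_loglik(Z, s, model$eventset, model$sigma),
         numeric(nrow(Z)))
}
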