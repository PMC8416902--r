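#' Fitting mixtures of linear z-score models
#'
#' The subtypes-progression model is a mixture of c event sequences with
#' mixing fractions f. Fitting alternates greedy coordinate ascent over each
#' sequence with EM updates of the fractions; the number of subtypes is grown
#' hierarchically by splitting one subtype of the c-subtype solution and is
#' chosen externally by cross-validation (see [cvic()]).
#'
#' @name subtype_inference
NULL

new_progression_model <- function(sequences, fractions, sigma, eventset,
                                  loglik = NA_real_, em_trace = numeric(0)) {
  stopifnot(length(sequences) == length(fractions))
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions <= 0)) {
    stop_("fractions must be positive and sum to 1")
  }
  for (s in sequences) validate_sequence(s, eventset)
  structure(list(sequences = sequences, fractions = fractions, sigma = sigma,
                 eventset = eventset, loglik = loglik, em_trace = em_trace),
            class = "progression_model")
}

#' @export
print.progression_model <- function(x, ...) {
  cat("Subtypes-progression model:", length(x$sequences), "subtype(s),",
      x$eventset$S, "events\n")
  cat("  fractions:", paste(sprintf("%.3f", x$fractions), collapse = ", "), "\n")
  cat("  log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' Greedy coordinate ascent over event orderings
#'
#' Repeatedly removes one event from the sequence and reinserts it at the
#' position maximizing the weighted stage-marginalized log-likelihood,
#' sweeping all events until a full sweep changes nothing. Only positions
#' preserving within-biomarker z order are considered; exact ties go to the
#' lowest position.
#'
#' @param Z z-score matrix.
#' @param weights per-subject non-negative responsibilities (not all zero).
#' @param init valid starting sequence.
#' @param eventset an `event_set`.
#' @param sigma noise scale (scalar or per-biomarker), default 1.
#' @param max_sweeps safety cap on full sweeps.
#' @return A list with `sequence` and its weighted `loglik`
#'   (>= the init's, up to numerical tolerance).
#' @export
optimize_sequence <- function(Z, weights, init, eventset, sigma = 1,
                              max_sweeps = 20) {
  validate_sequence(init, eventset)
  if (any(weights < 0)) stop_("weights must be non-negative")
  if (sum(weights) <= 0) stop_("degenerate responsibilities: all weights zero")
  ctx <- loglik_ctx(Z, eventset, sigma)
  ctx_optimize_sequence(ctx, weights, init, max_sweeps = max_sweeps)
}

# E-step on a context: n x c responsibilities and the dataset log-likelihood.
ctx_responsibilities <- function(ctx, sequences, fractions) {
  ll <- vapply(sequences, function(s) ctx_marginal_loglik(ctx, s),
               numeric(ctx$n))
  if (ctx$n == 1L) ll <- matrix(ll, nrow = 1L)
  lw <- sweep(ll, 2L, log(fractions), "+")
  tot <- row_logsumexp(lw)
  list(R = exp(lw - tot), loglik = sum(tot))
}

responsibilities <- function(Z, model) {
  ctx <- loglik_ctx(Z, model$eventset, model$sigma)
  ctx_responsibilities(ctx, model$sequences, model$fractions)
}

# Alternating EM: responsibilities and fractions, then one greedy relocation
# sweep per sequence (partial M-step; the update is a monotone generalized EM).
em_polish <- function(ctx, model, tol = 1e-6, max_iter = 100,
                      min_fraction = 1e-6, m_sweeps = 1) {
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    e <- ctx_responsibilities(ctx, model$sequences, model$fractions)
    trace <- c(trace, e$loglik)
    frac <- pmax(colMeans(e$R), min_fraction)
    frac <- frac / sum(frac)
    seqs <- model$sequences
    for (k in seq_along(seqs)) {
      seqs[[k]] <- ctx_optimize_sequence(ctx, e$R[, k], seqs[[k]],
                                         max_sweeps = m_sweeps)$sequence
    }
    model <- new_progression_model(seqs, frac, model$sigma, model$eventset)
    if (it > 1L && trace[it] - trace[it - 1L] < tol) break
  }
  e <- ctx_responsibilities(ctx, model$sequences, model$fractions)
  model$loglik <- e$loglik
  model$em_trace <- c(trace, e$loglik)
  # EM monotonicity, asserted on every fit (numerical tolerance only)
  stopifnot(all(diff(model$em_trace) >= -1e-6))
  model
}

#' Fit a subtypes-progression model
#'
#' For `c = 1`, the best of `n_starts` greedy ascents from random valid
#' sequences. For `c > 1`, the (c-1)-subtype model is fitted first and grown
#' by [split_and_fit()]; the training log-likelihood is therefore
#' non-decreasing in c.
#'
#' @param Z z-score matrix (subjects x biomarkers).
#' @param eventset an `event_set` matching the columns of `Z`.
#' @param c number of subtypes (>= 1, <= number of subjects).
#' @param n_starts random restarts for the single-subtype greedy fit (and,
#'   halved, for each split refit).
#' @param seed integer seed; all randomness derives from it.
#' @param sigma per-biomarker noise scale; default 1 (z-scale data).
#' @param tol,max_iter EM convergence controls.
#' @param n_partitions random split partitions per subtype (see
#'   [split_and_fit()]).
#' @return A `progression_model`. Use [fit_sustain_path()] to keep the whole
#'   1..c hierarchy.
#' @export
fit_sustain <- function(Z, eventset, c = 1, n_starts = 25, seed = 1,
                        sigma = 1, tol = 1e-6, max_iter = 100,
                        n_partitions = 5) {
  path <- fit_sustain_path(Z, eventset, c_max = c, n_starts = n_starts,
                           seed = seed, sigma = sigma, tol = tol,
                           max_iter = max_iter, n_partitions = n_partitions)
  path[[c]]
}

#' @rdname fit_sustain
#' @param c_max largest number of subtypes to fit.
#' @return `fit_sustain_path()`: a list of `progression_model`s for
#'   c = 1 .. c_max.
#' @export
fit_sustain_path <- function(Z, eventset, c_max = 1, n_starts = 25, seed = 1,
                             sigma = 1, tol = 1e-6, max_iter = 100,
                             n_partitions = 5) {
  Z <- as.matrix(Z)
  if (c_max < 1) stop_("c must be >= 1")
  if (c_max > nrow(Z)) stop_("more subtypes than subjects")
  ctx <- loglik_ctx(Z, eventset, sigma)
  best <- ctx_multistart_greedy(ctx, rep(1, nrow(Z)), eventset, n_starts, seed)
  m1 <- new_progression_model(list(best$sequence), 1, sigma, eventset,
                              loglik = best$loglik,
                              em_trace = best$loglik)
  path <- list(m1)
  cc <- 1L
  while (cc < c_max) {
    path[[cc + 1L]] <- split_and_fit(Z, path[[cc]],
                                     seed = child_seed(seed, 7000L + cc),
                                     n_starts = n_starts,
                                     n_partitions = n_partitions,
                                     tol = tol, max_iter = max_iter,
                                     ctx = ctx)
    cc <- cc + 1L
  }
  path
}

#' Grow a model from c to c+1 subtypes
#'
#' Each existing subtype is tentatively split: its (hard-assigned) subjects
#' are partitioned into two random halves, each half is refit by multistart
#' greedy ascent, and the resulting (c+1)-subtype candidate is polished by a
#' short EM on the full data. Because greedy ascent over orderings is
#' multimodal, `n_partitions` independent random partitions are tried per
#' subtype; the overall best candidate is then fully EM-polished. Subtypes
#' with fewer than 2 assigned subjects cannot be split and are skipped with
#' a message.
#'
#' @param Z z-score matrix.
#' @param model a fitted `progression_model` with c subtypes.
#' @param seed integer seed for the random halves and restarts.
#' @param n_starts greedy restarts per half.
#' @param n_partitions random partitions tried per subtype.
#' @param tol,max_iter EM controls for the final polish.
#' @param ctx internal likelihood context (precomputed by callers).
#' @return A `progression_model` with c+1 subtypes.
#' @export
split_and_fit <- function(Z, model, seed = 1, n_starts = 12, n_partitions = 5,
                          tol = 1e-6, max_iter = 100, ctx = NULL) {
  Z <- as.matrix(Z)
  if (is.null(ctx)) ctx <- loglik_ctx(Z, model$eventset, model$sigma)
  e <- ctx_responsibilities(ctx, model$sequences, model$fractions)
  hard <- max.col(e$R, ties.method = "first")
  best <- NULL
  half_starts <- max(3L, ceiling(n_starts / 2))
  for (k in seq_along(model$sequences)) {
    members <- which(hard == k)
    if (length(members) < 2L) {
      message("subtype ", k, " has <2 assigned subjects; split skipped")
      next
    }
    for (p in seq_len(n_partitions)) {
      halves <- with_seed_(child_seed(seed, 97L * k + p), {
        perm <- sample(members)
        split(perm, rep(1:2, length.out = length(perm)))
      })
      new_seqs <- lapply(seq_along(halves), function(h) {
        idx <- halves[[h]]
        hctx <- loglik_ctx(Z[idx, , drop = FALSE], model$eventset, model$sigma)
        ctx_multistart_greedy(hctx, rep(1, length(idx)), model$eventset,
                              half_starts,
                              child_seed(seed, 997L * k + 10L * p + h),
                              extra_inits = list(model$sequences[[k]]))$sequence
      })
      seqs <- c(model$sequences[-k], new_seqs)
      frac0 <- model$fractions[-k]
      frac <- c(frac0, rep(model$fractions[k] / 2, 2))
      cand <- new_progression_model(seqs, frac / sum(frac), model$sigma,
                                    model$eventset)
      cand <- em_polish(ctx, cand, tol = tol, max_iter = 8L)
      if (is.null(best) || cand$loglik > best$loglik) best <- cand
    }
  }
  if (is.null(best)) stop_("no subtype could be split (all have <2 subjects)")
  em_polish(ctx, best, tol = tol, max_iter = max_iter)
}

#' MCMC posterior over event orderings
#'
#' Metropolis-Hastings per subtype, holding fractions and responsibilities
#' fixed at the fitted model's values. The proposal mixes two symmetric
#' moves: relocating one uniformly chosen event to a uniformly chosen
#' position (global), and transposing a uniformly chosen adjacent pair
#' (local; global relocations alone are almost never accepted once the
#' posterior concentrates, freezing the chain). Proposals breaking
#' within-biomarker z order are rejected before evaluation; acceptance is by
#' likelihood ratio alone. The positional variance matrix (event x position
#' visit frequencies) summarizes uncertainty in each subtype's ordering.
#'
#' @param Z z-score matrix.
#' @param model fitted `progression_model`.
#' @param n_iter,burn_in iteration counts (`n_iter > burn_in`).
#' @param seed integer seed.
#' @return A `sequence_posterior`: per subtype, the retained samples (matrix
#'   of iterations x S), the positional variance matrix (S x S, rows sum to
#'   1), the acceptance rate, and the maximum-likelihood sampled sequence.
#' @export
mcmc_posterior <- function(Z, model, n_iter = 10000, burn_in = 1000, seed = 1) {
  Z <- as.matrix(Z)
  if (n_iter <= burn_in) stop_("n_iter must exceed burn_in")
  es <- model$eventset
  S <- es$S
  ctx <- loglik_ctx(Z, es, model$sigma)
  e <- ctx_responsibilities(ctx, model$sequences, model$fractions)
  out <- vector("list", length(model$sequences))
  for (k in seq_along(model$sequences)) {
    w <- if (length(model$sequences) == 1L) rep(1, nrow(Z)) else e$R[, k]
    out[[k]] <- with_seed_(child_seed(seed, k), {
      cur <- model$sequences[[k]]
      cur_ll <- ctx_weighted_loglik(ctx, cur, w)
      keep <- matrix(NA_integer_, n_iter - burn_in, S)
      keep_ll <- numeric(n_iter - burn_in)
      acc <- 0L
      for (it in seq_len(n_iter)) {
        if (stats::runif(1) < 0.5) {          # global relocation
          ev <- sample.int(S, 1L)
          to <- sample.int(S, 1L)
          from <- match(ev, cur)
          cand <- if (to == from) NULL else append(cur[-from], ev,
                                                   after = to - 1L)
          moved <- ev
        } else {                              # local adjacent transposition
          p <- sample.int(S - 1L, 1L)
          cand <- cur
          cand[c(p, p + 1L)] <- cand[c(p + 1L, p)]
          moved <- cur[p]
        }
        if (!is.null(cand) &&
            ctx_move_valid(cand, ctx$pre, ctx$pre$bm_id[moved])) {
          cand_ll <- ctx_weighted_loglik(ctx, cand, w)
          if (log(stats::runif(1)) < cand_ll - cur_ll) {
            cur <- cand
            cur_ll <- cand_ll
            acc <- acc + 1L
          }
        }
        if (it > burn_in) {
          keep[it - burn_in, ] <- cur
          keep_ll[it - burn_in] <- cur_ll
        }
      }
      pv <- positional_variance(keep, S)
      list(samples = keep, loglik = keep_ll, positional_variance = pv,
           acceptance_rate = acc / n_iter,
           ml_sequence = keep[which.max(keep_ll), ])
    })
  }
  structure(list(subtypes = out, n_iter = n_iter, burn_in = burn_in),
            class = "sequence_posterior")
}

# event x position frequency matrix from a sample matrix (iters x S)
positional_variance <- function(samples, S) {
  pv <- matrix(0, S, S, dimnames = list(event = NULL, position = NULL))
  for (i in seq_len(nrow(samples))) {
    pv[cbind(samples[i, ], seq_len(S))] <- pv[cbind(samples[i, ], seq_len(S))] + 1
  }
  pv <- pv / nrow(samples)
  stopifnot(all(abs(rowSums(pv) - 1) < 1e-9))
  pv
}
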