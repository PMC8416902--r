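# Internal likelihood engine. The fitting loops evaluate the stage-
# marginalized likelihood thousands of times; these helpers precompute
# everything that does not depend on the candidate sequence.

# Per-eventset precomputation: integer biomarker ids and event groups.
es_precomp <- function(eventset) {
  bm_names <- unique(eventset$events$biomarker)
  bm_id <- match(eventset$events$biomarker, bm_names)
  groups <- lapply(seq_along(bm_names), function(j) which(bm_id == j))
  list(S = eventset$S, B = length(bm_names), bm_id = as.integer(bm_id),
       z = as.numeric(eventset$events$z),
       groups = groups,
       max_z = as.numeric(unname(eventset$max_z[bm_names])))
}

# Likelihood context: data scaled by sigma, squared norms, constants.
loglik_ctx <- function(Z, eventset, sigma) {
  Z <- as.matrix(Z)
  B <- ncol(Z)
  if (length(sigma) == 1L) sigma <- rep(sigma, B)
  if (length(sigma) != B || any(sigma <= 0)) stop_("sigma must be positive, scalar or per-biomarker")
  if (any(!is.finite(Z))) stop_("Z must be finite")
  inv <- 1 / sigma
  Zs <- sweep(Z, 2L, inv, "*")
  const <- -0.5 * B * log(2 * pi) - sum(log(sigma))
  list(Z = Z, Zs = Zs, zz = rowSums(Zs^2), inv_sigma = inv,
       unit_sigma = all(sigma == 1),
       const = const,
       cz = const - 0.5 * rowSums(Zs^2),
       n = nrow(Z), pre = es_precomp(eventset),
       log_stages = log(eventset$S + 1))
}

# Per-subject stage-marginalized log-likelihood for one sequence (C++ core).
ctx_marginal_loglik <- function(ctx, seq) {
  seq_marginal_loglik_cpp(ctx$Zs, ctx$cz, as.integer(seq), ctx$pre$bm_id,
                          ctx$pre$z, ctx$pre$max_z, ctx$inv_sigma,
                          ctx$log_stages)
}

ctx_weighted_loglik <- function(ctx, seq, weights) {
  seq_weighted_loglik_cpp(ctx$Zs, ctx$cz, weights, as.integer(seq),
                          ctx$pre$bm_id, ctx$pre$z, ctx$pre$max_z,
                          ctx$inv_sigma, ctx$log_stages)
}

# Validity of a full sequence, checking only one biomarker's events
# (sufficient after relocating a single event of that biomarker).
ctx_move_valid <- function(cand, pre, bm) {
  idx <- pre$groups[[bm]]
  if (length(idx) == 1L) return(TRUE)
  !is.unsorted(match(idx, cand), strictly = TRUE)
}

# Greedy coordinate ascent on a prebuilt context (see optimize_sequence).
ctx_optimize_sequence <- function(ctx, weights, init, max_sweeps = 20) {
  S <- ctx$pre$S
  cur <- init
  cur_ll <- ctx_weighted_loglik(ctx, cur, weights)
  for (sweep_i in seq_len(max_sweeps)) {
    changed <- FALSE
    for (ev in seq_len(S)) {
      from <- match(ev, cur)
      base <- cur[-from]
      bm <- ctx$pre$bm_id[ev]
      best_ll <- cur_ll
      best_seq <- NULL
      for (to in seq_len(S)) {
        if (to == from) next
        cand <- append(base, ev, after = to - 1L)
        if (!ctx_move_valid(cand, ctx$pre, bm)) next
        ll <- ctx_weighted_loglik(ctx, cand, weights)
        if (ll > best_ll + 1e-12) {
          best_ll <- ll
          best_seq <- cand
        }
      }
      if (!is.null(best_seq)) {
        cur <- best_seq
        cur_ll <- best_ll
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(sequence = cur, loglik = cur_ll)
}

# Multistart greedy ascent with uniform random initial sequences.
ctx_multistart_greedy <- function(ctx, weights, eventset, n_starts, seed,
                                  extra_inits = list()) {
  best <- NULL
  inits <- c(extra_inits, lapply(seq_len(n_starts), function(s) {
    with_seed_(child_seed(seed, s), random_sequence(eventset))
  }))
  for (init in inits) {
    res <- ctx_optimize_sequence(ctx, weights, init)
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  best
}
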