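# Shared fixtures and independent oracles for the test suite.

# A small panel of increasing biomarkers with identical candidate events.
make_defs <- function(n_bm, events = c(1, 2), prefix = "bm") {
  biomarker_defs(paste0(prefix, seq_len(n_bm)), 1,
                 rep(list(events), n_bm))
}

# The well-separated two-subtype study design used for recovery experiments:
# ten single-event biomarkers (z = 3), reversed orderings, equal fractions.
separated_design <- function() {
  defs <- biomarker_defs(paste0("bm", 1:10), 1, rep(list(3), 10))
  es <- event_set_from_defs(defs)
  list(defs = defs, eventset = es, seq_a = 1:10, seq_b = 10:1)
}

separated_cohort <- function(seed, n_subjects = 600, fractions = c(0.5, 0.5),
                             noise_sd = 1) {
  d <- separated_design()
  subtypes <- if (length(fractions) == 1L) {
    list(subtype_spec(d$seq_a, 1))
  } else {
    list(subtype_spec(d$seq_a, fractions[1]), subtype_spec(d$seq_b, fractions[2]))
  }
  cfg <- cohort_config(n_subjects = n_subjects, n_controls = 100,
                       defs = d$defs, eventset = d$eventset,
                       subtypes = subtypes, noise_sd = noise_sd, seed = seed)
  cohort <- generate_patient_cohort(cfg)
  stats <- compute_control_stats(generate_control_group(cfg))
  Z <- to_zscores(cohort$raw_values, stats, d$defs)
  list(design = d, config = cfg, cohort = cohort, Z = Z)
}

# Kendall rank correlation between two event sequences (via event positions).
kendall_tau <- function(seq1, seq2) {
  stats::cor(match(seq_along(seq1), seq1), match(seq_along(seq2), seq2),
             method = "kendall")
}

# Best worst-case tau after matching fitted subtypes to truth subtypes.
matched_tau <- function(truth_seqs, fitted_seqs) {
  stopifnot(length(truth_seqs) == 2L, length(fitted_seqs) == 2L)
  direct <- min(kendall_tau(truth_seqs[[1]], fitted_seqs[[1]]),
                kendall_tau(truth_seqs[[2]], fitted_seqs[[2]]))
  crossed <- min(kendall_tau(truth_seqs[[1]], fitted_seqs[[2]]),
                 kendall_tau(truth_seqs[[2]], fitted_seqs[[1]]))
  max(direct, crossed)
}

# --- Independent brute-force oracles -------------------------------------
# These re-derive the model quantities from first principles (explicit
# per-stage Gaussian density products via dnorm, plain sums), avoiding the
# package's log-space engine.

oracle_stage_density <- function(x, seq, eventset, stage, sigma = 1) {
  traj <- expected_trajectory(seq, eventset)
  prod(stats::dnorm(x, mean = traj[stage + 1L, ], sd = sigma))
}

oracle_marginal_lik <- function(x, seq, eventset, sigma = 1) {
  S <- eventset$S
  mean(vapply(0:S, function(k) oracle_stage_density(x, seq, eventset, k, sigma),
              numeric(1)))
}

oracle_stage_posterior <- function(x, seq, eventset, sigma = 1) {
  S <- eventset$S
  d <- vapply(0:S, function(k) oracle_stage_density(x, seq, eventset, k, sigma),
              numeric(1))
  d / sum(d)
}

oracle_dataset_loglik <- function(Z, sequences, fractions, eventset, sigma = 1) {
  sum(vapply(seq_len(nrow(Z)), function(j) {
    log(sum(vapply(seq_along(sequences), function(c) {
      fractions[c] * oracle_marginal_lik(Z[j, ], sequences[[c]], eventset, sigma)
    }, numeric(1))))
  }, numeric(1)))
}

# All valid sequences of an event set (exhaustive; small S only).
all_valid_sequences <- function(eventset) {
  S <- eventset$S
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  Filter(function(s) sequence_is_valid(s, eventset), perms(seq_len(S)))
}

# A random z-score matrix for a given event set's biomarker count.
random_z <- function(n, eventset, seed, scale = 2) {
  B <- length(unique(eventset$events$biomarker))
  withr::with_seed(seed, {
    Z <- matrix(stats::rnorm(n * B, mean = 1, sd = scale), n, B)
    colnames(Z) <- unique(eventset$events$biomarker)
    Z
  })
}
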