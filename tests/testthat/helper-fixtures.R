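# Shared fixture builders. Everything is constructed in code; tiny windows
# keep exhaustive enumeration oracles tractable.

# A fully specified model on a short window (margin 2, motif 2 -> window 4
# positions per strand) with K dimer modes, small enough that totals can be
# enumerated. NB success probabilities are kept small so the truncated-tail
# mass beyond `max_total` is far below the oracles' tolerance.
tiny_params <- function(K = 0L, L = 2L, margin = 2L, bin_width = 2L,
                        p = 0.05, r = 1) {
  n_states <- K + 2L
  bound_bng <- make_binning(L, margin, bin_width, "bound")
  B <- length(bound_bng$fwd$sizes)
  states <- vector("list", n_states)
  states[[1]] <- list(fwd = list(p = p, r = r, lambda = 1),
                      rev = list(p = p, r = r, lambda = 1))
  for (k in seq_len(n_states - 1L)) {
    lam_f <- (seq_len(B) + k) / sum(seq_len(B) + k)
    lam_r <- rev(lam_f)
    states[[k + 1L]] <- list(fwd = list(p = p * (1 + k), r = r + k, lambda = lam_f),
                             rev = list(p = p * (1 + k), r = r + k, lambda = lam_r))
  }
  feature_names <- c("motif_score", if (K > 0) paste0("partner_score_", seq_len(K)))
  J <- length(feature_names)
  gamma <- matrix(0, J, K + 1L)
  gamma[1, ] <- 1
  if (K > 0) for (k in seq_len(K)) gamma[1L + k, 1L + k] <- 1
  beta <- matrix(0, J, K + 1L)
  beta[1, ] <- 0.8
  if (K > 0) for (k in seq_len(K)) beta[1L + k, 1L + k] <- 0.5
  modes <- binding_mode_spec(feature_names, K = K, gamma = gamma,
                             partner_features = if (K > 0) feature_names[-1])
  params <- footmix:::new_model_params(
    K = K, L = L, margin = margin, bin_width = bin_width, delta = 0.5,
    prior = list(beta0 = c(0.2, rep(-0.5, K)), beta = beta * gamma),
    gamma = modes$gamma, states = states)
  params$modes <- modes
  params
}

# Wrap raw fwd/rev count matrices as a CutMatrixPair.
as_cut_matrices <- function(fwd, rev, margin, L,
                            ids = sprintf("s%d", seq_len(nrow(fwd)))) {
  footmix:::new_cut_matrix_pair(fwd, rev, margin, L, ids)
}

# A MotifInstanceSet with the given feature matrix on a toy contig, windows
# well inside the contig and non-overlapping.
toy_sites <- function(features, L = 2L, margin = 2L, strand = NULL) {
  n <- nrow(features)
  start <- 100L + (seq_len(n) - 1L) * (2L * margin + L + 10L)
  if (is.null(strand)) strand <- rep("+", n)
  motif_instance_set(rep("chrT", n), start, start + L, strand,
                     sprintf("s%d", seq_len(n)), features)
}

# All weak compositions of total s over w cells (each row one composition).
compositions <- function(s, w) {
  if (w == 1L) return(matrix(s, 1L))
  out <- NULL
  for (first in 0:s) {
    rest <- compositions(s - first, w - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# Independent per-row likelihood oracle: straight dnbinom x multinomial
# density, no log-space tricks, no shared code with the implementation.
oracle_row_lik <- function(row, p, r, lam_pos) {
  s <- sum(row)
  nb <- dnbinom(s, size = r, prob = 1 - p)
  multi <- exp(lgamma(s + 1) - sum(lgamma(row + 1))) * prod(lam_pos^row)
  nb * multi
}

# Per-position coefficients straight from a bin-mass vector, independent of
# expand_lambda: mass / bin size per position, renormalized.
oracle_expand <- function(lambda, scheme) {
  v <- lambda[scheme$assignment] / scheme$sizes[scheme$assignment]
  v / sum(v)
}

# Brute-force posterior over states for one instance by direct Bayes.
oracle_posterior <- function(fwd_row, rev_row, eta_row, params) {
  n_states <- params$K + 2L
  w <- numeric(n_states)
  prior <- c(1, exp(eta_row))
  for (k in seq_len(n_states)) {
    st <- params$states[[k]]
    bng <- params$binning[[k]]
    w[k] <- prior[k] *
      oracle_row_lik(fwd_row, st$fwd$p, st$fwd$r,
                     oracle_expand(st$fwd$lambda, bng$fwd)) *
      oracle_row_lik(rev_row, st$rev$p, st$rev$r,
                     oracle_expand(st$rev$lambda, bng$rev))
  }
  w / sum(w)
}

# Simulated dataset ready for fitting: sites aligned to clipped matrices.
simulated_fit_inputs <- function(model, n, seed) {
  sim <- simulate_dataset(model, n = n, seed = seed)
  mat <- clip_counts(sim$matrices)
  list(sim = sim, sites = sim$sites, matrices = mat, modes = sim$modes)
}
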