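# Expectation-Maximization fitting: initialization from total cut counts,
# shrinkage M-step for the spatial profiles, quasi-Newton M-steps for the
# negative binomial size and the prior coefficients, and the convergence
# rule on the maximum posterior change.

#' Configuration of the EM fit
#'
#' @param delta shrinkage mixing parameter in `[0, 1]` for the spatial
#'   profiles (default 0.5; 1 = pure MLE, 0 = uniform).
#' @param tol convergence threshold on the maximum absolute change of any
#'   posterior entry between iterations (default 0.001).
#' @param max_iter iteration cap (default 100).
#' @param init_odds_high,init_odds_low prior odds assigned at
#'   initialization (defaults 100 and 0.01).
#' @param init_top_fraction fraction of instances given high initial odds
#'   (default 0.10).
#' @param seed integer seed for the initialization tie-break shuffle.
#' @param ridge L2 penalty on non-intercept prior coefficients (default
#'   1e-6), guarding against separability.
#' @param optim_maxit evaluation budget per quasi-Newton M-step (default
#'   200).
#' @return A `FitConfig` list.
#' @export
fit_config <- function(delta = 0.5, tol = 0.001, max_iter = 100L,
                       init_odds_high = 100, init_odds_low = 0.01,
                       init_top_fraction = 0.10, seed = 1L,
                       ridge = 1e-6, optim_maxit = 200L) {
  stopifnot(delta >= 0, delta <= 1, tol > 0, max_iter >= 1,
            init_top_fraction > 0, init_top_fraction < 1)
  structure(list(delta = delta, tol = tol, max_iter = as.integer(max_iter),
                 init_odds_high = init_odds_high, init_odds_low = init_odds_low,
                 init_top_fraction = init_top_fraction, seed = as.integer(seed),
                 ridge = ridge, optim_maxit = as.integer(optim_maxit)),
            class = "FitConfig")
}

#' Initial prior odds from total cut counts (and partner motif scores)
#'
#' The monomer mode receives odds `init_odds_high` for the top
#' `init_top_fraction` of instances by total cut count (both strands
#' pooled) and `init_odds_low` otherwise. A dimer mode receives high odds
#' only for instances in the top fraction by total cuts AND in the top
#' fraction by its designated partner-motif-score feature. Ties at either
#' cutoff are broken by instance order after a seeded shuffle, so exactly
#' `floor(init_top_fraction * n)` instances enter each top set.
#'
#' @param sites a [motif_instance_set()] (row order matching `matrices`).
#' @param matrices a clipped `CutMatrixPair`.
#' @param modes a [binding_mode_spec()].
#' @param config a [fit_config()].
#' @return Matrix `n x (K + 1)` of initial prior odds against unbound.
#' @export
initialize_prior_odds <- function(sites, matrices, modes, config = fit_config()) {
  n <- nrow(matrices$fwd)
  totals <- rowSums(matrices$fwd) + rowSums(matrices$rev)
  n_top <- max(1L, floor(config$init_top_fraction * n))
  top_set <- function(x) {
    perm <- sample.int(n)  # seeded shuffle; stable order() breaks ties by it
    ord <- perm[order(-x[perm])]
    seq_len(n) %in% ord[seq_len(n_top)]
  }
  set.seed(config$seed)
  top_cuts <- top_set(totals)
  odds <- matrix(config$init_odds_low, n, modes$K + 1L,
                 dimnames = list(NULL, modes$mode_names))
  odds[top_cuts, 1] <- config$init_odds_high
  if (modes$K > 0) {
    for (k in seq_len(modes$K)) {
      pf <- modes$partner_features[k]
      if (is.null(pf) || !pf %in% colnames(sites$features))
        stopf("dimer mode %d has no designated partner feature", k)
      top_partner <- top_set(sites$features[, pf])
      odds[top_cuts & top_partner, k + 1L] <- config$init_odds_high
    }
  }
  odds
}

# ---------------------------------------------------------------------------
# M-steps

# Indicator matrix positions x bins for one strand scheme.
bin_indicator <- function(scheme) {
  B <- length(scheme$sizes)
  W <- length(scheme$assignment)
  ind <- matrix(0, W, B)
  ind[cbind(seq_len(W), scheme$assignment)] <- 1
  ind
}

#' Shrinkage M-step for the per-bin spatial masses
#'
#' The weighted maximum-likelihood bin masses
#' `lambda_hat_b = sum_i w_i c_ib / sum_i w_i S_i` are mixed with the
#' size-proportional (per-position-uniform) target:
#' `delta * lambda_hat_b + (1 - delta) * |J_b| / sum_b |J_b|`. With all
#' weighted counts zero the uniform target is returned.
#'
#' @param matrices a `CutMatrixPair`.
#' @param binning a bound-mode [make_binning()] scheme.
#' @param weights per-instance posterior weights for this state, in
#'   `[0, 1]`.
#' @param delta shrinkage mixing parameter.
#' @return List with per-strand bin masses `fwd` and `rev`, each summing
#'   to 1.
#' @export
m_step_multinomial <- function(matrices, binning, weights, delta) {
  stopifnot(all(weights >= 0), all(weights <= 1))
  one_strand <- function(M, scheme) {
    target <- scheme$sizes / sum(scheme$sizes)
    cb <- as.numeric(crossprod(M %*% bin_indicator(scheme), weights))
    tot <- sum(cb)
    if (tot == 0) return(target)
    delta * (cb / tot) + (1 - delta) * target
  }
  list(fwd = one_strand(matrices$fwd, binning$fwd),
       rev = one_strand(matrices$rev, binning$rev))
}

#' Weighted negative binomial M-step
#'
#' Maximizes `sum_i w_i log NB(S_i; r, p)` by BFGS over `log r` on the
#' profile likelihood, with the closed-form
#' `p_hat(r) = S_bar / (S_bar + r)` where `S_bar` is the weighted mean
#' total; the fitted mean `p r / (1 - p)` therefore equals `S_bar`
#' exactly. Warm-started from the previous estimates.
#'
#' @param totals per-instance total counts `S_i`.
#' @param weights non-negative per-instance weights, `sum(weights) > 0`.
#' @param previous list with the warm-start values `p` and `r`.
#' @param maxit BFGS evaluation budget.
#' @return List with `p` and `r`.
#' @export
m_step_negbin <- function(totals, weights, previous, maxit = 200L) {
  wsum <- sum(weights)
  stopifnot(wsum > 0)
  sbar <- sum(weights * totals) / wsum
  if (sbar <= 0) {
    warnf("all weighted totals are zero; returning degenerate NB")
    return(list(p = 1e-8, r = previous$r))
  }
  negll <- function(logr) {
    r <- exp(logr)
    p <- sbar / (sbar + r)
    -sum(weights * log_nb(totals, r, p))
  }
  grad <- function(logr) {
    r <- exp(logr)
    p <- sbar / (sbar + r)
    # profile gradient: dp-terms vanish at p_hat(r)
    -r * sum(weights * (digamma(totals + r) - digamma(r) + log1p(-p)))
  }
  opt <- optim(log(previous$r), negll, grad, method = "BFGS",
               control = list(maxit = maxit))
  r <- exp(opt$par)
  list(p = sbar / (sbar + r), r = r)
}

#' Weighted multinomial-logistic M-step for the prior coefficients
#'
#' Maximizes the expected complete-data prior term
#' `sum_i sum_k w_ik log softmax_k(eta_i)` (pivot `eta_0 = 0`,
#' gamma-masked coefficients fixed at zero) minus an L2 ridge on the
#' non-intercept coefficients, by BFGS with analytic gradients.
#'
#' @param features numeric matrix, instances x features.
#' @param modes a [binding_mode_spec()] (supplies `gamma`).
#' @param weights matrix `n x (K + 2)` of posterior weights, rows summing
#'   to 1; column 1 is the unbound state.
#' @param previous optional warm-start list with `beta0` and `beta`.
#' @param ridge L2 penalty (default 1e-6).
#' @param maxit BFGS evaluation budget.
#' @return List with `beta0` (length `K + 1`) and `beta`
#'   (features x `K + 1`, exact zeros where masked), plus a logical
#'   `converged`.
#' @export
m_step_beta <- function(features, modes, weights, previous = NULL,
                        ridge = 1e-6, maxit = 200L) {
  features <- as.matrix(features)
  n <- nrow(features)
  gamma <- modes$gamma
  n_bound <- ncol(gamma)
  stopifnot(nrow(weights) == n, ncol(weights) == n_bound + 1L)
  if (max(abs(rowSums(weights) - 1)) > 1e-6)
    stopf("weight rows must sum to 1")
  active <- lapply(seq_len(n_bound), function(k) which(gamma[, k] == 1))
  n_par <- vapply(active, length, integer(1)) + 1L
  unpack <- function(theta) {
    beta0 <- numeric(n_bound)
    beta <- matrix(0, ncol(features), n_bound, dimnames = dimnames(gamma))
    off <- 0L
    for (k in seq_len(n_bound)) {
      beta0[k] <- theta[off + 1L]
      if (length(active[[k]]) > 0)
        beta[active[[k]], k] <- theta[off + 1L + seq_along(active[[k]])]
      off <- off + n_par[k]
    }
    list(beta0 = beta0, beta = beta)
  }
  pack <- function(beta0, beta) {
    unlist(lapply(seq_len(n_bound), function(k)
      c(beta0[k], beta[active[[k]], k])))
  }
  eta_of <- function(b) sweep(features %*% b$beta, 2L, b$beta0, `+`)
  negll <- function(theta) {
    b <- unpack(theta)
    eta <- eta_of(b)
    lse <- logsumexp_rows(cbind(0, eta))
    pen <- ridge / 2 * sum(b$beta^2)
    -(sum(weights[, -1, drop = FALSE] * eta) - sum(lse)) + pen
  }
  grad <- function(theta) {
    b <- unpack(theta)
    eta <- eta_of(b)
    P <- softmax_rows(cbind(0, eta))[, -1, drop = FALSE]
    D <- P - weights[, -1, drop = FALSE]   # n x n_bound
    g0 <- colSums(D)
    gB <- crossprod(features, D) + ridge * b$beta
    pack(g0, gB)
  }
  start <- if (!is.null(previous)) pack(previous$beta0, previous$beta)
           else numeric(sum(n_par))
  opt <- optim(start, negll, grad, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  if (opt$convergence != 0)
    warnf("prior coefficient M-step did not converge within budget; using best iterate")
  out <- unpack(opt$par)
  out$converged <- opt$convergence == 0
  out
}

# ---------------------------------------------------------------------------
# Full EM

# Observed-data log-likelihood (minus the ridge penalty) under params.
penalized_loglik <- function(eta, loglik, params, ridge) {
  lse_joint <- logsumexp_rows(cbind(0, eta) + loglik)
  lse_prior <- logsumexp_rows(cbind(0, eta))
  sum(lse_joint - lse_prior) - ridge / 2 * sum(params$prior$beta^2)
}

run_m_steps <- function(matrices, features, modes, weights, params, config) {
  n_states <- modes$K + 2L
  states <- params$states
  for (k in seq_len(n_states)) {
    if (k > 1L) {  # bound modes: refit spatial profile; unbound stays uniform
      lam <- m_step_multinomial(matrices, params$binning[[k]],
                                weights[, k], config$delta)
      states[[k]]$fwd$lambda <- lam$fwd
      states[[k]]$rev$lambda <- lam$rev
    }
    for (s in c("fwd", "rev")) {
      M <- if (s == "fwd") matrices$fwd else matrices$rev
      states[[k]][[s]][c("p", "r")] <-
        m_step_negbin(rowSums(M), weights[, k], states[[k]][[s]],
                      maxit = config$optim_maxit)
    }
  }
  b <- m_step_beta(features, modes, weights, previous = params$prior,
                   ridge = config$ridge, maxit = config$optim_maxit)
  new_model_params(K = modes$K, L = params$L, margin = params$margin,
                   bin_width = params$bin_width, delta = config$delta,
                   prior = list(beta0 = b$beta0, beta = b$beta),
                   gamma = modes$gamma, states = states)
}

#' Fit the footprint mixture model by Expectation-Maximization
#'
#' The sequence is: (1) assign initial prior odds from total cut counts
#' ([initialize_prior_odds()]); (2) fit the prior coefficients to the
#' resulting prior probabilities; (3) run a first Maximization step taking
#' the prior probabilities as the posterior weights; (4) iterate E-steps
#' ([posterior_probabilities()]) and M-steps (spatial profiles with
#' shrinkage, negative binomial per state and strand including the
#' unbound state, prior coefficients) until no posterior entry changes by
#' more than `tol`, or `max_iter` is reached. The unbound state's spatial
#' model stays fixed uniform throughout; its negative binomial is fitted
#' so the null can absorb the background sequencing depth.
#'
#' @param sites a [motif_instance_set()] whose row order matches
#'   `matrices` (see [subset_instances()]).
#' @param matrices a clipped `CutMatrixPair`.
#' @param modes a [binding_mode_spec()]; default: monomer-only model using
#'   all features.
#' @param config a [fit_config()].
#' @return A `FitResult` list: `params` (`ModelParams`), `posterior`
#'   (`PosteriorMatrix`), `n_iter`, `converged`, and `trajectory` (a data
#'   frame of per-iteration maximum posterior change and penalized
#'   observed-data log-likelihood).
#' @export
fit_footprint_model <- function(sites, matrices, modes = NULL,
                                config = fit_config()) {
  n <- nrow(matrices$fwd)
  if (n_instances(sites) != n)
    stopf("sites (%d) and matrices (%d) disagree in instance count; align them with subset_instances()",
          n_instances(sites), n)
  if (is.null(modes)) modes <- binding_mode_spec(colnames(sites$features))
  features <- sites$features
  L <- matrices$L; margin <- matrices$margin
  n_states <- modes$K + 2L

  odds <- initialize_prior_odds(sites, matrices, modes, config)
  w0 <- cbind(1, odds) / (1 + rowSums(odds))

  b <- m_step_beta(features, modes, w0, ridge = config$ridge,
                   maxit = config$optim_maxit)

  # seed chromatin parameters, then run the first M-step on the prior weights
  uniform_state <- function(B) {
    lam <- rep(1 / B, B)
    list(fwd = list(p = 0.5, r = 1, lambda = lam),
         rev = list(p = 0.5, r = 1, lambda = lam))
  }
  bound_binning <- make_binning(L, margin, mode = "bound")
  states0 <- c(list(uniform_state(1L)),
               rep(list(uniform_state(length(bound_binning$fwd$sizes))), n_states - 1L))
  params <- new_model_params(K = modes$K, L = L, margin = margin,
                             bin_width = bound_binning$bin_width,
                             delta = config$delta,
                             prior = list(beta0 = b$beta0, beta = b$beta),
                             gamma = modes$gamma, states = states0)
  params <- run_m_steps(matrices, features, modes, w0, params, config)

  prev_post <- w0
  converged <- FALSE
  n_iter <- 0L
  traj <- data.frame(iter = integer(), max_posterior_change = numeric(),
                     penalized_loglik = numeric())
  post <- NULL
  for (iter in seq_len(config$max_iter)) {
    eta <- prior_log_odds(features, params$prior, modes)
    ll <- chromatin_log_likelihood(matrices, params)
    post <- posterior_probabilities(eta, ll)
    dmax <- max(abs(post - prev_post))
    traj <- rbind(traj, data.frame(
      iter = iter, max_posterior_change = dmax,
      penalized_loglik = penalized_loglik(eta, ll, params, config$ridge)))
    n_iter <- iter
    if (dmax <= config$tol) { converged <- TRUE; break }
    params <- run_m_steps(matrices, features, modes, post, params, config)
    prev_post <- post
  }
  if (!converged) {
    # keep the returned posterior consistent with the returned parameters
    eta <- prior_log_odds(features, params$prior, modes)
    post <- posterior_probabilities(eta, chromatin_log_likelihood(matrices, params))
  }
  structure(list(params = params, posterior = post, n_iter = n_iter,
                 converged = converged, trajectory = traj),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult: %s after %d iteration(s); final max posterior change %.2g\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              tail(x$trajectory$max_posterior_change, 1)))
  invisible(x)
}
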