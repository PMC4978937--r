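# The mixture model proper: prior log-odds from sequence-derived features,
# the factorized negative binomial x multinomial chromatin likelihood, and
# their combination into per-state posteriors by Bayes' theorem.
#
# States are indexed k = 0..K+1: 0 = unbound, 1 = monomer, 2..K+1 =
# cooperative dimer modes. In R, state k lives at list/column index k + 1.

# ---------------------------------------------------------------------------
# Binding mode specification and prior coefficients

#' Specify the binding modes and their active prior features
#'
#' Defines the number of cooperative dimer modes `K` and, through the
#' binary indicator matrix `gamma`, which prior characteristic enters the
#' logistic prior of which bound mode. The monomer mode must not use
#' features that refer to a dimerization partner motif; partner features
#' are also what the EM initialization ranks dimer instances by.
#'
#' @param feature_names character vector naming the prior features
#'   (columns of the instance feature matrix).
#' @param K number of cooperative dimer modes (default 0: unbound +
#'   monomer only).
#' @param gamma binary matrix, features x bound modes (`K + 1` columns).
#'   Default: all features active in every mode.
#' @param partner_features character vector of length `K` naming, for each
#'   dimer mode, the feature holding the partner motif score (required when
#'   `K > 0`; used by the EM initialization).
#' @param mode_names optional names for the bound modes.
#' @return A `BindingModeSpec`.
#' @export
binding_mode_spec <- function(feature_names, K = 0L, gamma = NULL,
                              partner_features = NULL, mode_names = NULL) {
  J <- length(feature_names)
  n_bound <- K + 1L
  if (is.null(mode_names))
    mode_names <- c("monomer", if (K > 0) paste0("dimer_", seq_len(K)))
  if (is.null(gamma))
    gamma <- matrix(1, J, n_bound)
  gamma <- as.matrix(gamma)
  if (!all(gamma %in% c(0, 1)))
    stopf("gamma must be a binary indicator matrix")
  if (nrow(gamma) != J || ncol(gamma) != n_bound)
    stopf("gamma must be %d features x %d bound modes", J, n_bound)
  dimnames(gamma) <- list(feature_names, mode_names)
  if (K > 0) {
    if (is.null(partner_features) || length(partner_features) != K)
      stopf("partner_features must name one feature per dimer mode")
    if (!all(partner_features %in% feature_names))
      stopf("unknown partner feature(s)")
    if (any(gamma[partner_features, 1] != 0))
      stopf("partner-motif features must be inactive (gamma = 0) in the monomer mode")
  }
  structure(list(K = as.integer(K), gamma = gamma,
                 feature_names = feature_names, mode_names = mode_names,
                 partner_features = partner_features),
            class = "BindingModeSpec")
}

new_prior_coefficients <- function(beta0, beta, gamma) {
  beta <- as.matrix(beta)
  if (any(beta[gamma == 0] != 0))
    stopf("coefficients of gamma-masked features must be exactly 0")
  if (any(!is.finite(beta0)) || any(!is.finite(beta)))
    stopf("prior coefficients must be finite")
  list(beta0 = beta0, beta = beta)
}

#' Per-instance, per-mode prior log-odds against the unbound pivot
#'
#' Computes `eta[i, k] = beta0_k + sum_j beta[j, k] * gamma[j, k] * x[i, j]`
#' for each bound mode k, i.e. the log prior odds of mode k against the
#' unbound state, which carries implicit log-odds 0.
#'
#' @param features numeric matrix of prior characteristics, instances x
#'   features.
#' @param prior list with `beta0` (length `K + 1`) and `beta`
#'   (features x `K + 1`).
#' @param modes a [binding_mode_spec()].
#' @return Matrix `n x (K + 1)` of log prior odds.
#' @export
prior_log_odds <- function(features, prior, modes) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stopf("features must be finite")
  if (ncol(features) != nrow(modes$gamma))
    stopf("feature dimension does not match gamma")
  eff <- prior$beta * modes$gamma
  eta <- sweep(features %*% eff, 2L, prior$beta0, `+`)
  colnames(eta) <- modes$mode_names
  eta
}

# ---------------------------------------------------------------------------
# ModelParams

new_model_params <- function(K, L, margin, bin_width, delta, prior, gamma,
                             states) {
  stopifnot(length(states) == K + 2L)
  if (length(states[[1]]$fwd$lambda) != 1L || length(states[[1]]$rev$lambda) != 1L)
    stopf("the unbound state must have a single-bin (uniform) multinomial")
  binning <- c(list(make_binning(L, margin, bin_width, "unbound")),
               rep(list(make_binning(L, margin, bin_width, "bound")), K + 1L))
  structure(list(K = as.integer(K), L = as.integer(L),
                 margin = as.integer(margin), bin_width = as.integer(bin_width),
                 delta = delta, prior = prior, gamma = gamma,
                 states = states, binning = binning),
            class = "ModelParams")
}

#' @export
print.ModelParams <- function(x, ...) {
  cat(sprintf("ModelParams: K=%d dimer mode(s), motif %d bp, margin %d bp (bins of %d bp), delta=%g\n",
              x$K, x$L, x$margin, x$bin_width, x$delta))
  for (k in seq_along(x$states)) {
    st <- x$states[[k]]
    cat(sprintf("  state %d: NB mean fwd %.2f / rev %.2f\n", k - 1L,
                nb_mean(st$fwd$r, st$fwd$p), nb_mean(st$rev$r, st$rev$p)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Likelihood

#' Expand per-bin masses into per-position multinomial coefficients
#'
#' `lambda` holds one mass per bin (summing to 1 over bins); each bin's
#' mass is spread uniformly over its positions and the result renormalized,
#' so a size-proportional `lambda` expands to the exactly uniform
#' per-position model. This is the reading under which the shrinkage
#' target `(1 - delta) |J_b| / sum_b |J_b|` is the per-position-uniform
#' profile, consistent with the uniform unbound null.
#'
#' @param lambda numeric vector of bin masses (non-negative, not all zero).
#' @param scheme one strand of a [make_binning()] scheme (a list with
#'   `assignment` and `sizes`).
#' @return Numeric vector of per-position probabilities summing to 1.
#' @export
expand_lambda <- function(lambda, scheme) {
  if (length(lambda) != length(scheme$sizes))
    stopf("lambda has %d entries but the binning has %d bins",
          length(lambda), length(scheme$sizes))
  if (any(lambda < 0) || sum(lambda) == 0)
    stopf("lambda must be non-negative and not all zero")
  per_pos <- lambda[scheme$assignment] / scheme$sizes[scheme$assignment]
  per_pos / sum(per_pos)
}

#' Log-likelihood of cut-count rows under one strand's chromatin model
#'
#' Factorized likelihood: a negative binomial on the total count
#' `S = sum_j counts[j]` (convention `P(S = s) = C(s+r-1, s) (1-p)^r p^s`,
#' mean `p r / (1 - p)`) times a multinomial over the spatial distribution
#' of the `S` cuts with per-position coefficients expanded from `lambda`.
#' Computed with `lgamma` in log space, so clipped (non-integer) counts
#' and large totals are handled without overflow.
#'
#' @param counts numeric matrix (rows = instances) or a single row vector
#'   of per-position counts.
#' @param params list with `p`, `r`, `lambda` for this strand and state.
#' @param scheme one strand of a [make_binning()] scheme.
#' @return Numeric vector of per-row log-likelihoods.
#' @export
strand_log_likelihood <- function(counts, params, scheme) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  loglam <- pmax(log(expand_lambda(params$lambda, scheme)), -745)
  S <- rowSums(counts)
  log_nb(S, params$r, params$p) +
    lgamma(S + 1) - rowSums(lgamma(counts + 1)) +
    as.numeric(counts %*% loglam)
}

#' Per-state chromatin log-likelihood for every instance
#'
#' Conditional on the binding state, the strands (and any additional
#' chromatin data types, passed as a list of matrices) are independent, so
#' the log-likelihood is the sum of [strand_log_likelihood()] terms.
#'
#' @param matrices a `CutMatrixPair`, or a list of them for multiple
#'   chromatin data types (each scored with the same `ModelParams` unless
#'   a list of parameter sets of matching length is given).
#' @param params a `ModelParams`, or a list of them matching `matrices`.
#' @return Matrix `n x (K + 2)` of log-likelihoods; column k+1 is state k.
#' @export
chromatin_log_likelihood <- function(matrices, params) {
  if (!inherits(matrices, "CutMatrixPair")) {
    plist <- if (inherits(params, "ModelParams"))
      rep(list(params), length(matrices)) else params
    stopifnot(length(plist) == length(matrices))
    ll <- chromatin_log_likelihood(matrices[[1]], plist[[1]])
    for (i in seq_along(matrices)[-1])
      ll <- ll + chromatin_log_likelihood(matrices[[i]], plist[[i]])
    return(ll)
  }
  n_states <- params$K + 2L
  ll <- matrix(0, nrow(matrices$fwd), n_states)
  for (k in seq_len(n_states)) {
    st <- params$states[[k]]
    bng <- params$binning[[k]]
    ll[, k] <- strand_log_likelihood(matrices$fwd, st$fwd, bng$fwd) +
      strand_log_likelihood(matrices$rev, st$rev, bng$rev)
  }
  colnames(ll) <- paste0("state_", seq_len(n_states) - 1L)
  ll
}

#' Combine prior log-odds and chromatin log-likelihood into posteriors
#'
#' By Bayes' theorem,
#' `P(Z_i = k | X_i) = exp(eta_ik + l_ik) / sum_k' exp(eta_ik' + l_ik')`
#' with the unbound pivot `eta_i0 = 0`, evaluated via log-sum-exp.
#'
#' @param eta matrix `n x (K + 1)` of prior log-odds from
#'   [prior_log_odds()].
#' @param loglik matrix `n x (K + 2)` from [chromatin_log_likelihood()].
#' @return A `PosteriorMatrix`: matrix `n x (K + 2)` with rows summing to
#'   1; `1 - posterior[, 1]` is the bound probability `p_i`.
#' @export
posterior_probabilities <- function(eta, loglik) {
  if (nrow(eta) != nrow(loglik) || ncol(eta) + 1L != ncol(loglik))
    stopf("eta must be n x (K+1) and loglik n x (K+2)")
  logw <- cbind(0, eta) + loglik
  post <- softmax_rows(logw)
  colnames(post) <- paste0("state_", seq_len(ncol(post)) - 1L)
  class(post) <- c("PosteriorMatrix", class(post))
  post
}

#' Bound probability from a posterior matrix
#' @param posterior a `PosteriorMatrix`.
#' @return Numeric vector `p_i = 1 - P(Z_i = 0 | X_i)`.
#' @export
p_bound <- function(posterior) 1 - posterior[, 1]
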