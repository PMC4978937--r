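# Internal numerical helpers shared across modules.

# Row-wise log-sum-exp. `x` is a matrix; returns a vector of length nrow(x).
# Terms are clamped at -745 (below which exp() underflows to 0) so that a
# state ruled impossible by a zero multinomial coefficient contributes
# nothing without generating NaN.
logsumexp_rows <- function(x) {
  x <- pmax(x, -745)
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

# Negative binomial log pmf in the convention
#   P(S = s) = C(s + r - 1, s) (1 - p)^r p^s,  mean = p * r / (1 - p),
# where p is the success probability and r > 0 the real-valued number of
# failures. Written with lgamma() so that non-integer totals (which arise
# after quantile clipping) are handled continuously.
log_nb <- function(s, r, p) {
  lgamma(s + r) - lgamma(r) - lgamma(s + 1) + r * log1p(-p) + s * log(p)
}

# Mean of the negative binomial above.
nb_mean <- function(r, p) p * r / (1 - p)

# Solve nb_mean(r, p) = mu for p at fixed r.
nb_p_from_mean <- function(mu, r) mu / (mu + r)

# softmax over rows of a matrix of log-odds that already includes the pivot
# column (log-odds 0). Returns a matrix of the same shape with rows summing
# to 1.
softmax_rows <- function(eta) {
  eta <- pmax(eta, -745)
  m <- apply(eta, 1L, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
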