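# Evaluation against ChIP-seq labels (precision-recall, ROC, Spearman
# correlation with peak height) and the Binding-in-Closed-Chromatin
# statistic for quantifying pioneer-factor-like activity.

check_labels <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (all(labels) || !any(labels))
    stopf("labels must contain at least one positive and one negative")
  labels
}

# Descending-score threshold sweep with ties grouped: one curve point per
# distinct score value. Returns cumulative tp/fp per threshold.
threshold_sweep <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  list(threshold = s[last], tp = tp[last], fp = fp[last],
       P = sum(labels), N = sum(!labels))
}

#' Precision-recall curve and average precision
#'
#' Thresholds are placed at every distinct score (ties grouped). The area
#' under the curve is the step-based average precision
#' `sum_k (R_k - R_{k-1}) P_k`, not a trapezoidal interpolation, so
#' reported values are reproducible bit-for-bit and free of the known
#' optimism of linear PR interpolation.
#'
#' @param scores numeric prediction scores (higher = more likely bound).
#' @param labels logical (or 0/1) vector of reference labels.
#' @return An `EvalCurve` list: data frame `curve` with `threshold`,
#'   `recall`, `precision`, and the scalar `auc`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  sw <- threshold_sweep(scores, labels)
  recall <- sw$tp / sw$P
  precision <- sw$tp / (sw$tp + sw$fp)
  auc <- sum(diff(c(0, recall)) * precision)
  structure(list(curve = data.frame(threshold = sw$threshold,
                                    recall = recall, precision = precision),
                 auc = auc, type = "precision-recall"),
            class = "EvalCurve")
}

#' ROC curve and area under it
#'
#' Same ties-grouped threshold sweep as [pr_curve()]; the area is computed
#' by the trapezoidal rule over the grouped points, which equals the
#' normalized Mann-Whitney U statistic with half credit for score ties.
#'
#' @inheritParams pr_curve
#' @return An `EvalCurve` list: data frame `curve` with `threshold`,
#'   `fpr`, `tpr`, and the scalar `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  sw <- threshold_sweep(scores, labels)
  tpr <- c(0, sw$tp / sw$P)
  fpr <- c(0, sw$fp / sw$N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(curve = data.frame(threshold = c(Inf, sw$threshold),
                                    fpr = fpr, tpr = tpr),
                 auc = auc, type = "roc"),
            class = "EvalCurve")
}

#' @export
print.EvalCurve <- function(x, ...) {
  cat(sprintf("EvalCurve (%s): %d points, AUC = %.4f\n",
              x$type, nrow(x$curve), x$auc))
  invisible(x)
}

#' Spearman correlation of binding scores with ChIP-seq peak height
#'
#' Rank correlation (average ranks for ties) between prediction scores and
#' peak heights at the ChIP-bound sites.
#'
#' @param scores numeric prediction scores at bound sites.
#' @param peak_heights peak signal values at the same sites.
#' @return Spearman's rho.
#' @export
spearman_vs_peak_height <- function(scores, peak_heights) {
  stopifnot(length(scores) == length(peak_heights))
  if (length(scores) < 3L)
    stopf("need at least 3 bound sites for a rank correlation")
  cor(scores, peak_heights, method = "spearman")
}

#' Convenience wrapper: evaluate scores against a ChIP-seq labeling
#'
#' @param scores per-instance prediction scores, in the order of `labeling`.
#' @param labeling data frame from [label_instances()].
#' @return List with `pr`, `roc` (both [pr_curve()]-style objects),
#'   `auc_pr`, `auc_roc` and `spearman_rho` (NA when fewer than 3 bound
#'   sites).
#' @export
evaluate_predictions <- function(scores, labeling) {
  labels <- labeling$label == "bound"
  pr <- pr_curve(scores, labels)
  roc <- roc_curve(scores, labels)
  rho <- if (sum(labels) >= 3L)
    spearman_vs_peak_height(scores[labels], labeling$peak_height[labels])
  else NA_real_
  list(pr = pr, roc = roc, auc_pr = pr$auc, auc_roc = roc$auc,
       spearman_rho = rho)
}

# ---------------------------------------------------------------------------
# Binding in Closed Chromatin

#' Chromatin-component-only bound probability
#'
#' The probability that an instance is bound in any mode, using the
#' chromatin likelihood alone under flat prior odds across all `K + 2`
#' states (the prior, sequence-derived component is excluded; uniformity
#' is the unique choice that injects no sequence information):
#' `sum_{k>=1} exp(l_k) / sum_{k>=0} exp(l_k)`, via log-sum-exp.
#'
#' @param loglik matrix `n x (K + 2)` from [chromatin_log_likelihood()].
#' @return Numeric vector of per-instance probabilities.
#' @export
chromatin_component_probability <- function(loglik) {
  loglik <- as.matrix(loglik)
  lse_all <- logsumexp_rows(loglik)
  lse_bound <- if (ncol(loglik) > 2L)
    logsumexp_rows(loglik[, -1, drop = FALSE])
  else loglik[, 2]
  exp(lse_bound - lse_all)
}

#' Binding in Closed Chromatin (BCC)
#'
#' The area under the empirical CDF of the chromatin-component
#' probabilities at ChIP-bound sites, over [0, 1]. An open-chromatin-only
#' binder has all probabilities near 1 (CDF flat until the right edge,
#' BCC near 0); a factor that tolerates closed chromatin accumulates mass
#' at low-to-moderate probabilities and scores higher. The ECDF area
#' equals `1 - mean(probs)` exactly.
#'
#' @param probs chromatin-component probabilities at ChIP-bound sites
#'   (values in [0, 1]).
#' @return The BCC score in [0, 1].
#' @export
bcc_score <- function(probs) {
  stopifnot(length(probs) >= 1L, all(probs >= 0), all(probs <= 1))
  1 - mean(probs)
}

#' Threshold for calling high-BCC (pioneer-like) factors
#'
#' Given BCC values across a collection of TFs, the threshold is the
#' median plus one median absolute deviation (MAD taken unscaled, without
#' the 1.4826 normal-consistency factor; set `scaled = TRUE` for the
#' scaled variant).
#'
#' @param bcc_values numeric vector of BCC scores (length >= 2).
#' @param scaled use the 1.4826-scaled MAD (default `FALSE`).
#' @return List with `threshold`, `median`, `mad`, and logical `above`
#'   marking the values strictly exceeding the threshold.
#' @export
bcc_threshold <- function(bcc_values, scaled = FALSE) {
  stopifnot(length(bcc_values) >= 2L)
  med <- median(bcc_values)
  m <- mad(bcc_values, constant = if (scaled) 1.4826 else 1)
  list(threshold = med + m, median = med, mad = m,
       above = bcc_values > med + m)
}
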