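# Per-instance strand-specific cut matrices, spike clipping, and the
# position-to-bin mapping shared by all likelihood computations.

# ---------------------------------------------------------------------------
# CutMatrixPair

new_cut_matrix_pair <- function(fwd, rev, margin, L, instance_id,
                                clip_threshold = NULL) {
  structure(list(fwd = fwd, rev = rev, margin = as.integer(margin),
                 L = as.integer(L), instance_id = instance_id,
                 clip_threshold = clip_threshold),
            class = "CutMatrixPair")
}

#' @export
print.CutMatrixPair <- function(x, ...) {
  cat(sprintf("CutMatrixPair: %d instances x %d positions per strand (margin %d, motif %d bp)%s\n",
              nrow(x$fwd), ncol(x$fwd), x$margin, x$L,
              if (is.null(x$clip_threshold)) "" else
                sprintf(", clipped at %g", x$clip_threshold)))
  invisible(x)
}

#' Build strand-asymmetric cut matrices around candidate sites
#'
#' For every motif instance the forward-strand cuts are collected over the
#' window running from `margin` bp upstream of the motif through its last
#' base, and the reverse-strand cuts over the window from the first motif
#' base through `margin` bp downstream. "Forward" always means the
#' motif-sense strand: for a minus-strand instance the genomic strands are
#' swapped and the windows mirrored, so columns always run 5' to 3' in motif
#' orientation and a single profile model serves both orientations.
#'
#' Sites whose window would extend past the start of the contig (or past
#' `seqlengths` when supplied) are dropped with a warning; use the returned
#' `instance_id` field to subset the site set accordingly.
#'
#' @param track a `CutTrack` from [load_cut_track()] or
#'   [cuts_from_alignments()].
#' @param sites a [motif_instance_set()].
#' @param margin upstream/downstream window size in bp (default 200).
#' @param seqlengths optional named vector of contig lengths used for the
#'   right-edge drop rule; by default only the left contig edge is enforced.
#' @return A `CutMatrixPair` with integer matrices `fwd` and `rev`, each
#'   `n x (margin + L)`.
#' @export
build_cut_matrices <- function(track, sites, margin = 200L, seqlengths = NULL) {
  n <- n_instances(sites)
  L <- sites$motif_length
  W <- margin + L
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    s <- sites$start[i]; e <- sites$end[i]
    lo <- if (sites$strand[i] == "+") s - margin else s
    hi <- if (sites$strand[i] == "+") e else e + margin
    if (lo < 0) ok[i] <- FALSE
    sl <- seqlengths[[sites$chrom[i]]] %||% NA
    if (!is.na(sl) && hi > sl) ok[i] <- FALSE
  }
  if (!all(ok))
    warnf("dropping %d site(s) whose window extends past a contig edge", sum(!ok))
  keep <- which(ok)
  fwd <- matrix(0, length(keep), W)
  rev_ <- matrix(0, length(keep), W)
  for (j in seq_along(keep)) {
    i <- keep[j]
    s <- sites$start[i]; e <- sites$end[i]; ch <- sites$chrom[i]
    if (sites$strand[i] == "+") {
      fwd[j, ] <- track_slice(track, ch, "+", s - margin, e)
      rev_[j, ] <- track_slice(track, ch, "-", s, e + margin)
    } else {
      fwd[j, ] <- rev(track_slice(track, ch, "-", s, e + margin))
      rev_[j, ] <- rev(track_slice(track, ch, "+", s - margin, e))
    }
  }
  new_cut_matrix_pair(fwd, rev_, margin, L, sites$instance_id[keep])
}

#' Subset a MotifInstanceSet to the instances kept in a CutMatrixPair
#'
#' @param sites a [motif_instance_set()].
#' @param ids character vector of instance identifiers (e.g. the
#'   `instance_id` field of a `CutMatrixPair`).
#' @return The subset `MotifInstanceSet`, in the order of `ids`.
#' @export
subset_instances <- function(sites, ids) {
  idx <- match(ids, sites$instance_id)
  if (anyNA(idx)) stopf("unknown instance_id(s)")
  motif_instance_set(sites$chrom[idx], sites$start[idx], sites$end[idx],
                     sites$strand[idx], sites$instance_id[idx],
                     sites$features[idx, , drop = FALSE])
}

#' Clip artifactual cut-count spikes at an empirical quantile
#'
#' Short-read data are prone to artifactual spikes of reads mapped to a
#' single position and strand. The clipping threshold is the empirical
#' `q`-quantile (linear interpolation) of the pooled entries of both
#' matrices; entries above it are set to the threshold. The operation is
#' idempotent.
#'
#' @param matrices a `CutMatrixPair`.
#' @param q quantile in (0,1); default 0.999.
#' @return The clipped `CutMatrixPair`, with `clip_threshold` set.
#' @export
clip_counts <- function(matrices, q = 0.999) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stopf("clipping quantile must lie strictly between 0 and 1")
  if (nrow(matrices$fwd) == 0) stopf("cannot clip empty matrices")
  # clipping is a one-shot operation: re-estimating the quantile from
  # already-clipped entries would drift the threshold downwards
  if (!is.null(matrices$clip_threshold)) return(matrices)
  pooled <- c(matrices$fwd, matrices$rev)
  thr <- as.numeric(quantile(pooled, q, type = 7))
  matrices$fwd[matrices$fwd > thr] <- thr
  matrices$rev[matrices$rev > thr] <- thr
  matrices$clip_threshold <- thr
  matrices
}

# ---------------------------------------------------------------------------
# Binning

#' Construct the position-to-bin mapping for one binding state
#'
#' Bound states use contiguous `bin_width`-bp bins over the margin and
#' single-basepair bins over the motif, so the spatial profile is
#' coarse-grained outside the footprint and basepair-resolved inside it.
#' The unbound state puts every position into a single bin, which together
#' with uniform within-bin mass makes its spatial model exactly uniform.
#'
#' @param L motif length in bp (> 0).
#' @param margin margin size in bp.
#' @param bin_width margin bin width in bp (default 20). If `margin` is not
#'   divisible by `bin_width` the last margin bin is truncated, with a
#'   warning.
#' @param mode `"bound"` or `"unbound"`.
#' @return A `BinningScheme`: a list with elements `fwd` and `rev`, each
#'   holding `assignment` (bin index for every window position, 5' to 3' in
#'   motif orientation) and `sizes` (positions per bin).
#' @export
make_binning <- function(L, margin = 200L, bin_width = 20L,
                         mode = c("bound", "unbound")) {
  mode <- match.arg(mode)
  if (L <= 0) stopf("motif length must be positive")
  W <- margin + L
  if (mode == "unbound") {
    one <- list(assignment = rep(1L, W), sizes = W)
    return(structure(list(fwd = one, rev = one, L = as.integer(L),
                          margin = as.integer(margin),
                          bin_width = as.integer(bin_width), mode = mode),
                     class = "BinningScheme"))
  }
  if (margin %% bin_width != 0)
    warnf("margin %d not divisible by bin width %d; last margin bin truncated",
          margin, bin_width)
  n_margin_bins <- as.integer(ceiling(margin / bin_width))
  margin_bins <- pmin(((seq_len(margin) - 1L) %/% bin_width) + 1L, n_margin_bins)
  # fwd window: margin upstream then motif; rev window: motif then margin
  fwd_assign <- c(margin_bins, n_margin_bins + seq_len(L))
  rev_assign <- c(seq_len(L), L + margin_bins)
  scheme <- function(a) list(assignment = a, sizes = as.integer(tabulate(a)))
  structure(list(fwd = scheme(fwd_assign), rev = scheme(rev_assign),
                 L = as.integer(L), margin = as.integer(margin),
                 bin_width = as.integer(bin_width), mode = mode),
            class = "BinningScheme")
}

#' Free-parameter accounting for the mixture model
#'
#' The multinomial component of each bound state has, per strand, one free
#' parameter per bin minus one normalization constraint; with the default
#' binning this is `2 * (L + margin/bin_width - 1)` per bound state
#' (38 for a 10 bp motif with a 200 bp margin in 20 bp bins). The unbound
#' state's single-bin multinomial is forced uniform and contributes none.
#' Every state contributes 2 negative binomial parameters (p, r) per
#' strand, and each bound mode contributes an intercept plus its active
#' prior-feature coefficients.
#'
#' @param L motif length in bp.
#' @param margin margin in bp (default 200).
#' @param bin_width margin bin width in bp (default 20).
#' @param K number of cooperative dimer modes (default 0).
#' @param n_active_features number of prior features active per bound mode;
#'   scalar or vector of length `K + 1` (default 1).
#' @return A list with the per-component counts `multinomial`,
#'   `negative_binomial`, `prior`, the per-bound-mode multinomial count
#'   `multinomial_per_bound_mode`, and `total`.
#' @export
count_free_parameters <- function(L, margin = 200L, bin_width = 20L, K = 0L,
                                  n_active_features = 1L) {
  n_margin_bins <- as.integer(ceiling(margin / bin_width))
  per_mode_multinomial <- 2L * (L + n_margin_bins - 1L)
  n_bound <- K + 1L
  n_states <- K + 2L
  n_active <- rep_len(as.integer(n_active_features), n_bound)
  out <- list(
    multinomial = n_bound * per_mode_multinomial,
    multinomial_per_bound_mode = per_mode_multinomial,
    negative_binomial = 2L * 2L * n_states,
    prior = sum(1L + n_active)
  )
  out$total <- out$multinomial + out$negative_binomial + out$prior
  out
}
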