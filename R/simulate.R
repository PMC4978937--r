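# Generative simulator: draws datasets from the exact model (features ->
# latent states -> negative binomial totals -> multinomially scattered
# cuts) and can emit them as the standard on-disk formats, so the whole
# pipeline is testable end-to-end without any external data.

#' Construct a toy model with a footprint-shaped cut profile
#'
#' Builds a fully specified `ModelParams` suitable for simulation: bound
#' modes get a spatial profile with elevated flanks (the hypersensitive
#' region around a bound site) and a depleted motif core (the footprint),
#' plus a higher negative binomial mean than the unbound background; the
#' prior uses a standard-normal motif score (and, for each dimer mode, an
#' independent partner motif score active only in that mode).
#'
#' Defaults emulate a reasonably deep DNase-seq experiment: unbound
#' background of 10 cuts per strand per window, bound modes around 80,
#' and a footprint removing `footprint_depth` of the flank-level signal
#' within the motif.
#'
#' @param K number of cooperative dimer modes (default 0).
#' @param L motif length in bp (default 10).
#' @param margin margin in bp (default 200).
#' @param footprint_depth fraction of flank-level cut density removed
#'   within the motif, in [0, 1] (default 0.6; 0 gives a spatially
#'   uninformative bound profile).
#' @param seed integer seed for the small reproducible wiggle added to the
#'   profiles so distinct modes stay distinguishable.
#' @return A `ModelParams` with an attached [binding_mode_spec()] in
#'   `$modes`.
#' @export
make_toy_model <- function(K = 0L, L = 10L, margin = 200L,
                           footprint_depth = 0.6, seed = 1L) {
  stopifnot(K >= 0, footprint_depth >= 0, footprint_depth <= 1)
  set.seed(seed)
  feature_names <- c("motif_score",
                     if (K > 0) paste0("partner_score_", seq_len(K)))
  J <- length(feature_names)
  n_bound <- K + 1L
  gamma <- matrix(0, J, n_bound)
  gamma[1, ] <- 1                       # motif score active in every mode
  if (K > 0) for (k in seq_len(K)) gamma[1L + k, 1L + k] <- 1
  modes <- binding_mode_spec(feature_names, K = K, gamma = gamma,
                             partner_features = if (K > 0) feature_names[-1])

  gamma <- modes$gamma
  beta0 <- c(-1.5, rep(-2.5, K))
  beta <- matrix(0, J, n_bound, dimnames = dimnames(gamma))
  beta[1, ] <- 1
  if (K > 0) for (k in seq_len(K)) beta[1L + k, 1L + k] <- 1.5

  bound_bng <- make_binning(L, margin, mode = "bound")
  # Full-strength per-position shape in motif orientation: flanks elevated
  # with distance decay toward the motif edge, core depleted to 0.25x.
  # footprint_depth interpolates log-linearly between the uniform profile
  # (0) and this shape (1); the small reproducible wiggle scales with it
  # too, so depth 0 is exactly spatially uniform.
  profile_weights <- function(decay, amp) {
    flank <- 1 + amp * exp(-(margin:1) / decay)
    core <- rep(0.25, L)
    list(fwd = c(flank, core),              # upstream margin, then motif
         rev = c(core, rev(flank)))         # motif, then downstream margin
  }
  bin_masses <- function(w, scheme) {
    lw <- footprint_depth * (log(w) + rnorm(length(w), 0, 0.05))
    lam <- as.numeric(rowsum(exp(lw), scheme$assignment))
    lam / sum(lam)
  }
  states <- vector("list", K + 2L)
  states[[1]] <- list(fwd = list(p = nb_p_from_mean(10, 2), r = 2, lambda = 1),
                      rev = list(p = nb_p_from_mean(10, 2), r = 2, lambda = 1))
  for (k in seq_len(n_bound)) {
    w <- profile_weights(decay = 50 / k, amp = 1.5 + 0.5 * (k - 1))
    mu <- 80 + 20 * (k - 1)
    states[[k + 1L]] <- list(
      fwd = list(p = nb_p_from_mean(mu, 5), r = 5,
                 lambda = bin_masses(w$fwd, bound_bng$fwd)),
      rev = list(p = nb_p_from_mean(mu, 5), r = 5,
                 lambda = bin_masses(w$rev, bound_bng$rev)))
  }
  params <- new_model_params(K = K, L = L, margin = margin,
                             bin_width = bound_bng$bin_width, delta = 0.5,
                             prior = list(beta0 = beta0, beta = beta),
                             gamma = gamma, states = states)
  params$modes <- modes
  params
}

#' Simulate a dataset from the generative model
#'
#' Per instance: draw the prior features, draw the latent state from the
#' softmax of the prior log-odds, draw each strand's total cut count from
#' that state's negative binomial, and scatter the cuts over window
#' positions multinomially. Instances are placed on a toy contig with
#' non-overlapping windows (alternating strands), so the dataset can also
#' be written out as BED + TSV + two bedGraphs and re-read through the
#' standard readers, reproducing the matrices exactly.
#'
#' @param model a `ModelParams` from [make_toy_model()] (or with a
#'   `$modes` spec attached).
#' @param n number of instances.
#' @param feature_generator optional `function(n, feature_names)`
#'   returning the feature matrix; default: independent standard normals.
#' @param seed integer seed.
#' @param dir optional directory: when given, the fixture files
#'   (`sites.bed`, `features.tsv`, `cuts_fwd.bedGraph`,
#'   `cuts_rev.bedGraph`, `model.json`, `truth.json`) are written there.
#' @return A `SimulatedDataset` list: `sites`, `matrices` (unclipped
#'   `CutMatrixPair`), `true_states` (0 = unbound), `true_params`,
#'   `modes`, `track`, `seed`.
#' @export
simulate_dataset <- function(model, n, feature_generator = NULL, seed = 1L,
                             dir = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  modes <- model$modes %||% binding_mode_spec(rownames(model$gamma),
                                              K = model$K, gamma = model$gamma)
  L <- model$L; margin <- model$margin; W <- margin + L
  feature_names <- rownames(model$gamma)
  X <- if (is.null(feature_generator))
    matrix(rnorm(n * length(feature_names)), n,
           dimnames = list(NULL, feature_names))
  else feature_generator(n, feature_names)

  eta <- prior_log_odds(X, model$prior, modes)
  pz <- softmax_rows(cbind(0, eta))
  z <- apply(pz, 1L, function(p) sample.int(length(p), 1L, prob = p)) - 1L

  fwd <- matrix(0, n, W); rev_ <- matrix(0, n, W)
  for (k in 0:(model$K + 1L)) {
    idx <- which(z == k)
    if (length(idx) == 0) next
    st <- model$states[[k + 1L]]
    bng <- model$binning[[k + 1L]]
    for (s in c("fwd", "rev")) {
      lamt <- expand_lambda(st[[s]]$lambda, bng[[s]])
      tot <- rnbinom(length(idx), size = st[[s]]$r, prob = 1 - st[[s]]$p)
      M <- if (s == "fwd") fwd else rev_
      for (j in seq_along(idx))
        M[idx[j], ] <- rmultinom(1L, tot[j], lamt)
      if (s == "fwd") fwd <- M else rev_ <- M
    }
  }

  # lay instances out on a toy contig, alternating strands
  stride <- 2L * margin + L + 10L
  start <- margin + (seq_len(n) - 1L) * stride
  end <- start + L
  strand <- rep_len(c("+", "-"), n)
  ids <- sprintf("site_%05d", seq_len(n))
  sites <- motif_instance_set(rep("chrS", n), start, end, strand, ids, X)

  contig_len <- max(end) + margin + 10L
  plus <- numeric(contig_len); minus <- numeric(contig_len)
  for (i in seq_len(n)) {
    s <- start[i]; e <- end[i]
    if (strand[i] == "+") {
      plus[(s - margin + 1L):e] <- plus[(s - margin + 1L):e] + fwd[i, ]
      minus[(s + 1L):(e + margin)] <- minus[(s + 1L):(e + margin)] + rev_[i, ]
    } else {
      minus[(s + 1L):(e + margin)] <- minus[(s + 1L):(e + margin)] + rev(fwd[i, ])
      plus[(s - margin + 1L):e] <- plus[(s - margin + 1L):e] + rev(rev_[i, ])
    }
  }
  track <- new_cut_track(list(chrS = list("+" = plus, "-" = minus)))
  matrices <- new_cut_matrix_pair(fwd, rev_, margin, L, ids)

  sim <- structure(list(sites = sites, matrices = matrices, true_states = z,
                        true_params = model, modes = modes, track = track,
                        seed = as.integer(seed)),
                   class = "SimulatedDataset")
  if (!is.null(dir)) write_fixture_dir(sim, dir)
  sim
}

#' Write a simulated dataset as standard fixture files
#'
#' @param sim a `SimulatedDataset`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture_dir <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- sim$sites
  bed <- data.frame(s$chrom, s$start, s$end, s$instance_id,
                    s$features[, "motif_score"], s$strand)
  write.table(bed, file.path(dir, "sites.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  feat <- data.frame(instance_id = s$instance_id, s$features,
                     check.names = FALSE)
  write.table(feat, file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bedgraph(sim$track, file.path(dir, "cuts_fwd.bedGraph"),
                 file.path(dir, "cuts_rev.bedGraph"))
  save_model(sim$true_params, file.path(dir, "model.json"))
  jsonlite::write_json(list(seed = sim$seed, true_states = sim$true_states),
                       file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat(sprintf("SimulatedDataset: %d instances (%d bound), seed %d\n",
              length(x$true_states), sum(x$true_states > 0), x$seed))
  invisible(x)
}
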