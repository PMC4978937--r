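# Readers and writers for the standard formats the tool touches, plus
# ChIP-seq labeling. All genomic coordinates are 0-based half-open (BED
# convention) everywhere inside the package; conversions to the 1-based
# conventions of Bioconductor containers happen only inside this file.

# ---------------------------------------------------------------------------
# MotifInstanceSet

#' Construct a set of candidate motif instances
#'
#' A `MotifInstanceSet` holds the candidate binding sites for one TF: their
#' genomic coordinates (0-based, half-open), strand, a stable identifier and
#' a numeric matrix of prior characteristics (one row per instance), of
#' which the PWM score is the canonical first column.
#'
#' @param chrom character vector of contig names.
#' @param start,end integer vectors; `end - start` must be constant (the
#'   motif length `L`).
#' @param strand character vector of `"+"`/`"-"`.
#' @param instance_id character vector of unique identifiers.
#' @param features numeric matrix, one row per instance, with column names;
#'   no missing values allowed.
#' @return An object of class `MotifInstanceSet`.
#' @export
motif_instance_set <- function(chrom, start, end, strand, instance_id, features) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n, length(strand) == n,
            length(instance_id) == n)
  if (!all(strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  widths <- end - start
  if (n > 0 && length(unique(widths)) != 1L)
    stopf("inconsistent motif length: widths %s", paste(unique(widths), collapse = ", "))
  if (anyDuplicated(instance_id))
    stopf("instance_ids are not unique")
  features <- as.matrix(features)
  if (n > 0 && (nrow(features) != n || ncol(features) < 1L))
    stopf("feature matrix must have one row per instance and at least one column")
  if (anyNA(features) || any(!is.finite(features)))
    stopf("feature matrix contains missing or non-finite values")
  if (is.null(colnames(features)))
    stopf("feature matrix must have column names")
  rownames(features) <- instance_id
  structure(list(
    chrom = as.character(chrom), start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), instance_id = as.character(instance_id),
    features = features, motif_length = if (n > 0) as.integer(widths[1]) else NA_integer_
  ), class = "MotifInstanceSet")
}

#' @export
print.MotifInstanceSet <- function(x, ...) {
  cat(sprintf("MotifInstanceSet: %d instances, motif length %d bp, %d feature(s): %s\n",
              length(x$chrom), x$motif_length, ncol(x$features),
              paste(colnames(x$features), collapse = ", ")))
  invisible(x)
}

#' Number of instances in a MotifInstanceSet
#' @param x a `MotifInstanceSet`.
#' @export
n_instances <- function(x) length(x$chrom)

#' Read candidate binding sites from BED, with optional extra features
#'
#' Reads a BED6 file of equal-width candidate motif instances. The BED score
#' column becomes the feature `motif_score` unless the optional TSV supplies
#' a column of the same name. The TSV must be keyed by a column
#' `instance_id` matching the BED name column and contain only numeric
#' feature columns; every BED instance must be present in it.
#'
#' @param bed_path path to a BED file with at least 6 columns.
#' @param feature_path optional path to a TSV of extra per-instance features.
#' @return A [motif_instance_set()], sorted by (chrom, start).
#' @export
read_candidate_sites <- function(bed_path, feature_path = NULL) {
  if (!file.exists(bed_path)) stopf("BED file not found: %s", bed_path)
  bed <- read.table(bed_path, sep = "", header = FALSE,
                    colClasses = c("character", "integer", "integer",
                                   "character", "numeric", "character"),
                    col.names = c("chrom", "start", "end", "name", "score", "strand"),
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stopf("BED file must have at least 6 columns")
  widths <- bed$end - bed$start
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stopf("inconsistent motif length at line %d of %s (width %d, expected %d)",
          bad, bed_path, widths[bad], widths[1])
  }
  feats <- matrix(bed$score, ncol = 1, dimnames = list(NULL, "motif_score"))
  if (!is.null(feature_path)) {
    tab <- read.table(feature_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
    if (!"instance_id" %in% colnames(tab))
      stopf("feature TSV must have an 'instance_id' column")
    missing <- setdiff(bed$name, tab$instance_id)
    if (length(missing) > 0)
      stopf("feature TSV is missing instance_id(s): %s",
            paste(head(missing, 5), collapse = ", "))
    idx <- match(bed$name, tab$instance_id)
    extra <- tab[idx, setdiff(colnames(tab), "instance_id"), drop = FALSE]
    if (!all(vapply(extra, is.numeric, logical(1))))
      stopf("feature TSV columns must be numeric")
    extra <- as.matrix(extra)
    keep <- setdiff(colnames(feats), colnames(extra))
    feats <- cbind(feats[, keep, drop = FALSE], extra)
  }
  ord <- order(bed$chrom, bed$start)
  motif_instance_set(bed$chrom[ord], bed$start[ord], bed$end[ord],
                     bed$strand[ord], bed$name[ord],
                     feats[ord, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# PeakSet

#' Read ChIP-seq peaks from an ENCODE narrowPeak file
#'
#' The narrowPeak dialect is BED6+4; the peak height used downstream is the
#' `signalValue` column (column 7). `.` placeholders in the name/strand
#' columns are tolerated. Overlapping peaks are retained as-is.
#'
#' @param path path to a 10-column narrowPeak file.
#' @return A data frame of class `PeakSet` with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `signal_value`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stopf("narrowPeak file not found: %s", path)
  info <- file.info(path)
  if (info$size == 0) {
    pk <- data.frame(chrom = character(), start = integer(), end = integer(),
                     signal_value = numeric())
    class(pk) <- c("PeakSet", "data.frame")
    return(pk)
  }
  tab <- read.table(path, sep = "", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 10L)
    stopf("narrowPeak file must have 10 columns, found %d", ncol(tab))
  if (!all(tab[[2]] < tab[[3]]))
    stopf("narrowPeak intervals must satisfy start < end")
  pk <- data.frame(chrom = as.character(tab[[1]]),
                   start = as.integer(tab[[2]]), end = as.integer(tab[[3]]),
                   signal_value = as.numeric(tab[[7]]))
  class(pk) <- c("PeakSet", "data.frame")
  pk
}

#' Label motif instances as bound or unbound using ChIP-seq peaks
#'
#' A motif instance is labeled bound if it overlaps any peak by at least one
#' basepair (half-open interval semantics); `peak_height` is the maximum
#' `signal_value` over the overlapping peaks, `NA` for unbound instances.
#'
#' @param sites a [motif_instance_set()].
#' @param peaks a `PeakSet` from [read_peaks()].
#' @return A data frame with columns `instance_id`, `label`
#'   (factor bound/unbound) and `peak_height`.
#' @export
label_instances <- function(sites, peaks) {
  n <- n_instances(sites)
  lab <- rep("unbound", n)
  height <- rep(NA_real_, n)
  if (n > 0 && nrow(peaks) > 0) {
    gr_sites <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(sites$start + 1L, sites$end))
    gr_peaks <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
    hits <- GenomicRanges::findOverlaps(gr_sites, gr_peaks, minoverlap = 1L)
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      sv <- peaks$signal_value[S4Vectors::subjectHits(hits)]
      best <- tapply(sv, qh, max)
      idx <- as.integer(names(best))
      lab[idx] <- "bound"
      height[idx] <- as.numeric(best)
    }
  }
  data.frame(instance_id = sites$instance_id,
             label = factor(lab, levels = c("bound", "unbound")),
             peak_height = height, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# CutTrack

new_cut_track <- function(counts, seqlengths = NULL) {
  if (is.null(seqlengths)) {
    seqlengths <- vapply(counts, function(x) max(length(x[["+"]]), length(x[["-"]])),
                         numeric(1))
  }
  structure(list(counts = counts, seqlengths = seqlengths), class = "CutTrack")
}

#' @export
print.CutTrack <- function(x, ...) {
  tot <- sum(vapply(x$counts, function(ch) sum(ch[["+"]]) + sum(ch[["-"]]), numeric(1)))
  cat(sprintf("CutTrack: %d contig(s), %g cuts total\n", length(x$counts), tot))
  invisible(x)
}

# Extract per-base counts over the 0-based half-open interval [start, end);
# positions outside the stored extent count 0.
track_slice <- function(track, chrom, strand, start, end) {
  out <- numeric(end - start)
  ch <- track$counts[[chrom]]
  if (is.null(ch)) return(out)
  v <- ch[[strand]]
  if (is.null(v) || length(v) == 0) return(out)
  lo <- max(start, 0L); hi <- min(end, length(v))
  if (hi > lo) out[(lo - start + 1L):(hi - start)] <- v[(lo + 1L):hi]
  out
}

bedgraph_to_vectors <- function(path, strand_label) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) return(list())
  if (any(gr$score < 0))
    stopf("negative cut counts in %s", path)
  self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(self) > 0)
    stopf("overlapping intervals in bedGraph %s", path)
  out <- list()
  chroms <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  scores <- gr$score
  for (chrom in unique(chroms)) {
    sel <- chroms == chrom
    w <- ends[sel] - starts[sel] + 1L
    v <- numeric(max(ends[sel]))
    v[sequence(w, from = starts[sel])] <- rep(scores[sel], w)
    out[[chrom]] <- v
  }
  out
}

#' Load a strand-specific cut-count track from two bedGraph files
#'
#' Each bedGraph value `v` over an interval expands to a per-base count of
#' `v` at every base of the interval. Unrepresented positions count 0.
#'
#' @param fwd_path bedGraph of forward-strand cut counts.
#' @param rev_path bedGraph of reverse-strand cut counts.
#' @return A `CutTrack` giving O(1) access to per-base counts by
#'   (contig, strand, position).
#' @export
load_cut_track <- function(fwd_path, rev_path) {
  fwd <- bedgraph_to_vectors(fwd_path)
  rev <- bedgraph_to_vectors(rev_path)
  chroms <- union(names(fwd), names(rev))
  counts <- lapply(setNames(chroms, chroms), function(chrom) {
    list("+" = fwd[[chrom]] %||% numeric(0),
         "-" = rev[[chrom]] %||% numeric(0))
  })
  new_cut_track(counts)
}

#' Write a CutTrack as a pair of bedGraph files
#'
#' Inverse of [load_cut_track()]: zero runs are omitted, so a round trip
#' through the two files reproduces the track exactly.
#'
#' @param track a `CutTrack`.
#' @param fwd_path,rev_path output paths for the two strands.
#' @export
write_bedgraph <- function(track, fwd_path, rev_path) {
  write_one <- function(strand, path) {
    grs <- list()
    for (chrom in names(track$counts)) {
      v <- track$counts[[chrom]][[strand]]
      if (length(v) == 0) next
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values != 0
      if (!any(keep)) next
      grs[[chrom]] <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(starts[keep], ends[keep]), score = r$values[keep])
    }
    gr <- if (length(grs) > 0) do.call(c, unname(grs)) else
      GenomicRanges::GRanges(score = numeric(0))
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  write_one("+", fwd_path)
  write_one("-", rev_path)
  invisible(c(fwd_path, rev_path))
}

#' Extract per-base cut counts from aligned reads
#'
#' Tallies the 5' end of each aligned sequence tag: the leftmost aligned
#' position for a forward-strand read, the rightmost for a reverse-strand
#' read (optionally shifted by `reverse_shift` bp). Unmapped, secondary and
#' duplicate records are skipped.
#'
#' @param path an indexed BAM file.
#' @param reverse_shift integer offset added to the reverse-strand cut
#'   position (default 0).
#' @return A `CutTrack`.
#' @export
cuts_from_alignments <- function(path, reverse_shift = 0L) {
  if (!file.exists(path)) stopf("BAM file not found: %s", path)
  if (!file.exists(paste0(path, ".bai")) && !file.exists(sub("\\.bam$", ".bai", path)))
    stopf("missing BAM index for %s", path)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  aln <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flag))
  counts <- list()
  if (length(aln) > 0) {
    chrom <- as.character(GenomicAlignments::seqnames(aln))
    str <- as.character(BiocGenerics::strand(aln))
    # 0-based cut positions
    pos <- ifelse(str == "+",
                  GenomicAlignments::start(aln) - 1L,
                  GenomicAlignments::end(aln) - 1L + as.integer(reverse_shift))
    strand_out <- ifelse(str == "+", "+", "-")
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      counts[[ch]] <- list("+" = numeric(0), "-" = numeric(0))
      for (s in c("+", "-")) {
        p <- pos[sel & strand_out == s]
        p <- p[p >= 0]
        if (length(p) == 0) next
        v <- numeric(max(p) + 1L)
        t <- table(p)
        v[as.integer(names(t)) + 1L] <- as.numeric(t)
        counts[[ch]][[s]] <- v
      }
    }
  }
  new_cut_track(counts)
}

# ---------------------------------------------------------------------------
# Posteriors and model persistence

#' Write per-instance posterior probabilities as TSV
#'
#' One row per instance: identifier, coordinates, the bound probability
#' `p_bound` and one column per state (`state_0` = unbound, `state_1` =
#' monomer, `state_k` for dimer modes).
#'
#' @param sites a [motif_instance_set()].
#' @param posterior numeric matrix, one row per instance, one column per
#'   state, rows summing to 1.
#' @param path output TSV path.
#' @export
write_posteriors <- function(sites, posterior, path) {
  posterior <- as.matrix(posterior)
  if (nrow(posterior) != n_instances(sites))
    stopf("posterior has %d rows but sites has %d instances",
          nrow(posterior), n_instances(sites))
  df <- data.frame(instance_id = sites$instance_id,
                   chrom = sites$chrom, start = sites$start, end = sites$end,
                   strand = sites$strand,
                   p_bound = 1 - posterior[, 1],
                   stringsAsFactors = FALSE)
  states <- as.data.frame(posterior)
  colnames(states) <- paste0("state_", seq_len(ncol(posterior)) - 1L)
  write.table(cbind(df, states), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read back a posterior TSV written by [write_posteriors()]
#' @param path TSV path.
#' @return A data frame with the columns written by [write_posteriors()].
#' @export
read_posteriors <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Save / load fitted model parameters as JSON
#'
#' The JSON layout is `{delta, prior: {feature_names, beta0, beta, gamma},
#' states: [{fwd: {p, r, lambda}, rev: {...}}, ...], binning, L, margin,
#' bin_width, K}`. A save/load round trip reproduces the parameters to
#' within 1e-12.
#'
#' @param params a `ModelParams` object (see [fit_footprint_model()]).
#' @param path JSON path.
#' @export
save_model <- function(params, path) {
  obj <- list(
    delta = params$delta, K = params$K, L = params$L,
    margin = params$margin, bin_width = params$bin_width,
    prior = list(feature_names = colnames(params$gamma),
                 beta0 = params$prior$beta0,
                 beta = params$prior$beta,
                 gamma = params$gamma),
    states = lapply(params$states, function(st) {
      lapply(st, function(s) list(p = s$p, r = s$r, lambda = s$lambda))
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the `ModelParams` object.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  gamma <- matrix(as.numeric(obj$prior$gamma), ncol = obj$K + 1L)
  beta <- matrix(as.numeric(obj$prior$beta), ncol = obj$K + 1L)
  rownames(gamma) <- rownames(beta) <- obj$prior$feature_names
  states <- lapply(seq_along(obj$states), function(i) {
    st <- obj$states[[i]]
    list(fwd = list(p = st$fwd$p, r = st$fwd$r, lambda = as.numeric(st$fwd$lambda)),
         rev = list(p = st$rev$p, r = st$rev$r, lambda = as.numeric(st$rev$lambda)))
  })
  new_model_params(K = obj$K, L = obj$L, margin = obj$margin,
                   bin_width = obj$bin_width, delta = obj$delta,
                   prior = list(beta0 = as.numeric(obj$prior$beta0), beta = beta),
                   gamma = gamma, states = states)
}
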