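write_lines <- function(lines, path) writeLines(lines, path)

test_that("read_candidate_sites maps BED fields and merges TSV features", {
  bed <- withr::local_tempfile(fileext = ".bed")
  write_lines(c("chr1\t100\t110\tm1\t12.5\t+",
                "chr1\t50\t60\tm2\t3.0\t-",
                "chr2\t10\t20\tm3\t7.25\t+"), bed)
  sites <- read_candidate_sites(bed)
  expect_equal(sites$motif_length, 10L)
  # sorted by (chrom, start)
  expect_equal(sites$instance_id, c("m2", "m1", "m3"))
  expect_equal(unname(sites$features[, "motif_score"]), c(3.0, 12.5, 7.25))
  expect_equal(sites$strand, c("-", "+", "+"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("instance_id\tpartner_score",
                "m1\t1.5", "m2\t-0.5", "m3\t0.25"), tsv)
  sites2 <- read_candidate_sites(bed, tsv)
  expect_equal(colnames(sites2$features), c("motif_score", "partner_score"))
  # row order matches the sorted sites, verified against a hand-built matrix
  expect_equal(unname(sites2$features),
               matrix(c(3.0, 12.5, 7.25, -0.5, 1.5, 0.25), ncol = 2))
})

test_that("read_candidate_sites rejects malformed inputs informatively", {
  bed <- withr::local_tempfile(fileext = ".bed")
  write_lines(c("chr1\t100\t110\tm1\t1\t+",
                "chr1\t200\t212\tm2\t1\t+"), bed)
  expect_error(read_candidate_sites(bed), "inconsistent motif length.*line 2")

  bed2 <- withr::local_tempfile(fileext = ".bed")
  write_lines("chr1\t100\t110\tm1\t1\t+", bed2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("instance_id\tx", "other\t1"), tsv)
  expect_error(read_candidate_sites(bed2, tsv), "missing instance_id")
})

test_that("read_peaks parses narrowPeak and keeps overlapping peaks as-is", {
  np <- withr::local_tempfile(fileext = ".narrowPeak")
  write_lines(c("chr1\t100\t200\t.\t0\t.\t5.5\t-1\t-1\t50",
                "chr1\t150\t250\t.\t0\t.\t9.0\t-1\t-1\t50"), np)
  pk <- read_peaks(np)
  expect_s3_class(pk, "PeakSet")
  expect_equal(nrow(pk), 2L)       # no merging
  expect_equal(pk$signal_value, c(5.5, 9.0))

  empty <- withr::local_tempfile(fileext = ".narrowPeak")
  file.create(empty)
  expect_equal(nrow(read_peaks(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".narrowPeak")
  write_lines("chr1\t1\t2\t.\t0\t.", bad)
  expect_error(read_peaks(bad), "10 columns")
})

test_that("label_instances uses half-open overlap and max peak height", {
  feats <- matrix(0, 3, 1, dimnames = list(NULL, "motif_score"))
  sites <- motif_instance_set(rep("chr1", 3), c(100L, 100L, 300L),
                              c(110L, 110L, 310L), rep("+", 3),
                              c("a", "b", "c"), feats)
  # a: 1 bp overlap with [109,200); b is the same interval; c overlapped twice
  pk <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                   start = c(109L, 305L, 300L), end = c(200L, 400L, 306L),
                   signal_value = c(2, 5, 9))
  class(pk) <- c("PeakSet", "data.frame")
  lab <- label_instances(sites, pk)
  expect_equal(as.character(lab$label), c("bound", "bound", "bound"))
  expect_equal(lab$peak_height, c(2, 2, 9))

  # half-open boundary: peak starting exactly at site end does not overlap
  pk2 <- pk[1, ]; pk2$start <- 110L
  lab2 <- label_instances(sites, pk2)
  expect_equal(as.character(lab2$label), c("unbound", "unbound", "unbound"))
  expect_true(all(is.na(lab2$peak_height)))
})

test_that("labeling matches a brute-force base-by-base oracle and is peak-order invariant", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 20L
    starts <- sample(0:500, n)
    feats <- matrix(0, n, 1, dimnames = list(NULL, "motif_score"))
    sites <- motif_instance_set(rep("chr1", n), starts, starts + 8L,
                                rep("+", n), sprintf("s%d", 1:n), feats)
    m <- 8L
    ps <- sample(0:500, m); pe <- ps + sample(1:60, m, replace = TRUE)
    pk <- data.frame(chrom = rep("chr1", m), start = ps, end = pe,
                     signal_value = runif(m, 1, 10))
    class(pk) <- c("PeakSet", "data.frame")
    lab <- label_instances(sites, pk)
    # brute force: intersect base sets
    for (i in seq_len(n)) {
      bases <- seq(starts[i], starts[i] + 7L)
      hits <- vapply(seq_len(m), function(j)
        any(bases %in% seq(ps[j], pe[j] - 1L)), logical(1))
      expect_equal(lab$label[i] == "bound", any(hits))
      if (any(hits))
        expect_equal(lab$peak_height[i], max(pk$signal_value[hits]))
    }
    # permutation invariance
    perm <- sample(m)
    pk_perm <- pk[perm, ]; class(pk_perm) <- c("PeakSet", "data.frame")
    expect_equal(label_instances(sites, pk_perm), lab)
  }
})

test_that("bedGraph values expand to per-base counts and round-trip", {
  fwd <- withr::local_tempfile(fileext = ".bedGraph")
  rev <- withr::local_tempfile(fileext = ".bedGraph")
  write_lines("chr1\t5\t8\t2", fwd)
  write_lines("chr1\t0\t1\t7", rev)
  track <- load_cut_track(fwd, rev)
  expect_equal(footmix:::track_slice(track, "chr1", "+", 4, 9), c(0, 2, 2, 2, 0))
  expect_equal(footmix:::track_slice(track, "chr1", "-", 0, 2), c(7, 0))
  # missing region and missing contig both count zero
  expect_equal(footmix:::track_slice(track, "chr1", "+", 100, 103), c(0, 0, 0))
  expect_equal(footmix:::track_slice(track, "chr9", "+", 0, 2), c(0, 0))

  # round trip on a random sparse track
  set.seed(7)
  v_plus <- rpois(300, 0.3); v_minus <- rpois(300, 0.3)
  tr <- footmix:::new_cut_track(list(chrA = list("+" = v_plus, "-" = v_minus)))
  f2 <- withr::local_tempfile(fileext = ".bedGraph")
  r2 <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f2, r2)
  tr2 <- load_cut_track(f2, r2)
  expect_equal(footmix:::track_slice(tr2, "chrA", "+", 0, 300), v_plus)
  expect_equal(footmix:::track_slice(tr2, "chrA", "-", 0, 300), v_minus)
})

test_that("negative bedGraph values are rejected", {
  fwd <- withr::local_tempfile(fileext = ".bedGraph")
  rev <- withr::local_tempfile(fileext = ".bedGraph")
  write_lines("chr1\t5\t8\t-2", fwd)
  write_lines("chr1\t0\t1\t1", rev)
  expect_error(load_cut_track(fwd, rev), "negative")
})

make_sam_bam <- function(records, dir) {
  sam <- file.path(dir, "reads.sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:10000")
  writeLines(c(header, records), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

sam_record <- function(name, flag, pos1, width = 36L) {
  sprintf("%s\t%d\tchr1\t%d\t60\t%dM\t*\t0\t0\t%s\t%s", name, flag, pos1,
          width, paste(rep("A", width), collapse = ""),
          paste(rep("I", width), collapse = ""))
}

test_that("cuts_from_alignments tallies 5' tag ends strand-specifically", {
  dir <- withr::local_tempdir()
  # one + read at 1-based 51 ([50,86) 0-based) and one - read there
  bam <- make_sam_bam(c(sam_record("r1", 0L, 51L), sam_record("r2", 16L, 51L)),
                      dir)
  track <- cuts_from_alignments(bam)
  expect_equal(footmix:::track_slice(track, "chr1", "+", 50, 51), 1)
  expect_equal(footmix:::track_slice(track, "chr1", "-", 85, 86), 1)
  expect_equal(sum(footmix:::track_slice(track, "chr1", "+", 0, 10000)), 1)
  expect_equal(sum(footmix:::track_slice(track, "chr1", "-", 0, 10000)), 1)
  # reverse-strand shift knob
  track_sh <- cuts_from_alignments(bam, reverse_shift = 1L)
  expect_equal(footmix:::track_slice(track_sh, "chr1", "-", 86, 87), 1)
})

test_that("BAM ingestion matches a per-record oracle and bedGraph ingestion", {
  set.seed(11)
  n <- 100L
  pos1 <- sort(sample(100:2000, n, replace = TRUE))
  flags <- sample(c(0L, 16L), n, replace = TRUE)
  dir <- withr::local_tempdir()
  bam <- make_sam_bam(vapply(seq_len(n), function(i)
    sam_record(sprintf("r%03d", i), flags[i], pos1[i]), character(1)), dir)
  track <- cuts_from_alignments(bam)
  # brute-force tally: + reads cut at pos-1 (0-based), - reads at pos+36-2
  exp_plus <- table(pos1[flags == 0L] - 1L)
  exp_minus <- table(pos1[flags == 16L] + 34L)
  for (p in as.integer(names(exp_plus)))
    expect_equal(footmix:::track_slice(track, "chr1", "+", p, p + 1L),
                 as.numeric(exp_plus[as.character(p)]))
  for (p in as.integer(names(exp_minus)))
    expect_equal(footmix:::track_slice(track, "chr1", "-", p, p + 1L),
                 as.numeric(exp_minus[as.character(p)]))
  expect_equal(sum(footmix:::track_slice(track, "chr1", "+", 0, 10000)),
               sum(flags == 0L))

  # same fragment set via bedGraph gives the identical track
  f <- withr::local_tempfile(fileext = ".bedGraph")
  r <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(track, f, r)
  track2 <- load_cut_track(f, r)
  expect_equal(footmix:::track_slice(track2, "chr1", "+", 0, 3000),
               footmix:::track_slice(track, "chr1", "+", 0, 3000))
  expect_equal(footmix:::track_slice(track2, "chr1", "-", 0, 3000),
               footmix:::track_slice(track, "chr1", "-", 0, 3000))
})

test_that("cuts_from_alignments requires an index", {
  dir <- withr::local_tempdir()
  bam <- make_sam_bam(sam_record("r1", 0L, 51L), dir)
  file.remove(paste0(bam, ".bai"))
  expect_error(cuts_from_alignments(bam), "index")
})

test_that("posterior TSV and model JSON round-trip", {
  feats <- matrix(c(1, 2), 2, 1, dimnames = list(NULL, "motif_score"))
  sites <- toy_sites(feats)
  post <- matrix(c(0.25, 0.75, 0.9, 0.1), 2, 2, byrow = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_posteriors(sites, post, path)
  back <- read_posteriors(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$state_0 + back$state_1, c(1, 1))
  expect_equal(back$p_bound, 1 - post[, 1], tolerance = 1e-6)
  expect_error(write_posteriors(sites, post[1, , drop = FALSE], path),
               "rows")

  params <- tiny_params(K = 1L)
  mpath <- withr::local_tempfile(fileext = ".json")
  save_model(params, mpath)
  back_params <- load_model(mpath)
  for (k in seq_along(params$states)) for (s in c("fwd", "rev")) {
    expect_equal(back_params$states[[k]][[s]]$p, params$states[[k]][[s]]$p,
                 tolerance = 1e-12)
    expect_equal(back_params$states[[k]][[s]]$lambda,
                 params$states[[k]][[s]]$lambda, tolerance = 1e-12)
  }
  expect_equal(back_params$prior$beta0, params$prior$beta0, tolerance = 1e-12)
  expect_equal(unname(back_params$prior$beta), unname(params$prior$beta),
               tolerance = 1e-12)
  expect_equal(back_params$delta, params$delta)
})
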