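test_that("motif validation and basic scanning behave as specified", {
  expect_error(iupac_motif("ACGX"), "invalid IUPAC")
  expect_equal(iupac_motif()$length, 19L)

  # consensus with Y resolved to C is a zero-mismatch forward hit
  hits <- scan_motif(paste0("AAAA", "GGGCCCGTTTGGGGCAGCT", "AAAA"),
                     max_mismatch = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$end - hits$start, 19L)
  expect_identical(hits$orientation, "forward")
  expect_equal(hits$mismatches, 0L)

  expect_equal(nrow(scan_motif(strrep("A", 200), max_mismatch = 0)), 0L)
})

test_that("scan_motif equals the exhaustive degenerate scan", {
  set.seed(11)
  seq <- rand_seq(10000)
  # plant a few motif instances, one with mismatches, one reverse
  motif <- "GGGYCYGTTTGGGGCAGCT"
  inst <- gsub("Y", "T", motif)
  substr(seq, 2001, 2019) <- inst
  substr(seq, 5001, 5019) <- paste0("TT", substr(inst, 3, 19))  # 2 mismatches
  substr(seq, 8001, 8019) <- rc_oracle(inst)
  got <- scan_motif(seq, motif, max_mismatch = 2)
  want <- oracle_scan(seq, motif, 2)
  expect_equal(got[, c("start", "end", "orientation", "mismatches")],
               want, ignore_attr = TRUE)
  expect_gte(nrow(got), 3L)
})

test_that("scanning the reverse complement mirrors the hit set", {
  set.seed(12)
  seq <- rand_seq(4000)
  inst <- gsub("Y", "C", "GGGYCYGTTTGGGGCAGCT")
  substr(seq, 501, 519) <- inst
  substr(seq, 3001, 3019) <- rc_oracle(inst)
  h1 <- scan_motif(seq, max_mismatch = 1)
  h2 <- scan_motif(rc_oracle(seq), max_mismatch = 1)
  n <- nchar(seq)
  mirrored <- data.frame(start = n - h1$end, end = n - h1$start,
                         orientation = ifelse(h1$orientation == "forward",
                                              "reverse", "forward"),
                         mismatches = h1$mismatches)
  mirrored <- mirrored[order(mirrored$start, mirrored$orientation), ]
  expect_equal(h2[, c("start", "end", "orientation", "mismatches")],
               mirrored, ignore_attr = TRUE)
})

test_that("inverted-repeat discovery matches the naive oracle", {
  # planted 19-bp IR separated by 1 kb is recovered at its coordinates
  set.seed(21)
  arm <- rand_seq(19)
  region <- paste0(rand_seq_without(200, c(arm, rc_oracle(arm))), arm,
                   rand_seq_without(1000, c(arm, rc_oracle(arm))),
                   rc_oracle(arm),
                   rand_seq_without(200, c(arm, rc_oracle(arm))))
  ir <- discover_inverted_repeats(region, min_match = 19)
  hit <- ir[ir$arm_length >= 19, , drop = FALSE]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$left_start, 200L)
  expect_equal(hit$right_end, 200L + 19L + 1000L + 19L)

  # shorter than two arms -> empty
  expect_equal(nrow(discover_inverted_repeats("ACGTACGT", min_match = 5)), 0L)
  expect_error(discover_inverted_repeats("ACGT", min_match = 2), "min_match")

  # random region equals the O(n^2) brute force
  for (seed in c(31, 32)) {
    set.seed(seed)
    region <- rand_seq(500)
    got <- discover_inverted_repeats(region, min_match = 5, max_span = 400)
    want <- oracle_inverted_repeats(region, 5, 400)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("TIR pairing respects the span window and one-use rule", {
  tir <- gsub("Y", "C", "GGGYCYGTTTGGGGCAGCT")
  set.seed(41)
  mk <- function(gap) {
    paste0(rand_seq(100), tir, rand_seq(gap), rc_oracle(tir), rand_seq(100))
  }
  # right TIR ending ~35 kb downstream: no pair
  far <- mk(35000)
  hits <- scan_motif(far, max_mismatch = 0)
  expect_equal(nrow(pair_tirs(hits, far)), 0L)
  # ~5 kb downstream: one pair
  near <- mk(5000)
  hits <- scan_motif(near, max_mismatch = 0)
  cand <- pair_tirs(hits, near)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$span, 19L + 5000L + 19L)

  # a single hit yields nothing
  single <- paste0(rand_seq(100), tir, rand_seq(100))
  expect_equal(nrow(pair_tirs(scan_motif(single, max_mismatch = 0), single)), 0L)
})

test_that("pairing prefers the TSD-valid partner", {
  tir <- gsub("Y", "C", "GGGYCYGTTTGGGGCAGCT")
  set.seed(43)
  avoid <- c(tir, rc_oracle(tir))
  # forward TIR at 100; reverse TIRs at 600 and 900; only the 900 pairing
  # has matching 3-bp flanks
  g <- paste0(rand_seq_without(97, avoid), "TTA", tir,
              rand_seq_without(481, avoid), rc_oracle(tir), "GGC",
              rand_seq_without(278, avoid), rc_oracle(tir), "TTA",
              rand_seq_without(100, avoid))
  hits <- scan_motif(g, max_mismatch = 0)
  expect_equal(nrow(hits), 3L)
  cand <- pair_tirs(hits, g, min_span = 50)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$right_start, 900L)
  expect_true(cand$tsd_valid)
  expect_identical(cand$tsd_left, "TTA")
})

test_that("TSD extraction validates flanks and handles scaffold edges", {
  g <- paste0("TTA", strrep("G", 20), "TTA")
  r <- extract_tsd(g, left_start = 3, right_end = 23)
  expect_identical(r$tsd_left, "TTA")
  expect_identical(r$tsd_right, "TTA")
  expect_true(r$tsd_valid)

  g2 <- paste0("TTA", strrep("G", 20), "GGC")
  expect_false(extract_tsd(g2, 3, 23)$tsd_valid)

  # element flush with the scaffold edge -> sentinel
  edge <- extract_tsd(strrep("G", 10), left_start = 1, right_end = 9)
  expect_identical(edge$tsd_left, "NNN")
  expect_false(edge$tsd_valid)
})

test_that("validity flags match planted truth on mixed constructions", {
  set.seed(44)
  for (i in 1:10) {
    valid <- i %% 2 == 0
    tsd <- rand_seq(3)
    other <- if (valid) tsd else rand_seq(3)
    inner <- rand_seq(30)
    g <- paste0(rand_seq(20), tsd, inner, other, rand_seq(20))
    r <- extract_tsd(g, left_start = 23, right_end = 53)
    expect_identical(r$tsd_valid, identical(tsd, other))
  }
})

test_that("clean synthetic candidates coincide with planted coordinates", {
  sp <- synthetic_spec(genome_length = 80000, seed = 77,
                       class_counts = c(AUTONOMOUS = 2, MITE_LIKE = 6),
                       mutation_rate = 0, n_genes = 0,
                       variant_extra_insertions = 0)
  ds <- generate_dataset(sp, withr::local_tempdir())
  hits <- scan_motif(ds$genome, max_mismatch = 0)
  cand <- pair_tirs(hits, ds$genome)
  expect_equal(nrow(cand), nrow(ds$truth))
  cand <- cand[order(cand$left_start), ]
  tr <- ds$truth[order(ds$truth$start), ]
  expect_equal(cand$left_start, tr$start)
  expect_equal(cand$right_end, tr$end)
  expect_true(all(cand$tsd_valid))
  expect_true(all(cand$tsd_left == "TTA"))
})
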