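test_that("footprint overlap with the top set is a plain set intersection", {
  top <- c(12L, 15L, 18L, 40L)
  expect_equal(overlap_with_top_set(10L, 19L, top), 3L)
  expect_equal(overlap_with_top_set(10L, 19L, integer(0)), 0L) # empty set
  expect_equal(overlap_with_top_set(10L, 19L, 5:45), 10L)      # saturation
  expect_error(overlap_with_top_set(19L, 10L, top))
})

make_matches <- function(starts, ends, strand = "+", sid = "w1",
                         motif = "M1", score = 20) {
  data.frame(sequence_id = sid, chrom = "chr1", start = starts, end = ends,
             strand = strand, score = score, motif_id = motif,
             stringsAsFactors = FALSE)
}

test_that("functional calls require the overlap clause on top of the cutoff", {
  # worked example: overlaps {2, 3, 5} -> exactly {3, 5} are functional
  top_sets <- list(w1 = c(5L, 6L, 10L, 11L, 12L, 30L, 31L, 40L))
  m <- make_matches(starts = c(11L, 10L, 28L), ends = c(22L, 21L, 39L))
  # overlaps: {11,12} = 2; {10,11,12} = 3; {30,31,40}... check: 28..39 -> {30,31}
  m$end[3] <- 41L # 28..41 covers {30, 31, 40} = 3... widen to 5 via more top positions
  top_sets$w1 <- c(5L, 6L, 10L, 11L, 12L, 30L, 31L, 32L, 33L, 40L)
  # overlaps now: m1 {11,12}=2, m2 {10,11,12}=3, m3 {30,31,32,33,40}=5
  fc <- call_functional(m, top_sets, min_overlap = 3L)
  expect_equal(fc$calls$overlap_count[order(fc$calls$start)], c(3L, 2L, 5L))
  expect_equal(sum(fc$calls$functional), 2L)
  expect_equal(min(fc$calls$overlap_count[fc$calls$functional]), 3L)
  # both clauses hold on every emitted functional call
  expect_true(all(fc$calls$score[fc$calls$functional] >= 20))
  expect_true(all(fc$calls$overlap_count[fc$calls$functional] >= 3L))

  # vacuous threshold: every match is functional
  fc0 <- call_functional(m, top_sets, min_overlap = 0L)
  expect_true(all(fc0$calls$functional))

  # monotonicity: raising min_overlap never increases the functional count
  counts <- vapply(0:6, function(k) {
    sum(call_functional(m, top_sets, min_overlap = k)$calls$functional)
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))

  # strand does not change the overlap count
  fm <- call_functional(make_matches(10L, 21L, strand = "-"), top_sets, 3L)
  fp <- call_functional(make_matches(10L, 21L, strand = "+"), top_sets, 3L)
  expect_equal(fm$calls$overlap_count, fp$calls$overlap_count)

  # per-motif summary counts
  expect_equal(fc$summary$n_matches, 3L)
  expect_equal(fc$summary$n_functional, 2L)

  # missing top set for a match is a pairing error
  expect_error(call_functional(make_matches(1L, 12L, sid = "w2"), top_sets),
               "no top-position set")

  # determinism: identical inputs give identical call tables
  expect_identical(call_functional(m, top_sets, 3L),
                   call_functional(m, top_sets, 3L))
})

test_that("genomic matches are converted to window coordinates via offsets", {
  top_sets <- list(w1 = 1:12)
  m <- make_matches(1001L, 1012L)
  fc <- call_functional(m, top_sets, 3L,
                        match_offsets = c(w1 = 1001L))
  expect_equal(fc$calls$overlap_count, 12L)
  expect_true(fc$calls$functional)
})

test_that("recovery reporting scores calls against planted truth", {
  truth <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(100L, 500L, 100L), end = c(111L, 511L, 111L),
                      motif_id = c("M1", "M1", "M2"), strand = "+")
  perfect <- data.frame(sequence_id = "x", chrom = truth$chrom,
                        start = truth$start, end = truth$end, strand = "+",
                        score = 20, motif_id = truth$motif_id,
                        overlap_count = 5L, functional = TRUE)
  r <- recovery_report(perfect, truth)
  expect_equal(r$precision, rep(1, 3))
  expect_equal(r$recall, rep(1, 3))
  expect_equal(r$f1, rep(1, 3))

  # no calls: recall 0, precision reported as 0 and flagged undefined
  r0 <- recovery_report(perfect[0, ], truth)
  pooled <- r0[r0$motif_id == "pooled", ]
  expect_equal(pooled$recall, 0)
  expect_equal(pooled$precision, 0)
  expect_false(pooled$precision_defined)

  # motif identity matters: a call on the wrong motif is a false positive
  wrong <- perfect[3, ]; wrong$motif_id <- "M1"
  r2 <- recovery_report(rbind(perfect[1:2, ], wrong), truth)
  m1 <- r2[r2$motif_id == "M1", ]
  expect_equal(m1$n_calls, 3L)
  expect_equal(m1$n_tp_calls, 2L)
  expect_equal(m1$precision, 2 / 3)
  expect_equal(r2[r2$motif_id == "M2", "recall"], 0)

  # tolerance widens the match window
  near <- perfect[1, ]; near$start <- 113L; near$end <- 124L # gap of 1 bp
  expect_equal(recovery_report(near, truth[1, ], tolerance_bp = 0L)$n_tp_calls[1], 0L)
  expect_equal(recovery_report(near, truth[1, ], tolerance_bp = 2L)$n_tp_calls[1], 1L)

  # non-functional calls are ignored
  nf <- perfect; nf$functional <- FALSE
  r3 <- recovery_report(nf, truth)
  expect_equal(r3[r3$motif_id == "pooled", "n_calls"], 0L)
})
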