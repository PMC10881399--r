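test_that("JASPAR parsing, pseudocounts and serialisation behave", {
  # degenerate toy matrix without pseudocount: hard 0/1 frequencies
  toy <- toy_pwm(pseudocount_frac = 0)
  expect_equal(unname(toy$freq[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(toy$freq[, 2]), c(0, 1, 0, 0))
  expect_equal(toy$width, 2L)

  # uniform counts + uniform background => all log-odds are 0
  flat <- flat_pwm()
  expect_equal(unname(flat$log_odds), matrix(0, 4, 5))

  # frequencies always renormalise to 1 per column
  pwms <- fixture_pwms()
  expect_named(pwms, c("MA0522.1-like", "MA0028.2-like"))
  for (p in pwms) {
    expect_equal(unname(colSums(p$freq)), rep(1, p$width))
    expect_equal(unname(p$log_odds), unname(log2(p$freq / 0.25)))
  }

  # write -> load round trip preserves frequencies to 1e-9
  tmp <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pwms, tmp)
  back <- load_jaspar(tmp)
  for (id in names(pwms)) {
    expect_equal(back[[id]]$freq, pwms[[id]]$freq, tolerance = 1e-9)
  }

  # malformed inputs fail with the offending line
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">M1 bad", "A [ 1 2 ]", "C [ 1 2 3 ]",
               "G [ 1 2 ]", "T [ 1 2 ]"), bad)
  expect_error(load_jaspar(bad), "line 3")
  writeLines(c(">M1 bad", "A [ 1 -2 ]", "C [ 1 2 ]",
               "G [ 1 2 ]", "T [ 1 2 ]"), bad)
  expect_error(load_jaspar(bad), "negative")
  expect_error(pwm_model(matrix(1, 3, 4), "X"), "4 rows")
})

test_that("window scoring is the log-odds sum with a strand convention", {
  # hand-computed oracle: toy matrix, pseudocount mass 0.01, uniform bg
  toy <- toy_pwm(pseudocount_frac = 0.01)
  f_hit <- (4 + 0.01 * 4 / 4) / (4 * 1.01)
  f_miss <- (0.01 * 4 / 4) / (4 * 1.01)
  expect_equal(score_window(toy, "AC"),
               log2(f_hit / 0.25) * 2)
  expect_equal(score_window(toy, "TT"),
               log2(f_miss / 0.25) * 2)

  # zero-information motif scores 0 on every window
  flat <- flat_pwm()
  set.seed(4)
  for (i in 1:5) expect_equal(score_window(flat, random_dna(5)), 0)

  # minus-strand score of a window is the score of its reverse complement
  pwm <- fixture_pwms()[[2]]
  wdw <- random_dna(pwm$width)
  sc <- scan_pwm(pwm, wdw, -Inf)
  expect_equal(sc$score[sc$strand == "-"], score_window(pwm, revcomp(wdw)))
  expect_equal(sc$score[sc$strand == "+"], score_window(pwm, wdw))

  # N makes the score undefined
  expect_true(is.na(score_window(toy, "AN")))
  expect_error(score_window(toy, "ACG"), "length")
})

test_that("scan equals exhaustive offset-by-strand enumeration", {
  pwms <- fixture_pwms()
  brute <- function(pwm, s, cutoff) {
    W <- pwm$width
    rows <- list()
    for (i in seq_len(max(nchar(s) - W + 1L, 0L))) {
      wdw <- substr(s, i, i + W - 1L)
      for (strand in c("+", "-")) {
        sc <- score_window(pwm, if (strand == "+") wdw else revcomp(wdw))
        if (!is.na(sc) && sc >= cutoff) {
          rows[[length(rows) + 1L]] <- data.frame(start = i, end = i + W - 1L,
                                                  strand = strand, score = sc)
        }
      }
    }
    if (!length(rows)) return(data.frame(start = integer(0), end = integer(0),
                                         strand = character(0), score = numeric(0)))
    df <- do.call(rbind, rows)
    df <- df[order(df$start, df$strand), ]
    rownames(df) <- NULL
    df
  }
  set.seed(21)
  for (i in 1:50) {
    pwm <- pwms[[1 + i %% 2]]
    s <- random_dna(sample(20:100, 1))
    cutoff <- runif(1, -5, 10)
    got <- scan_pwm(pwm, s, cutoff)
    want <- brute(pwm, s, cutoff)
    expect_equal(got[, c("start", "end", "strand", "score")], want)
  }
})

test_that("scan respects strand symmetry, cutoffs and short sequences", {
  pwm <- fixture_pwms()[[2]] # non-palindromic ETS motif
  set.seed(9)
  s <- paste0(random_dna(20), "AACCGGAAGTGT", random_dna(18)) # planted at 21..32
  hits <- scan_pwm(pwm, s, 15)
  expect_equal(hits$start, 21L)
  expect_equal(hits$end, 32L)
  expect_equal(hits$strand, "+")

  # scanning the reverse complement mirrors coordinates and flips strands
  rc_hits <- scan_pwm(pwm, revcomp(s), 15)
  expect_equal(rc_hits$start, nchar(s) - hits$end + 1L)
  expect_equal(rc_hits$strand, "-")

  expect_equal(nrow(scan_pwm(pwm, s, Inf)), 0L) # infinite cutoff
  expect_equal(nrow(scan_pwm(pwm, "ACGT", 0)), 0L) # shorter than the motif

  # genomic offset shifts coordinates
  g <- scan_pwm(pwm, s, 15, sequence_id = "w1", chrom = "chr2", offset = 1001L)
  expect_equal(g$start, 1021L)
  expect_equal(g$chrom, "chr2")
})

test_that("cutoff calibration bounds the recomputed FPR and is monotone", {
  pwm <- fixture_pwms()[[1]]
  set.seed(6)
  bg <- vapply(1:1500, function(i) random_dna(120, gc = 0.41), character(1))

  cal <- calibrate_cutoff(pwm, bg, target_fpr = 0.01)
  expect_s3_class(cal, "cutoff_calibration")
  # direct recount at the returned cutoff
  best <- vapply(bg, function(s) {
    hits <- scan_pwm(pwm, s, -Inf)
    max(hits$score)
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(cal$achieved_fpr, mean(best >= cal$cutoff))
  expect_lt(cal$achieved_fpr, 0.01)
  expect_equal(cal$n_background_windows, 1500L)

  # lowering the target never lowers the cutoff
  cal_loose <- calibrate_cutoff(pwm, bg, target_fpr = 0.05)
  expect_gte(cal$cutoff, cal_loose$cutoff)
  expect_lt(cal_loose$achieved_fpr, 0.05)

  # vacuous bound: everything passes at the minimum observed score
  cal1 <- calibrate_cutoff(pwm, bg, target_fpr = 1)
  expect_equal(cal1$cutoff, min(best))
  expect_equal(cal1$achieved_fpr, 1)

  # separable case: cutoff splits planted consensus from background exactly
  cons <- "AAACAGCTGTTT"
  expect_gte(score_window(pwm, cons), cal$cutoff)

  # too few windows for the requested FPR resolution
  expect_error(calibrate_cutoff(pwm, bg[1:50], target_fpr = 0.01), "at least")
})
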