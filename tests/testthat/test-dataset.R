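test_that("positive-set filter applies the tag cutoff inclusively and drops sex chromosomes", {
  genome <- generate_genome(genome_config(c(chr1 = 5000L, chrX = 5000L), seed = 2))
  peaks <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr1", "chrX"),
                      start = c(501L, 1001L, 1501L, 2001L, 501L),
                      end = c(800L, 1300L, 1800L, 2300L, 800L),
                      peak_id = paste0("p", 1:5),
                      tag_count = c(10L, 31L, 32L, 100L, 500L))
  cfg <- dataset_config()
  pos <- build_positives(peaks, genome, cfg)
  expect_equal(nrow(pos), 2L) # tags {32, 100} survive; 31 and chrX do not
  expect_true(all(pos$tag_count >= 32L))
  expect_false(any(pos$chrom %in% c("chrX", "chrY")))
  expect_true(all(nchar(pos$sequence) == 300L))
  expect_true(all(pos$label == 1L))

  # windows are centred on the peak midpoint
  expect_equal(pos$start, floor((peaks$start[3:4] + peaks$end[3:4]) / 2) - 149L)

  # empty input gives an empty, correctly-typed result
  expect_equal(nrow(build_positives(peaks[0, ], genome, cfg)), 0L)

  # a window running past the chromosome end is dropped with a warning
  edge <- data.frame(chrom = "chr1", start = 4801L, end = 4990L,
                     peak_id = "pe", tag_count = 99L)
  expect_warning(out <- build_positives(edge, genome, cfg), "chromosome end")
  expect_equal(nrow(out), 0L)
})

test_that("negative sampling is balanced, GC-bin-matched and avoids positives", {
  w <- small_world()
  pos <- w$positives
  cfg <- w$dataset_config
  neg <- sample_gc_matched_negatives(w$genome, pos, cfg)

  expect_equal(nrow(neg), nrow(pos)) # class balance, always
  expect_true(all(neg$label == 0L))
  expect_false(any(neg$chrom %in% cfg$excluded_chromosomes))

  # per-pair bin matching: every negative lands in its positive's 2% bin,
  # hence within one bin width of the bin centre
  bin <- function(g) pmin(floor(g / cfg$gc_bin_width), 49)
  expect_equal(bin(neg$gc), bin(pos$gc))
  centres <- (bin(pos$gc) + 0.5) * cfg$gc_bin_width
  expect_true(all(abs(neg$gc - centres) <= cfg$gc_bin_width))

  # distribution match at bin resolution: identical histograms, so the
  # binned Kolmogorov-Smirnov distance is 0 <= bin width
  expect_equal(table(bin(neg$gc)), table(bin(pos$gc)))
  edges <- seq(0, 1, by = cfg$gc_bin_width)
  ks_binned <- max(abs(stats::ecdf(pos$gc)(edges) - stats::ecdf(neg$gc)(edges)))
  expect_lte(ks_binned, cfg$gc_bin_width)

  # no negative overlaps any positive window
  for (cm in unique(neg$chrom)) {
    p <- pos[pos$chrom == cm, ]
    n <- neg[neg$chrom == cm, ]
    for (i in seq_len(nrow(n))) {
      expect_false(any(n$start[i] <= p$end & n$end[i] >= p$start))
    }
  }

  # determinism under the configuration seed
  expect_identical(neg, sample_gc_matched_negatives(w$genome, pos, cfg))

  # an infeasible GC bin raises a sampling error naming the bin
  pos_bad <- pos[1, ]
  pos_bad$gc <- 0.99
  cfg_fast <- cfg; cfg_fast$negative_retry_cap <- 200L
  expect_error(sample_gc_matched_negatives(w$genome, pos_bad, cfg_fast),
               "GC bin")

  # empty positive set: empty negative set with a warning, not an error
  expect_warning(none <- sample_gc_matched_negatives(w$genome, pos[0, ], cfg),
                 "no positives")
  expect_equal(nrow(none), 0L)
})

test_that("splits are a function of chromosome only and partition the examples", {
  cfg <- dataset_config()
  ex <- data.frame(chrom = c("chr1", "chr8", "chr9", "chr2", "chr8"))
  sp <- assign_splits(ex, cfg)
  expect_equal(as.character(sp$split),
               c("train", "validation", "test", "train", "validation"))

  w <- small_world()
  exs <- w$examples
  expect_true(all(exs$split[exs$chrom == "chr8"] == "validation"))
  expect_true(all(exs$split[exs$chrom == "chr9"] == "test"))
  expect_true(all(exs$split[!exs$chrom %in% c("chr8", "chr9")] == "train"))
  # no interval appears in more than one split
  key <- paste(exs$chrom, exs$start, exs$end)
  expect_equal(anyDuplicated(key), 0L)

  expect_error(dataset_config(validation_chromosome = "chr9",
                              test_chromosome = "chr9"), "differ")
})

test_that("one-hot encoding is canonical and reverse-complement compatible", {
  m <- encode_onehot("ACGT")
  expect_equal(unname(m), diag(4))
  expect_equal(unname(encode_onehot("N")), matrix(0.25, 1, 4))
  expect_error(encode_onehot("ACGB"), "illegal character")
  expect_equal(rowSums(encode_onehot("ACGTN")), rep(1, 5))

  # encode(revcomp(s)) equals row-reversal + A<->T, C<->G column swap
  set.seed(42)
  for (i in 1:10) {
    s <- random_dna(20)
    direct <- encode_onehot(revcomp(s))
    swapped <- encode_onehot(s)[20:1, c(4, 3, 2, 1)]
    dimnames(swapped) <- dimnames(direct)
    expect_equal(direct, swapped)
  }
})
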