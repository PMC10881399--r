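test_that("generated genomes respect composition, length and determinism", {
  # degenerate composition: gc = 0 gives AT-only sequence
  g0 <- generate_genome(genome_config(c(chrT = 10L), gc_content = 0, seed = 3))
  expect_equal(nchar(g0[["chrT"]]), 10L)
  expect_true(grepl("^[AT]+$", g0[["chrT"]]))

  # observed GC converges to the target (binomial SE ~ 0.0016 at n = 1e5)
  cfg <- genome_config(c(chrT = 100000L), gc_content = 0.5, seed = 1)
  g <- generate_genome(cfg)
  expect_lt(abs(gc_fraction(g[["chrT"]]) - 0.5), 0.02)

  # identical config + seed => byte-identical genome; different seed differs
  expect_identical(g, generate_genome(cfg))
  cfg2 <- cfg; cfg2$seed <- 2L
  expect_false(identical(g, generate_genome(cfg2)))

  expect_error(genome_config(c(chrT = 100L), gc_content = 1.5), "gc_content")
  expect_error(genome_config(c(chrT = 0L)), "positive")
  expect_error(genome_config(c(100L)), "named")
})

test_that("planting writes PWM instances with a complete, consistent truth table", {
  pwms <- fixture_pwms()
  gcfg <- genome_config(c(chr1 = 30000L, chr2 = 30000L), seed = 11)
  genome <- generate_genome(gcfg)

  # count conservation: n_active x |pwms| x instances
  pcfg <- peakset_config(n_active_peaks = 10L, n_inactive_peaks = 5L, seed = 12)
  pl <- plant_enhancers(genome, pwms, pcfg)
  expect_equal(nrow(pl$truth), 10L * 2L * 1L)
  expect_equal(nrow(pl$peaks), 15L)
  expect_equal(sum(pl$peaks$active), 10L)

  # every truth interval matches the genome (reverse-complemented on -)
  for (i in seq_len(nrow(pl$truth))) {
    fwd <- substr(pl$genome[[pl$truth$chrom[i]]],
                  pl$truth$start[i], pl$truth$end[i])
    want <- if (pl$truth$strand[i] == "+") pl$truth$sampled_sequence[i] else
      revcomp(pl$truth$sampled_sequence[i])
    expect_identical(fwd, want)
    expect_equal(pl$truth$end[i] - pl$truth$start[i] + 1L,
                 nchar(pl$truth$sampled_sequence[i]))
  }

  # instances lie inside their active peaks, which do not overlap each other
  act <- pl$peaks[pl$peaks$active, ]
  for (i in seq_len(nrow(pl$truth))) {
    expect_true(any(act$chrom == pl$truth$chrom[i] &
                      act$start <= pl$truth$start[i] &
                      act$end >= pl$truth$end[i]))
  }
  by_chrom <- split(pl$peaks, pl$peaks$chrom)
  for (pk in by_chrom) {
    pk <- pk[order(pk$start), ]
    if (nrow(pk) > 1L) expect_true(all(pk$start[-1] > pk$end[-nrow(pk)]))
  }

  # no-op planting: zero instances leaves the genome untouched
  pl0 <- plant_enhancers(genome, pwms,
                         peakset_config(n_active_peaks = 10L,
                                        n_inactive_peaks = 5L,
                                        motifs_per_active_peak = 0L, seed = 12))
  expect_equal(nrow(pl0$truth), 0L)
  expect_identical(pl0$genome, genome)

  # determinism of the whole generator
  pl2 <- plant_enhancers(genome, pwms, pcfg)
  expect_identical(pl, pl2)
})

test_that("impossible motif packing raises a generation error", {
  pwms <- fixture_pwms()
  genome <- generate_genome(genome_config(c(chr1 = 5000L), seed = 4))
  # 13 instances x 12 bp cannot fit without overlap in a 30 bp peak
  cfg <- peakset_config(n_active_peaks = 1L, n_inactive_peaks = 0L,
                        peak_length = 30L, motifs_per_active_peak = 13L,
                        seed = 4)
  expect_error(plant_enhancers(genome, pwms, cfg), "non-overlapping motif")
  # motif as wide as the peak is rejected up front
  cfg2 <- peakset_config(n_active_peaks = 1L, n_inactive_peaks = 0L,
                         peak_length = 12L, seed = 4)
  expect_error(plant_enhancers(genome, pwms, cfg2), "peak_length")
})

test_that("fixtures round-trip losslessly through the writers and readers", {
  pwms <- fixture_pwms()
  genome <- generate_genome(genome_config(c(chr1 = 20000L, chr2 = 15000L), seed = 5))
  pl <- plant_enhancers(genome, pwms,
                        peakset_config(n_active_peaks = 3L, n_inactive_peaks = 2L,
                                       seed = 6))
  dir <- withr::local_tempdir()
  paths <- write_fixture(pl$genome, pl$peaks, pl$truth, dir)

  expect_identical(read_genome_fasta(paths[["genome"]]), pl$genome)

  pk <- read_peak_table(paths[["peaks"]])
  expect_equal(pk$start, pl$peaks$start)
  expect_equal(pk$end, pl$peaks$end)
  expect_equal(pk$tag_count, pl$peaks$tag_count)
  expect_equal(nrow(pk), 5L) # one data line per peak

  tr <- read_motif_truth(paths[["truth"]], genome = pl$genome)
  expect_equal(tr$start, pl$truth$start)
  expect_equal(tr$strand, pl$truth$strand)
  # truth consistency: re-extracted sequences equal the sampled ones
  expect_identical(tr$sampled_sequence, pl$truth$sampled_sequence)

  # empty peak and truth tables produce valid zero-record files
  empty <- pl$peaks[0, ]
  paths2 <- write_fixture(pl$genome, empty, pl$truth[0, ], dir)
  expect_equal(nrow(read_peak_table(paths2[["peaks"]])), 0L)
  expect_equal(nrow(read_motif_truth(paths2[["truth"]])), 0L)
})
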