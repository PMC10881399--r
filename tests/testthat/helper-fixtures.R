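# Shared fixtures, built once per test run and cached. Everything is
# generated in code; nothing is read from outside the package.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

fixture_jaspar <- function() {
  system.file("extdata", "synthetic_tcf3_elk1.jaspar", package = "enhancerlift")
}

fixture_pwms <- function() memo("pwms", load_jaspar(fixture_jaspar()))

# A toy 2-column PWM with degenerate columns (consensus "AC").
toy_pwm <- function(pseudocount_frac = 0) {
  counts <- matrix(c(4, 0, 0, 0,
                     0, 4, 0, 0), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm_model(counts, "TOY01", pseudocount_frac = pseudocount_frac)
}

# Zero-information motif: uniform counts in every column.
flat_pwm <- function(width = 5) {
  pwm_model(matrix(10, 4, width), "FLAT01")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A small planted-motif world: genome, peaks, labelled examples and one
# trained single-member classifier. Used by classifier and attribution
# tests; ~15 s to build, cached for the whole run.
small_world <- function() {
  memo("small_world", {
    gcfg <- genome_config(c(stats::setNames(rep(40000L, 6L), paste0("chr", 1:6)),
                            chr8 = 40000L, chr9 = 40000L, chrX = 8000L),
                          gc_content = 0.41, seed = 401)
    genome <- generate_genome(gcfg)
    pcfg <- peakset_config(n_active_peaks = 280L, n_inactive_peaks = 280L,
                           seed = 402)
    planted <- plant_enhancers(genome, fixture_pwms(), pcfg)
    dcfg <- dataset_config(seed = 403)
    pos <- build_positives(planted$peaks, planted$genome, dcfg)
    neg <- sample_gc_matched_negatives(planted$genome, pos, dcfg,
                                       avoid = planted$peaks[planted$peaks$active, ])
    examples <- assign_splits(rbind(pos, neg), dcfg)
    model <- train_classifier(examples[examples$split == "train", ],
                              examples[examples$split == "validation", ],
                              classifier_config(epochs = 40L, seed = 404))
    list(genome = planted$genome, peaks = planted$peaks,
         truth = planted$truth, examples = examples,
         positives = pos, model = model, dataset_config = dcfg)
  })
}

# A model that outputs the same probability for every input (all-zero
# parameters): importance scores must vanish identically.
constant_model <- function() {
  memo("constant_model", {
    m <- small_world()$model
    m$params <- lapply(m$params, function(p) p * 0)
    m
  })
}

# The default-scale study conditions used by the acceptance tests: one full
# pipeline run at global seed 1 (cached; ~3 min).
default_run <- function() {
  memo("default_run", run_pipeline(pipeline_config(seed = 1L), verbose = FALSE))
}

# The default-scale labelled dataset exactly as the seed-1 pipeline builds
# it (stage seeds derived the same way).
default_examples <- function() {
  memo("default_examples", {
    ds <- enhancerlift:::derive_seed
    cfg <- pipeline_config(seed = 1L)
    gcfg <- cfg$genome; gcfg$seed <- ds(1L, "genome")
    genome <- generate_genome(gcfg)
    pcfg <- cfg$peaks; pcfg$seed <- ds(1L, "peaks")
    planted <- plant_enhancers(genome, fixture_pwms(), pcfg)
    dcfg <- cfg$dataset; dcfg$seed <- ds(1L, "dataset")
    pos <- build_positives(planted$peaks, planted$genome, dcfg)
    neg <- sample_gc_matched_negatives(planted$genome, pos, dcfg,
                                       avoid = planted$peaks[planted$peaks$active, ])
    assign_splits(rbind(pos, neg), dcfg)
  })
}

# Tiny pipeline configuration for orchestration tests (~40 s per run).
tiny_pipeline_config <- function(seed = 7L, ...) {
  pipeline_config(
    genome = genome_config(c(stats::setNames(rep(12000L, 4L), paste0("chr", 1:4)),
                             chr8 = 12000L, chr9 = 12000L, chrX = 5000L),
                           gc_content = 0.41),
    peaks = peakset_config(n_active_peaks = 40L, n_inactive_peaks = 40L),
    classifier = classifier_config(epochs = 4L),
    n_models = 1L,
    target_fpr = 0.01, n_background_windows = 1200L,
    seed = seed, ...)
}
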