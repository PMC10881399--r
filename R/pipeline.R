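# End-to-end orchestration: simulate -> build dataset -> train -> attribute
# -> calibrate + scan -> call functional motifs -> recovery report. One
# global seed deterministically derives every stage seed (derive_seed), so
# changing one stage's configuration never reshuffles another stage's
# randomness.

#' Full pipeline configuration
#'
#' Nested configurations for every stage plus pipeline-level settings. The
#' per-stage `seed` fields are overwritten at run time with seeds derived
#' from the global `seed` and the stage name.
#'
#' @param genome a [genome_config()].
#' @param peaks a [peakset_config()].
#' @param dataset a [dataset_config()].
#' @param classifier a [classifier_config()].
#' @param n_models classifier ensemble size (default 4); predictions and
#'   importance scores are averaged over members so that attributions do
#'   not depend on which of several co-occurring motifs a single network
#'   happens to exploit.
#' @param jaspar_file JASPAR-format PWM file; defaults to the synthetic
#'   TCF3/ELK1-shaped fixtures shipped with the package.
#' @param target_fpr per-window false-positive-rate target for the PWM
#'   cutoff (default 0.002).
#' @param n_background_windows background windows for calibration; must be
#'   at least `10 / target_fpr` (default 6000).
#' @param fraction top-importance fraction per window (default 0.2).
#' @param min_overlap footprint positions required inside the top set
#'   (default 3).
#' @param attribution_method `"deeplift_rescale"` or `"grad_x_input"`.
#' @param seed global integer seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(genome = genome_config(),
                            peaks = peakset_config(),
                            dataset = dataset_config(),
                            classifier = classifier_config(),
                            n_models = 4L,
                            jaspar_file = system.file("extdata",
                                                      "synthetic_tcf3_elk1.jaspar",
                                                      package = "enhancerlift"),
                            target_fpr = 0.002,
                            n_background_windows = 6000L,
                            fraction = 0.2, min_overlap = 3L,
                            attribution_method = "deeplift_rescale",
                            seed = 1L) {
  structure(list(genome = genome, peaks = peaks, dataset = dataset,
                 classifier = classifier, n_models = as.integer(n_models),
                 jaspar_file = jaspar_file,
                 target_fpr = target_fpr,
                 n_background_windows = as.integer(n_background_windows),
                 fraction = fraction, min_overlap = as.integer(min_overlap),
                 attribution_method = attribution_method,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Collects every detectable problem without side effects; an empty result
#' means the configuration is runnable.
#'
#' @param config a [pipeline_config()].
#' @return character vector of issues (length 0 when valid).
#' @export
validate_pipeline_config <- function(config) {
  issues <- character(0)
  add <- function(x) issues <<- c(issues, x)
  if (!inherits(config, "pipeline_config")) {
    return("not a pipeline_config object")
  }
  ds <- config$dataset
  if (identical(ds$validation_chromosome, ds$test_chromosome)) {
    add("validation and test chromosome are identical")
  }
  if (!ds$validation_chromosome %in% names(config$genome$chromosome_lengths)) {
    add("validation chromosome absent from the genome")
  }
  if (!ds$test_chromosome %in% names(config$genome$chromosome_lengths)) {
    add("test chromosome absent from the genome")
  }
  if (config$fraction <= 0 || config$fraction > 1) {
    add("fraction must lie in (0, 1]")
  }
  if (floor(config$fraction * ds$window_length) < 1) {
    add("fraction selects zero positions at the configured window length")
  }
  if (config$target_fpr <= 0 || config$target_fpr > 1) {
    add("target_fpr must lie in (0, 1]")
  }
  if (config$target_fpr < 1 &&
      config$n_background_windows < ceiling(10 / config$target_fpr)) {
    add(sprintf("n_background_windows (%d) below 10 / target_fpr (%d)",
                config$n_background_windows, ceiling(10 / config$target_fpr)))
  }
  if (!file.exists(config$jaspar_file)) {
    add(paste0("jaspar_file not found: ", config$jaspar_file))
  }
  if (config$min_overlap < 0) add("min_overlap must be non-negative")
  if (config$n_models < 1) add("n_models must be at least 1")
  if (config$dataset$window_length != config$classifier$window_length) {
    add("dataset and classifier window lengths differ")
  }
  if (config$genome$gc_content < 0 || config$genome$gc_content > 1) {
    add("gc_content must lie in [0, 1]")
  }
  issues
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

run_stage <- function(name, timings, verbose, expr) {
  stage_log(verbose, "stage %s ...", name)
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 2)
  list(result = res, timings = timings)
}

#' Run the full pipeline
#'
#' Executes simulate, dataset construction, training, attribution, cutoff
#' calibration, scanning, functional calling and the recovery report from a
#' single configuration. Recovery is computed against planted truth
#' intervals that lie inside the analysed (tag-filtered) positive windows.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, stage outputs (FASTA,
#'   peak/truth files, example BED, importance tracks, matches, calls,
#'   JSON report) are persisted there.
#' @param verbose log one line per stage.
#' @return list of class `pipeline_report`: configuration snapshot, dataset
#'   sizes per split, training history, validation/test auROC, per-motif
#'   calibration, match/functional-call counts, recovery table, and
#'   wall-time per stage.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  issues <- validate_pipeline_config(config)
  if (length(issues) > 0L) {
    stop("invalid pipeline configuration:\n  - ",
         paste(issues, collapse = "\n  - "))
  }
  timings <- list()

  gcfg <- config$genome
  gcfg$seed <- derive_seed(config$seed, "genome")
  st <- run_stage("genome", timings, verbose, generate_genome(gcfg))
  genome0 <- st$result; timings <- st$timings

  pwms <- load_jaspar(config$jaspar_file)

  pcfg <- config$peaks
  pcfg$seed <- derive_seed(config$seed, "peaks")
  st <- run_stage("plant", timings, verbose,
                  plant_enhancers(genome0, pwms, pcfg))
  planted <- st$result; timings <- st$timings
  genome <- planted$genome

  dcfg <- config$dataset
  dcfg$seed <- derive_seed(config$seed, "dataset")
  # negatives and calibration backgrounds avoid every active peak, not only
  # the retained positives: active peaks that fail the tag filter still
  # carry planted motif instances and would contaminate the background
  active_peaks <- planted$peaks[planted$peaks$active, , drop = FALSE]
  st <- run_stage("dataset", timings, verbose, {
    pos <- build_positives(planted$peaks, genome, dcfg)
    neg <- sample_gc_matched_negatives(genome, pos, dcfg, avoid = active_peaks)
    assign_splits(rbind(pos, neg), dcfg)
  })
  examples <- st$result; timings <- st$timings
  sizes <- table(examples$split, examples$label)

  ccfg <- config$classifier
  ccfg$seed <- derive_seed(config$seed, "classifier")
  st <- run_stage("train", timings, verbose, {
    train_ensemble(examples[examples$split == "train", ],
                   examples[examples$split == "validation", ],
                   ccfg, n_models = config$n_models, verbose = FALSE)
  })
  model <- st$result; timings <- st$timings
  validation_auroc <- evaluate_auroc(model,
                                     examples[examples$split == "validation", ])
  test_auroc <- evaluate_auroc(model, examples[examples$split == "test", ])
  stage_log(verbose, "test auROC %.4f (validation %.4f)",
            test_auroc, validation_auroc)

  positives <- examples[examples$label == 1L, , drop = FALSE]

  st <- run_stage("attribute", timings, verbose, {
    tracks <- lapply(positives$sequence, function(s) {
      importance_track(model, s, config$attribution_method)
    })
    names(tracks) <- positives$example_id
    tops <- lapply(tracks, top_fraction_positions, fraction = config$fraction)
    list(tracks = tracks, tops = tops)
  })
  attribution <- st$result; timings <- st$timings

  st <- run_stage("calibrate", timings, verbose, {
    bg <- sample_background_windows(genome, config$n_background_windows, dcfg,
                                    positives = positives,
                                    seed = derive_seed(config$seed, "background"),
                                    avoid = active_peaks)
    lapply(pwms, calibrate_cutoff, background_windows = bg,
           target_fpr = config$target_fpr,
           seed = derive_seed(config$seed, "background"),
           background_source = "gc_matched_genomic")
  })
  calibrations <- st$result; timings <- st$timings

  st <- run_stage("scan", timings, verbose, {
    res <- lapply(pwms, function(pwm) {
      cut <- calibrations[[pwm$motif_id]]$cutoff
      do.call(rbind, lapply(seq_len(nrow(positives)), function(i) {
        scan_pwm(pwm, positives$sequence[i], cut,
                 sequence_id = positives$example_id[i],
                 chrom = positives$chrom[i], offset = positives$start[i])
      }))
    })
    do.call(rbind, res)
  })
  matches <- st$result; timings <- st$timings
  if (is.null(matches)) {
    matches <- scan_pwm(pwms[[1]], "", Inf) # typed empty frame
  }

  st <- run_stage("call", timings, verbose, {
    offs <- stats::setNames(positives$start, positives$example_id)
    call_functional(matches, attribution$tops, config$min_overlap,
                    match_offsets = offs)
  })
  fcalls <- st$result; timings <- st$timings

  st <- run_stage("recover", timings, verbose, {
    tr <- planted$truth
    if (nrow(tr) > 0L) {
      keep <- vapply(seq_len(nrow(tr)), function(i) {
        any(positives$chrom == tr$chrom[i] &
              positives$start <= tr$start[i] & positives$end >= tr$end[i])
      }, logical(1))
      tr <- tr[keep, , drop = FALSE]
    }
    list(truth = tr, report = recovery_report(fcalls, tr, tolerance_bp = 0L))
  })
  recovery <- st$result; timings <- st$timings

  report <- structure(list(
    config = config,
    n_examples = as.data.frame.matrix(sizes),
    history = lapply(model$members, `[[`, "history"),
    member_val_auroc = vapply(model$members, `[[`, numeric(1), "best_val_auroc"),
    validation_auroc = validation_auroc,
    test_auroc = test_auroc,
    calibrations = lapply(calibrations, unclass),
    n_matches = nrow(fcalls$calls),
    n_functional = sum(fcalls$calls$functional),
    call_summary = fcalls$summary,
    recovery = recovery$report,
    n_truth_analysed = nrow(recovery$truth),
    timings = timings
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    persist_run(out_dir, genome, planted, examples, model, attribution,
                matches, fcalls, report)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat("  examples per split x label:\n")
  print(x$n_examples)
  cat(sprintf("  validation auROC %.4f, test auROC %.4f (%d-member ensemble)\n",
              x$validation_auroc, x$test_auroc, length(x$member_val_auroc)))
  for (cl in x$calibrations) {
    cat(sprintf("  %s: cutoff %.3f, achieved FPR %.4f%%\n",
                cl$motif_id, cl$cutoff, 100 * cl$achieved_fpr))
  }
  cat(sprintf("  %d match(es), %d functional\n", x$n_matches, x$n_functional))
  cat("  recovery vs planted truth:\n")
  print(x$recovery[, c("motif_id", "n_truth", "n_calls", "precision",
                       "recall", "f1")])
  invisible(x)
}

# Persist every stage output as plain-text files plus a JSON report.
persist_run <- function(out_dir, genome, planted, examples, model,
                        attribution, matches, fcalls, report) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fixture(genome, planted$peaks, planted$truth, out_dir)
  ex <- examples
  write.table(data.frame(ex$chrom, ex$start - 1L, ex$end, ex$example_id,
                         ex$label, ".", as.character(ex$split)),
              file.path(out_dir, "examples.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  hist <- do.call(rbind, lapply(seq_along(model$members), function(k) {
    cbind(member = k, model$members[[k]]$history)
  }))
  write.table(hist, file.path(out_dir, "training_history.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  trk <- do.call(rbind, lapply(names(attribution$tracks), function(id) {
    sc <- attribution$tracks[[id]]
    data.frame(sequence_id = id, pos = seq_along(sc), final_score = sc,
               in_top_set = as.integer(seq_along(sc) %in% attribution$tops[[id]]))
  }))
  write.table(trk, file.path(out_dir, "importance_tracks.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- fcalls$calls
  write.table(cl, file.path(out_dir, "functional_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(cl) > 0L) {
    write.table(data.frame(cl$chrom, cl$start - 1L, cl$end, cl$motif_id,
                           round(cl$score * 100), cl$strand, cl$overlap_count,
                           as.integer(cl$functional)),
                file.path(out_dir, "functional_calls.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    file.create(file.path(out_dir, "functional_calls.bed"))
  }
  rep_json <- report
  rep_json$config <- unserialise_config(report$config)
  jsonlite::write_json(unclass(rep_json),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

# configuration snapshot as plain lists for JSON/YAML serialisation
unserialise_config <- function(config) {
  rapply(unclass(config), unclass, how = "replace")
}

#' Read a pipeline configuration from YAML
#'
#' Fields mirror [pipeline_config()]; omitted fields keep their defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, values) {
    if (is.null(values)) return(ctor())
    if (!is.null(values$chromosome_lengths)) {
      values$chromosome_lengths <- unlist(values$chromosome_lengths)
    }
    do.call(ctor, values)
  }
  args <- list(genome = build(genome_config, y$genome),
               peaks = build(peakset_config, y$peaks),
               dataset = build(dataset_config, y$dataset),
               classifier = build(classifier_config, y$classifier))
  for (nm in c("jaspar_file", "target_fpr", "n_background_windows",
               "fraction", "min_overlap", "attribution_method", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  do.call(pipeline_config, args)
}
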