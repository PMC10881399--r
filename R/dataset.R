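# Labelled dataset construction: tag-count filtering, window
# standardisation, GC-matched negative sampling and chromosome-holdout
# splits. All coordinates in memory are 1-based inclusive.

#' Configuration for dataset construction
#'
#' @param window_length classifier window in bp (default 300).
#' @param min_tag_count minimum (inclusive) histone-mark tag count for a
#'   peak to enter the positive set (default 32).
#' @param excluded_chromosomes chromosomes removed entirely (default the sex
#'   chromosomes `chrX`, `chrY`).
#' @param validation_chromosome,test_chromosome held-out chromosomes
#'   (defaults chr8 and chr9); all other chromosomes train.
#' @param gc_bin_width width of the GC-fraction histogram bins used for
#'   negative matching (default 0.02, i.e. 2% bins).
#' @param max_n_fraction windows with a higher fraction of `N` bases are
#'   rejected on both sides (default 0.10).
#' @param negative_retry_cap random draws attempted per positive before the
#'   sampler gives up on a GC bin (default 10000).
#' @param seed integer seed for negative sampling.
#' @return an object of class `dataset_config`.
#' @export
dataset_config <- function(window_length = 300L, min_tag_count = 32L,
                           excluded_chromosomes = c("chrX", "chrY"),
                           validation_chromosome = "chr8",
                           test_chromosome = "chr9",
                           gc_bin_width = 0.02, max_n_fraction = 0.10,
                           negative_retry_cap = 10000L, seed = 1L) {
  if (window_length <= 0) stop("window_length must be positive")
  if (identical(validation_chromosome, test_chromosome)) {
    stop("validation and test chromosomes must differ")
  }
  structure(list(window_length = as.integer(window_length),
                 min_tag_count = as.integer(min_tag_count),
                 excluded_chromosomes = excluded_chromosomes,
                 validation_chromosome = validation_chromosome,
                 test_chromosome = test_chromosome,
                 gc_bin_width = gc_bin_width,
                 max_n_fraction = max_n_fraction,
                 negative_retry_cap = as.integer(negative_retry_cap),
                 seed = as.integer(seed)),
            class = "dataset_config")
}

gc_bin <- function(gc, width) pmin(floor(gc / width), floor(1 / width) - 1L)

#' Build the positive example set from peaks
#'
#' Retains peaks with `tag_count >= min_tag_count` whose chromosome is not
#' excluded, and standardises each to a fixed-length window centred on the
#' peak midpoint. Windows that would extend past a chromosome end, or that
#' contain more than `max_n_fraction` `N` bases, are dropped with a warning.
#'
#' @param peaks data.frame with chrom, start, end, peak_id, tag_count.
#' @param genome named character vector of chromosome sequences.
#' @param config a [dataset_config()].
#' @return data.frame of labelled examples (label = 1): chrom, start, end,
#'   example_id, sequence, gc, tag_count, label.
#' @export
build_positives <- function(peaks, genome, config) {
  stopifnot(inherits(config, "dataset_config"))
  L <- config$window_length
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      example_id = character(0), sequence = character(0),
                      gc = numeric(0), tag_count = integer(0), label = integer(0),
                      stringsAsFactors = FALSE)
  keep <- peaks$tag_count >= config$min_tag_count &
    !(peaks$chrom %in% config$excluded_chromosomes)
  pk <- peaks[keep, , drop = FALSE]
  if (nrow(pk) == 0L) return(empty)
  mid <- floor((pk$start + pk$end) / 2)
  ws <- mid - floor(L / 2) + 1L
  we <- ws + L - 1L
  lens <- vapply(genome, nchar, integer(1))
  in_bounds <- ws >= 1L & we <= lens[pk$chrom]
  if (any(!in_bounds)) {
    warning(sum(!in_bounds), " peak(s) dropped: window extends past chromosome end")
  }
  pk <- pk[in_bounds, , drop = FALSE]
  ws <- ws[in_bounds]; we <- we[in_bounds]
  if (nrow(pk) == 0L) return(empty)
  seqs <- mapply(genome_substr, pk$chrom, ws, we,
                 MoreArgs = list(genome = genome))
  ok_n <- n_fraction(seqs) <= config$max_n_fraction
  if (any(!ok_n)) {
    warning(sum(!ok_n), " peak(s) dropped: too many N bases in window")
  }
  if (!any(ok_n)) return(empty)
  data.frame(chrom = pk$chrom[ok_n], start = ws[ok_n], end = we[ok_n],
             example_id = pk$peak_id[ok_n], sequence = unname(seqs[ok_n]),
             gc = gc_fraction(seqs[ok_n]),
             tag_count = pk$tag_count[ok_n], label = 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Internal rejection sampler for genomic windows. For each entry of
# target_bin (NA = unconstrained) draws a window on a non-excluded
# chromosome that does not overlap `avoid` and lands in that GC bin.
# With relax = TRUE an exhausted bin falls back to the candidate whose GC
# came closest to the bin centre instead of erroring (used for calibration
# backgrounds, where a rare extreme bin must not abort the run).
sample_windows <- function(genome, n, target_bin, config, avoid = NULL,
                           relax = FALSE) {
  L <- config$window_length
  lens <- vapply(genome, nchar, integer(1))
  ok <- setdiff(names(lens)[lens >= L], config$excluded_chromosomes)
  if (length(ok) == 0L) stop("no eligible chromosome of length >= ", L)
  w <- lens[ok] - L + 1
  avoid_by_chrom <- if (!is.null(avoid) && nrow(avoid) > 0L) {
    split(avoid[, c("start", "end")], avoid$chrom)
  } else list()
  out <- data.frame(chrom = character(n), start = integer(n), end = integer(n),
                    sequence = character(n), gc = numeric(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    found <- FALSE
    centre <- (target_bin[i] + 0.5) * config$gc_bin_width
    best <- NULL
    best_dist <- Inf
    for (try in seq_len(config$negative_retry_cap)) {
      cm <- sample(ok, 1L, prob = w)
      s <- sample.int(lens[[cm]] - L + 1L, 1L)
      e <- s + L - 1L
      av <- avoid_by_chrom[[cm]]
      if (!is.null(av) && any(s <= av$end & e >= av$start)) next
      sq <- genome_substr(genome, cm, s, e)
      if (n_fraction(sq) > config$max_n_fraction) next
      g <- gc_fraction(sq)
      if (!is.na(target_bin[i]) &&
          gc_bin(g, config$gc_bin_width) != target_bin[i]) {
        if (relax && abs(g - centre) < best_dist) {
          best <- list(chrom = cm, start = s, end = e, sequence = sq, gc = g)
          best_dist <- abs(g - centre)
        }
        next
      }
      out$chrom[i] <- cm; out$start[i] <- s; out$end[i] <- e
      out$sequence[i] <- sq; out$gc[i] <- g
      found <- TRUE
      break
    }
    if (!found) {
      if (relax && !is.null(best)) {
        out$chrom[i] <- best$chrom; out$start[i] <- best$start
        out$end[i] <- best$end; out$sequence[i] <- best$sequence
        out$gc[i] <- best$gc
      } else {
        stop("could not sample a window for GC bin [",
             format(target_bin[i] * config$gc_bin_width), ", ",
             format((target_bin[i] + 1) * config$gc_bin_width),
             ") after ", config$negative_retry_cap, " draws")
      }
    }
  }
  out
}

#' Sample GC-content-matched negative examples
#'
#' Draws exactly one negative window per positive, labelled 0, from
#' non-excluded chromosomes, not overlapping any positive window, such that
#' each negative falls in the same GC-fraction histogram bin
#' (width `gc_bin_width`) as its paired positive. Deterministic given the
#' configuration seed.
#'
#' @param genome named character vector of chromosome sequences.
#' @param positives data.frame from [build_positives()].
#' @param config a [dataset_config()].
#' @param avoid optional data.frame (chrom, start, end) of additional
#'   intervals negatives must not overlap, e.g. candidate peaks that failed
#'   the tag filter but still carry enhancer-like sequence.
#' @return data.frame of labelled examples (label = 0) with the same columns
#'   as the positives (tag_count = NA).
#' @export
sample_gc_matched_negatives <- function(genome, positives, config, avoid = NULL) {
  stopifnot(inherits(config, "dataset_config"))
  if (nrow(positives) == 0L) {
    warning("no positives supplied; returning an empty negative set")
    return(positives)
  }
  bins <- gc_bin(positives$gc, config$gc_bin_width)
  avoid_all <- rbind(positives[, c("chrom", "start", "end")],
                     if (!is.null(avoid)) avoid[, c("chrom", "start", "end")])
  neg <- with_seed(config$seed,
                   sample_windows(genome, nrow(positives), bins, config,
                                  avoid = avoid_all))
  data.frame(chrom = neg$chrom, start = neg$start, end = neg$end,
             example_id = sprintf("neg_%05d", seq_len(nrow(neg))),
             sequence = neg$sequence, gc = neg$gc,
             tag_count = NA_integer_, label = 0L, stringsAsFactors = FALSE)
}

#' Sample background windows for cutoff calibration
#'
#' Draws `n` windows with the same machinery as the negative sampler,
#' GC-matched to the positive set's bin distribution (bins recycled over the
#' positives) when `positives` is supplied, unconstrained otherwise.
#'
#' @param genome named character vector of chromosome sequences.
#' @param n number of windows.
#' @param config a [dataset_config()].
#' @param positives optional data.frame from [build_positives()]; windows
#'   avoid these intervals and match their GC bins.
#' @param seed integer seed (defaults to the configuration seed).
#' @param avoid optional data.frame (chrom, start, end) of additional
#'   intervals to avoid (e.g. all candidate peaks, so the background is
#'   motif-free).
#' @return character vector of `n` window sequences.
#' @export
sample_background_windows <- function(genome, n, config, positives = NULL,
                                      seed = config$seed, avoid = NULL) {
  stopifnot(inherits(config, "dataset_config"))
  bins <- if (!is.null(positives) && nrow(positives) > 0L) {
    rep_len(gc_bin(positives$gc, config$gc_bin_width), n)
  } else rep(NA_integer_, n)
  avoid_all <- rbind(if (!is.null(positives) && nrow(positives) > 0L)
                       positives[, c("chrom", "start", "end")],
                     if (!is.null(avoid)) avoid[, c("chrom", "start", "end")])
  with_seed(seed, sample_windows(genome, n, bins, config,
                                 avoid = avoid_all, relax = TRUE))$sequence
}

#' Uniform-random DNA windows
#'
#' Convenience generator of i.i.d. windows (each base equiprobable at the
#' default `gc = 0.5`), e.g. as a calibration background.
#'
#' @param n number of windows.
#' @param length window length in bp.
#' @param gc GC fraction.
#' @param seed integer seed.
#' @return character vector of `n` sequences.
#' @export
random_windows <- function(n, length = 300L, gc = 0.5, seed = 1L) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(.BASES, length, replace = TRUE, prob = probs), collapse = "")
  }, character(1)))
}

#' Assign chromosome-holdout splits
#'
#' Examples on the validation chromosome go to `validation`, those on the
#' test chromosome to `test`, everything else to `train`. The split is a
#' function of the chromosome only.
#'
#' @param examples data.frame with a `chrom` column.
#' @param config a [dataset_config()].
#' @return `examples` with a `split` factor column added.
#' @export
assign_splits <- function(examples, config) {
  stopifnot(inherits(config, "dataset_config"))
  split <- rep("train", nrow(examples))
  split[examples$chrom == config$validation_chromosome] <- "validation"
  split[examples$chrom == config$test_chromosome] <- "test"
  examples$split <- factor(split, levels = c("train", "validation", "test"))
  examples
}

#' One-hot encode a DNA sequence
#'
#' Fixed column order A, C, G, T; `N` rows are 0.25 everywhere so an
#' ambiguous base carries the uniform background. Satisfies the
#' reverse-complement identity: encoding the reverse complement equals
#' row-reversing the encoding and swapping columns A<->T and C<->G.
#'
#' @param sequence DNA string over `{A,C,G,T,N}`.
#' @return numeric matrix, `nchar(sequence)` x 4.
#' @examples
#' encode_onehot("ACGT")
#' @export
encode_onehot <- function(sequence) {
  codes <- seq_to_codes(sequence)
  m <- matrix(0, length(codes), 4L, dimnames = list(NULL, .BASES))
  for (b in 1:4) m[codes == b, b] <- 1
  m[codes == 5L, ] <- 0.25
  m
}
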