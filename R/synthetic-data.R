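# Synthetic genomes, enhancer peaks and planted motif instances with known
# ground truth. The generator emulates the structure of a processed
# ATAC-seq/H3K27ac experiment: called peak intervals with per-peak
# histone-mark tag counts, where "active" peaks carry motif instances and
# high tag counts and "inactive" peaks carry neither.

#' Configuration for a synthetic genome
#'
#' @param chromosome_lengths named integer vector, chromosome name to length
#'   in bp. Defaults to ten 100 kb autosomes plus short `chrX`/`chrY` so the
#'   sex-chromosome filter downstream is exercised.
#' @param gc_content overall GC fraction in `[0, 1]`; bases are drawn i.i.d.
#'   with `P(G) = P(C) = gc_content / 2`. Default 0.41, mouse-like.
#' @param seed integer seed; identical configuration and seed give a
#'   byte-identical genome.
#' @return an object of class `genome_config`.
#' @export
genome_config <- function(chromosome_lengths = c(
                            stats::setNames(rep(100000L, 10L), paste0("chr", 1:10)),
                            chrX = 50000L, chrY = 20000L
                          ),
                          gc_content = 0.41, seed = 1L) {
  if (is.null(names(chromosome_lengths)) || any(!nzchar(names(chromosome_lengths)))) {
    stop("chromosome_lengths must be a named vector")
  }
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be positive")
  if (!is.numeric(gc_content) || gc_content < 0 || gc_content > 1) {
    stop("gc_content must lie in [0, 1]")
  }
  structure(list(chromosome_lengths = chromosome_lengths,
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "genome_config")
}

#' Generate a random genome
#'
#' Each chromosome is an i.i.d. base string with
#' `P(G) + P(C) = gc_content` split evenly and the remainder split evenly
#' between `A` and `T`.
#'
#' @param config a [genome_config()].
#' @return named character vector of chromosome sequences.
#' @examples
#' g <- generate_genome(genome_config(c(chrT = 50L), gc_content = 0.5, seed = 7))
#' nchar(g[["chrT"]])
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "genome_config"))
  gc <- config$gc_content
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(config$seed, {
    vapply(config$chromosome_lengths, function(len) {
      paste(sample(.BASES, len, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
  })
}

#' Configuration for a synthetic peak set
#'
#' @param n_active_peaks,n_inactive_peaks number of active (motif-carrying,
#'   high-tag) and inactive (background) peaks.
#' @param peak_length peak width in bp (default 300, the classifier window).
#' @param motifs_per_active_peak instances planted per PWM per active peak.
#' @param tag_mean_active,tag_mean_inactive negative-binomial mean tag count
#'   for active/inactive peaks. Defaults (100 vs 8) emulate strong H3K27ac at
#'   active enhancers against background, around the downstream cutoff of 32.
#' @param tag_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param seed integer seed.
#' @return an object of class `peakset_config`.
#' @export
peakset_config <- function(n_active_peaks = 700L, n_inactive_peaks = 700L,
                           peak_length = 300L, motifs_per_active_peak = 1L,
                           tag_mean_active = 100, tag_mean_inactive = 8,
                           tag_dispersion = 0.25, seed = 1L) {
  stopifnot(n_active_peaks >= 0, n_inactive_peaks >= 0, peak_length > 0,
            motifs_per_active_peak >= 0, tag_mean_active > 0,
            tag_mean_inactive > 0, tag_dispersion > 0)
  structure(list(n_active_peaks = as.integer(n_active_peaks),
                 n_inactive_peaks = as.integer(n_inactive_peaks),
                 peak_length = as.integer(peak_length),
                 motifs_per_active_peak = as.integer(motifs_per_active_peak),
                 tag_mean_active = tag_mean_active,
                 tag_mean_inactive = tag_mean_inactive,
                 tag_dispersion = tag_dispersion,
                 seed = as.integer(seed)),
            class = "peakset_config")
}

# Sample one sequence column-wise from a PWM's frequency matrix.
sample_pwm_instance <- function(pwm) {
  codes <- vapply(seq_len(pwm$width), function(i) {
    sample.int(4L, 1L, prob = pwm$freq[, i])
  }, integer(1))
  codes_to_seq(codes)
}

# Place n non-overlapping intervals of width len on the given chromosomes,
# rejecting overlaps with `occupied` (list of 2-column matrices per chrom).
place_intervals <- function(chrom_lengths, n, len, occupied, max_tries = NULL) {
  if (is.null(max_tries)) max_tries <- 1000L * max(n, 1L)
  ok <- names(chrom_lengths)[chrom_lengths >= len]
  if (length(ok) == 0L && n > 0L) stop("no chromosome can hold a ", len, " bp peak")
  w <- chrom_lengths[ok] - len + 1
  out <- data.frame(chrom = character(n), start = integer(n), end = integer(n),
                    stringsAsFactors = FALSE)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n, " non-overlapping peaks after ",
           max_tries, " draws (impossible packing?)")
    }
    cm <- sample(ok, 1L, prob = w)
    s <- sample.int(chrom_lengths[[cm]] - len + 1L, 1L) # 1-based start
    e <- s + len - 1L
    occ <- occupied[[cm]]
    if (!is.null(occ) && nrow(occ) > 0L &&
        any(s <= occ[, 2L] & e >= occ[, 1L])) next
    placed <- placed + 1L
    out$chrom[placed] <- cm
    out$start[placed] <- s
    out$end[placed] <- e
    occupied[[cm]] <- rbind(occ, c(s, e))
  }
  list(intervals = out, occupied = occupied)
}

#' Plant motif instances into a genome and emit peaks with tag counts
#'
#' Active peaks receive `motifs_per_active_peak` instances of every PWM,
#' each sampled column-wise from the PWM's frequency matrix, written into
#' the genome at non-overlapping offsets on a uniformly random strand.
#' Tag counts are drawn from a negative-binomial model with the configured
#' means and dispersion. Inactive peaks receive no instances.
#'
#' @param genome named character vector (from [generate_genome()]).
#' @param pwms list of [pwm_model()] objects.
#' @param config a [peakset_config()].
#' @return list with elements `genome` (with instances written in), `peaks`
#'   (data.frame: chrom, start, end, peak_id, tag_count, active; coordinates
#'   1-based inclusive) and `truth` (data.frame: chrom, start, end, motif_id,
#'   strand, sampled_sequence).
#' @export
plant_enhancers <- function(genome, pwms, config) {
  stopifnot(inherits(config, "peakset_config"))
  if (length(pwms) > 0 && is.null(names(pwms))) {
    names(pwms) <- vapply(pwms, `[[`, character(1), "motif_id")
  }
  widths <- vapply(pwms, `[[`, numeric(1), "width")
  if (length(widths) && any(widths >= config$peak_length)) {
    stop("motif width must be smaller than peak_length")
  }
  lens <- vapply(genome, nchar, integer(1))
  with_seed(config$seed, {
    n_tot <- config$n_active_peaks + config$n_inactive_peaks
    placed <- place_intervals(lens, n_tot, config$peak_length,
                              stats::setNames(vector("list", length(lens)), names(lens)))
    peaks <- placed$intervals
    peaks$peak_id <- sprintf("peak_%05d", seq_len(n_tot))
    peaks$active <- rep(c(TRUE, FALSE),
                        c(config$n_active_peaks, config$n_inactive_peaks))
    mu <- ifelse(peaks$active, config$tag_mean_active, config$tag_mean_inactive)
    peaks$tag_count <- rnbinom(n_tot, mu = mu, size = 1 / config$tag_dispersion)

    truth <- list()
    if (config$motifs_per_active_peak > 0L && length(pwms) > 0L) {
      plan <- expand.grid(pwm = names(pwms),
                          rep = seq_len(config$motifs_per_active_peak),
                          stringsAsFactors = FALSE)
      for (p in which(peaks$active)) {
        used <- matrix(numeric(0), ncol = 2) # offsets occupied within the peak
        for (j in seq_len(nrow(plan))) {
          pwm <- pwms[[plan$pwm[j]]]
          w <- pwm$width
          off <- NA_integer_
          for (try in seq_len(1000L)) {
            cand <- sample.int(config$peak_length - w + 1L, 1L)
            if (nrow(used) == 0L ||
                !any(cand <= used[, 2L] & (cand + w - 1L) >= used[, 1L])) {
              off <- cand
              break
            }
          }
          if (is.na(off)) {
            stop("could not place ", nrow(plan), " non-overlapping motif ",
                 "instances in a ", config$peak_length, " bp peak")
          }
          used <- rbind(used, c(off, off + w - 1L))
          strand <- sample(c("+", "-"), 1L)
          inst <- sample_pwm_instance(pwm)
          gstart <- peaks$start[p] + off - 1L
          gend <- gstart + w - 1L
          fwd <- if (strand == "+") inst else revcomp(inst)
          substr(genome[[peaks$chrom[p]]], gstart, gend) <- fwd
          truth[[length(truth) + 1L]] <- data.frame(
            chrom = peaks$chrom[p], start = gstart, end = gend,
            motif_id = pwm$motif_id, strand = strand,
            sampled_sequence = inst, stringsAsFactors = FALSE)
        }
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 motif_id = character(0), strand = character(0),
                 sampled_sequence = character(0), stringsAsFactors = FALSE)
    list(genome = genome,
         peaks = peaks[, c("chrom", "start", "end", "peak_id", "tag_count", "active")],
         truth = truth)
  })
}

#' Write a synthetic fixture to disk
#'
#' Genome as FASTA, peaks as a headerless 5-column TSV
#' (chrom, start, end, peak_id, tag_count) and truth as BED6
#' (name = motif_id, score = 0). Files use BED conventions
#' (0-based half-open); in-memory coordinates are 1-based inclusive.
#'
#' @param genome named character vector of chromosome sequences.
#' @param peaks,truth data.frames as returned by [plant_enhancers()].
#' @param out_dir output directory (created if absent).
#' @return named character vector of the three file paths.
#' @export
write_fixture <- function(genome, peaks, truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fa)
  pk <- file.path(out_dir, "peaks.tsv")
  write.table(data.frame(peaks$chrom, peaks$start - 1L, peaks$end,
                         peaks$peak_id, peaks$tag_count),
              pk, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tr <- file.path(out_dir, "truth.bed")
  write.table(data.frame(truth$chrom, truth$start - 1L, truth$end,
                         truth$motif_id, rep(0L, nrow(truth)), truth$strand),
              tr, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  c(genome = fa, peaks = pk, truth = tr)
}

#' Read a genome FASTA into the package's genome container
#'
#' @param path FASTA file path.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a peak table (chrom, start, end, peak_id, tag_count TSV)
#'
#' @param path headerless tab-separated file as written by [write_fixture()].
#' @return data.frame with 1-based inclusive coordinates.
#' @export
read_peak_table <- function(path) {
  cols <- c("chrom", "start", "end", "peak_id", "tag_count")
  df <- tryCatch(read.table(path, sep = "\t", col.names = cols,
                            colClasses = c("character", "integer", "integer",
                                           "character", "integer")),
                 error = function(e) {
                   stats::setNames(data.frame(character(0), integer(0), integer(0),
                                              character(0), integer(0)), cols)
                 })
  df$start <- df$start + 1L
  df
}

#' Read a planted-motif truth BED
#'
#' @param path BED6 as written by [write_fixture()].
#' @param genome optional genome; when given, the PWM-orientation sequence of
#'   each record is re-extracted (reverse-complemented for `-` strand).
#' @return data.frame with 1-based inclusive coordinates.
#' @export
read_motif_truth <- function(path, genome = NULL) {
  cols <- c("chrom", "start", "end", "motif_id", "score", "strand")
  df <- tryCatch(read.table(path, sep = "\t", col.names = cols,
                            colClasses = c("character", "integer", "integer",
                                           "character", "integer", "character")),
                 error = function(e) {
                   stats::setNames(data.frame(character(0), integer(0), integer(0),
                                              character(0), integer(0), character(0)), cols)
                 })
  df$start <- df$start + 1L
  df$score <- NULL
  if (!is.null(genome) && nrow(df) > 0L) {
    fwd <- mapply(genome_substr, df$chrom, df$start, df$end,
                  MoreArgs = list(genome = genome))
    df$sampled_sequence <- ifelse(df$strand == "+", fwd, revcomp(fwd))
  }
  df
}
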