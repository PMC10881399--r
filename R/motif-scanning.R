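# PWM loading, log-odds scoring on both strands, and calibration of the
# minimum score cutoff to an empirical per-window false-positive rate.

#' Construct a PWM model
#'
#' Counts (or frequencies) are converted to per-column frequencies after
#' adding a pseudocount mass of `pseudocount_frac` times the column total,
#' split across bases in proportion to the background; the log-odds matrix
#' is `log2(freq / background)`.
#'
#' @param counts 4 x W numeric matrix, rows A, C, G, T.
#' @param motif_id identifier (e.g. a JASPAR accession).
#' @param name optional human-readable name.
#' @param pseudocount_frac pseudocount mass as a fraction of each column
#'   total (default 0.01); 0 disables the pseudocount.
#' @param background base composition, length-4 vector summing to 1
#'   (default uniform).
#' @return an object of class `pwm_model` with elements `motif_id`, `name`,
#'   `counts`, `freq`, `log_odds` (4 x W), `width`, `background`,
#'   `pseudocount_frac`.
#' @export
pwm_model <- function(counts, motif_id, name = motif_id,
                      pseudocount_frac = 0.01,
                      background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6) {
    stop("background must be a length-4 composition summing to 1")
  }
  rownames(counts) <- .BASES
  tot <- colSums(counts)
  if (any(tot == 0)) stop("every column needs positive total counts")
  pseudo <- outer(background, tot) * pseudocount_frac
  freq <- sweep(counts + pseudo, 2L, tot * (1 + pseudocount_frac), "/")
  structure(list(motif_id = motif_id, name = name, counts = counts,
                 freq = freq, log_odds = log2(freq / background),
                 width = ncol(counts), background = background,
                 pseudocount_frac = pseudocount_frac),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("pwm_model %s (%s), width %d, consensus %s\n",
              x$motif_id, x$name, x$width,
              paste(.BASES[apply(x$freq, 2, which.max)], collapse = "")))
  invisible(x)
}

#' Load PWMs from a JASPAR-format text file
#'
#' Parses the JASPAR 2016+ text layout: a `>ID NAME` header followed by
#' four base rows such as `A [ 4 19 0 ]` (brackets optional).
#'
#' @param path file path.
#' @param pseudocount_frac,background passed to [pwm_model()].
#' @return named list of `pwm_model` objects.
#' @export
load_jaspar <- function(path, pseudocount_frac = 0.01,
                        background = rep(0.25, 4)) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no '>' header found in ", path)
  out <- list()
  for (h in heads) {
    hdr <- strsplit(sub("^>", "", lines[h]), "[\t ]+")[[1]]
    id <- hdr[1]
    nm <- if (length(hdr) > 1L) paste(hdr[-1], collapse = " ") else id
    rows <- matrix(NA_real_, 4L, 0L)
    got <- character(0)
    for (j in (h + 1L):min(h + 4L, length(lines))) {
      ln <- lines[j]
      m <- regmatches(ln, regexec("^\\s*([ACGT])\\s*\\[?([^]]*)\\]?\\s*$", ln))[[1]]
      if (length(m) == 0L) stop("line ", j, ": expected a base row, got: ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
      if (anyNA(vals)) stop("line ", j, ": non-numeric count in matrix row")
      if (any(vals < 0)) stop("line ", j, ": negative count in matrix row")
      if (ncol(rows) == 0L) rows <- matrix(NA_real_, 4L, length(vals))
      if (length(vals) != ncol(rows)) {
        stop("line ", j, ": row length ", length(vals),
             " differs from previous rows (", ncol(rows), ")")
      }
      rows[match(m[2], .BASES), ] <- vals
      got <- c(got, m[2])
    }
    if (!setequal(got, .BASES)) {
      stop("matrix ", id, " is missing base row(s): ",
           paste(setdiff(.BASES, got), collapse = ", "))
    }
    out[[id]] <- pwm_model(rows, id, nm, pseudocount_frac, background)
  }
  out
}

#' Write PWMs as JASPAR-format text
#'
#' @param pwms list of `pwm_model` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  txt <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$motif_id, "\t", p$name),
      vapply(1:4, function(b) {
        sprintf("%s  [ %s ]", .BASES[b],
                paste(format(p$counts[b, ], trim = TRUE), collapse = " "))
      }, character(1)))
  }))
  writeLines(txt, path)
  invisible(path)
}

#' Score a single window against a PWM
#'
#' The score is the sum over positions of the log-odds of the observed base.
#' Windows containing `N` are undefined and return `NA`.
#'
#' @param pwm a `pwm_model`.
#' @param window DNA string of the PWM's width.
#' @return log-odds score (numeric scalar), or `NA` for `N`-containing
#'   windows.
#' @export
score_window <- function(pwm, window) {
  if (nchar(window) != pwm$width) {
    stop("window must have length ", pwm$width)
  }
  codes <- seq_to_codes(window)
  if (any(codes == 5L)) return(NA_real_)
  sum(pwm$log_odds[cbind(codes, seq_len(pwm$width))])
}

# Scores at every offset of a coded sequence, one strand. Offsets covering
# an N return NA. Vectorised over offsets; loops only over the motif width.
score_offsets_codes <- function(lo, codes) {
  W <- ncol(lo)
  n <- length(codes) - W + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  lo_n <- rbind(lo, NA_real_) # code 5 (N) picks up NA
  for (k in seq_len(W)) {
    s <- s + lo_n[cbind(codes[k:(k + n - 1L)], k)]
  }
  s
}

# Both-strand offset scores for a sequence; the minus strand scores the
# reverse complement of each width-W window at the same forward offset.
score_both_strands <- function(pwm, sequence) {
  codes <- seq_to_codes(sequence)
  fwd <- score_offsets_codes(pwm$log_odds, codes)
  rc <- rev(.COMP_CODE[codes])
  rev_scores <- rev(score_offsets_codes(pwm$log_odds, rc))
  list(fwd = fwd, rev = rev_scores)
}

# Best score anywhere in the window on either strand (NA offsets ignored;
# -Inf if nothing is scorable).
window_best_score <- function(pwm, sequence) {
  s <- score_both_strands(pwm, sequence)
  v <- c(s$fwd, s$rev)
  v <- v[!is.na(v)]
  if (length(v) == 0L) -Inf else max(v)
}

#' Calibrate the PWM score cutoff to an empirical false-positive rate
#'
#' Scores every background window at every offset on both strands; a window
#' is a false positive when any offset on either strand reaches the cutoff.
#' The cutoff is the smallest value on the grid of observed per-window best
#' scores for which the fraction of passing windows is below `target_fpr`.
#' With `target_fpr >= 1` the bound is vacuous and the minimum observed
#' best score is returned (every window passes).
#'
#' @param pwm a `pwm_model`.
#' @param background_windows character vector of background sequences; at
#'   least `10 / target_fpr` are required for a meaningful estimate.
#' @param target_fpr target false-positive rate (default 0.002, i.e. 0.2%).
#' @param seed recorded in the calibration record (the procedure itself is
#'   deterministic given the background set).
#' @param background_source free-text tag recorded in the result.
#' @return an object of class `cutoff_calibration`: `motif_id`,
#'   `target_fpr`, `cutoff`, `n_background_windows`, `achieved_fpr`,
#'   `background_source`, `seed`.
#' @export
calibrate_cutoff <- function(pwm, background_windows, target_fpr = 0.002,
                             seed = NA_integer_,
                             background_source = "user") {
  stopifnot(inherits(pwm, "pwm_model"), target_fpr > 0)
  n <- length(background_windows)
  need <- ceiling(10 / target_fpr)
  if (target_fpr < 1 && n < need) {
    stop("calibration at target FPR ", target_fpr, " needs at least ",
         need, " background windows; got ", n)
  }
  best <- vapply(background_windows, window_best_score, numeric(1),
                 pwm = pwm, USE.NAMES = FALSE)
  if (target_fpr >= 1) {
    cutoff <- min(best)
  } else {
    grid <- sort(unique(best))
    pass <- vapply(grid, function(cc) mean(best >= cc), numeric(1))
    ok <- which(pass < target_fpr)
    if (length(ok) == 0L) {
      stop("no cutoff on the background score grid achieves FPR < ", target_fpr)
    }
    cutoff <- grid[ok[1L]]
  }
  structure(list(motif_id = pwm$motif_id, target_fpr = target_fpr,
                 cutoff = cutoff, n_background_windows = n,
                 achieved_fpr = mean(best >= cutoff),
                 background_source = background_source,
                 seed = seed),
            class = "cutoff_calibration")
}

#' @export
print.cutoff_calibration <- function(x, ...) {
  cat(sprintf(paste0("cutoff_calibration %s: cutoff %.4f, achieved FPR %.4f%%",
                     " (target < %.4f%%) on %d windows\n"),
              x$motif_id, x$cutoff, 100 * x$achieved_fpr,
              100 * x$target_fpr, x$n_background_windows))
  invisible(x)
}

#' Scan a sequence for motif matches above a cutoff
#'
#' Scores every width-W offset on both strands and emits matches with score
#' at or above the cutoff, in forward-strand coordinates (1-based
#' inclusive), sorted by start then strand. Offsets covering an `N` are
#' skipped. Overlapping matches are all reported.
#'
#' @param pwm a `pwm_model`.
#' @param sequence DNA string (length >= the PWM width; shorter sequences
#'   give an empty result).
#' @param cutoff minimum (inclusive) log-odds score.
#' @param sequence_id optional identifier copied into the result.
#' @param chrom,offset optional chromosome name and 1-based start of
#'   `sequence` on it; when given, match coordinates are genomic.
#' @return data.frame: sequence_id, chrom, start, end, strand, score,
#'   motif_id.
#' @export
scan_pwm <- function(pwm, sequence, cutoff, sequence_id = NA_character_,
                     chrom = NA_character_, offset = 1L) {
  stopifnot(inherits(pwm, "pwm_model"))
  empty <- data.frame(sequence_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      motif_id = character(0), stringsAsFactors = FALSE)
  if (nchar(sequence) < pwm$width) return(empty)
  s <- score_both_strands(pwm, sequence)
  hit_f <- which(!is.na(s$fwd) & s$fwd >= cutoff)
  hit_r <- which(!is.na(s$rev) & s$rev >= cutoff)
  if (length(hit_f) + length(hit_r) == 0L) return(empty)
  df <- data.frame(
    sequence_id = sequence_id, chrom = chrom,
    start = c(hit_f, hit_r) + offset - 1L,
    end = c(hit_f, hit_r) + offset - 2L + pwm$width,
    strand = c(rep("+", length(hit_f)), rep("-", length(hit_r))),
    score = c(s$fwd[hit_f], s$rev[hit_r]),
    motif_id = pwm$motif_id, stringsAsFactors = FALSE)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}
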