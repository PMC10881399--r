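# Final "functional motif" calls: PWM matches above the calibrated cutoff
# whose footprint places at least `min_overlap` positions inside the
# per-sequence top-importance position set.

#' Count motif footprint positions inside a top-importance set
#'
#' Positions are counted in forward coordinates regardless of the match
#' strand (the aggregated importance track is strand-symmetric).
#'
#' @param match_start,match_end match interval, 1-based inclusive, in the
#'   same coordinate system as `top_positions`.
#' @param top_positions integer vector of top-importance positions.
#' @return integer overlap count in `[0, match width]`.
#' @export
overlap_with_top_set <- function(match_start, match_end, top_positions) {
  stopifnot(match_start <= match_end)
  sum(top_positions >= match_start & top_positions <= match_end)
}

#' Call functional motifs
#'
#' Combines PWM matches (already filtered to the calibrated cutoff by
#' [scan_pwm()]) with per-sequence top-importance position sets. A match is
#' functional when at least `min_overlap` of its footprint positions fall in
#' the top set of its window.
#'
#' @param matches data.frame from [scan_pwm()] (any number of sequences /
#'   motifs row-bound); must carry `sequence_id` and window-local
#'   1-based coordinates in `start`/`end` (or see `match_offsets`).
#' @param top_sets named list: `sequence_id` -> integer vector of
#'   window-local top positions (from [top_fraction_positions()]).
#' @param min_overlap minimum footprint positions inside the top set
#'   (default 3).
#' @param match_offsets optional named integer vector: `sequence_id` ->
#'   1-based genomic start of the window, used to convert genomic match
#'   coordinates to window-local ones before counting.
#' @return list of class `functional_calls`: `calls` (the matches with
#'   `overlap_count` and `functional` columns, sorted by chrom, start,
#'   strand) and `summary` (per-motif n_matches / n_functional).
#' @export
call_functional <- function(matches, top_sets, min_overlap = 3L,
                            match_offsets = NULL) {
  stopifnot(min_overlap >= 0)
  if (nrow(matches) > 0L) {
    missing_ts <- setdiff(unique(matches$sequence_id), names(top_sets))
    if (length(missing_ts) > 0L) {
      stop("no top-position set for sequence(s): ",
           paste(head(missing_ts, 5L), collapse = ", "))
    }
  }
  n <- nrow(matches)
  overlap <- integer(n)
  for (i in seq_len(n)) {
    sid <- matches$sequence_id[i]
    shift <- if (!is.null(match_offsets)) match_offsets[[sid]] - 1L else 0L
    s <- matches$start[i] - shift
    e <- matches$end[i] - shift
    if (s < 1L || e < s) stop("match outside its sequence window: row ", i)
    overlap[i] <- overlap_with_top_set(s, e, top_sets[[sid]])
  }
  calls <- matches
  calls$overlap_count <- overlap
  calls$functional <- overlap >= min_overlap
  if (n > 0L) {
    calls <- calls[order(calls$chrom, calls$start, calls$strand), , drop = FALSE]
    rownames(calls) <- NULL
  }
  motifs <- unique(calls$motif_id)
  summary <- data.frame(
    motif_id = motifs,
    n_matches = vapply(motifs, function(m) sum(calls$motif_id == m), integer(1)),
    n_functional = vapply(motifs, function(m) {
      sum(calls$functional[calls$motif_id == m])
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(calls = calls, summary = summary,
                 min_overlap = as.integer(min_overlap)),
            class = "functional_calls")
}

#' @export
print.functional_calls <- function(x, ...) {
  cat(sprintf("functional_calls: %d match(es), %d functional (min_overlap = %d)\n",
              nrow(x$calls), sum(x$calls$functional), x$min_overlap))
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' Precision/recall/F1 of functional calls against planted truth
#'
#' A functional call is a true positive when a truth interval of the same
#' motif id overlaps it within `tolerance_bp` (0 = plain overlap of at
#' least one base); a truth entry is recovered when at least one functional
#' call of its motif overlaps it. Precision with zero calls is reported as
#' 0 with `precision_defined = FALSE`.
#'
#' @param calls a `functional_calls` object or its `calls` data.frame
#'   (with genomic `chrom`/`start`/`end` coordinates).
#' @param truth data.frame from [plant_enhancers()] (chrom, start, end,
#'   motif_id, strand).
#' @param tolerance_bp maximum gap between call and truth intervals still
#'   counted as overlapping.
#' @return data.frame with one row per motif id plus a `pooled` row:
#'   motif_id, n_truth, n_calls, n_tp_calls, n_recovered, precision, recall,
#'   f1, precision_defined.
#' @export
recovery_report <- function(calls, truth, tolerance_bp = 0L) {
  if (inherits(calls, "functional_calls")) calls <- calls$calls
  if (nrow(calls) > 0L) calls <- calls[calls$functional, , drop = FALSE]
  motifs <- sort(unique(c(calls$motif_id, truth$motif_id)))
  one <- function(cl, tr) {
    n_calls <- nrow(cl); n_truth <- nrow(tr)
    if (n_calls > 0L && n_truth > 0L) {
      cg <- GenomicRanges::GRanges(cl$chrom, IRanges::IRanges(cl$start, cl$end))
      tg <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start, tr$end))
      # tolerance 0 demands a shared base; tolerance t > 0 allows a gap <= t
      mg <- if (tolerance_bp > 0L) as.integer(tolerance_bp) else -1L
      hits <- GenomicRanges::findOverlaps(cg, tg, maxgap = mg)
      tp_calls <- length(unique(S4Vectors::queryHits(hits)))
      recovered <- length(unique(S4Vectors::subjectHits(hits)))
    } else {
      tp_calls <- 0L; recovered <- 0L
    }
    precision <- if (n_calls > 0L) tp_calls / n_calls else 0
    recall <- if (n_truth > 0L) recovered / n_truth else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    data.frame(n_truth = n_truth, n_calls = n_calls, n_tp_calls = tp_calls,
               n_recovered = recovered, precision = precision, recall = recall,
               f1 = f1, precision_defined = n_calls > 0L)
  }
  per <- do.call(rbind, lapply(motifs, function(m) {
    cbind(motif_id = m,
          one(calls[calls$motif_id == m, , drop = FALSE],
              truth[truth$motif_id == m, , drop = FALSE]))
  }))
  pooled <- local({
    # pooled counts: each call/truth entry still matched within its motif
    tp <- sum(per$n_tp_calls); nc <- sum(per$n_calls)
    rec <- sum(per$n_recovered); nt <- sum(per$n_truth)
    precision <- if (nc > 0L) tp / nc else 0
    recall <- if (nt > 0L) rec / nt else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    data.frame(motif_id = "pooled", n_truth = nt, n_calls = nc,
               n_tp_calls = tp, n_recovered = rec, precision = precision,
               recall = recall, f1 = f1, precision_defined = nc > 0L)
  })
  out <- rbind(per, pooled)
  rownames(out) <- NULL
  out
}
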