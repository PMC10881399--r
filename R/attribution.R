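# Per-nucleotide importance scores for the classifier. The default backend
# propagates DeepLIFT-style multipliers against a uniform (0.25-per-base)
# reference through every layer in a delta-preserving way, so the
# summation-to-delta identity sum(scores) = p(x) - p(reference) holds to
# floating-point accuracy:
#   * linear layers (conv im2col products, dense): chain-rule multipliers,
#     exactly delta-preserving because the bias cancels in the difference;
#   * ReLU and the output sigmoid: rescale rule, m = delta_out / delta_in;
#   * max-pool: the pooled delta is routed entirely to the in-window input
#     with the largest |delta|, with multiplier delta_out / delta_in. A
#     plain gradient path (route to the actual argmax) would break
#     summation-to-delta whenever the actual and reference argmax differ.
# The gradient-x-input fallback uses the ordinary gradient at the input and
# is exempt from the summation-to-delta guarantee.

.RESCALE_EPS <- 1e-9

# rescale multiplier with derivative fallback for vanishing deltas
rescale_mult <- function(delta_out, delta_in, deriv) {
  ifelse(abs(delta_in) > .RESCALE_EPS, delta_out / delta_in, deriv)
}

# Multipliers through a max-pool, delta-preserving (see header comment).
pool_multipliers <- function(m_pooled, Ax, Ar, pool, npool, F, n) {
  da <- (Ax - Ar)[seq_len(pool * npool), , drop = FALSE]
  dim(da) <- c(pool, npool, F)
  best <- matrix(abs(da[1L, , ]), npool, F)
  J <- matrix(1L, npool, F)
  if (pool > 1L) for (k in 2:pool) {
    ak <- matrix(abs(da[k, , ]), npool, F)
    upd <- ak > best
    J[upd] <- k
    best[upd] <- ak[upd]
  }
  lin <- cbind(as.vector((row(J) - 1L) * pool + J), as.vector(col(J)))
  denom <- (Ax - Ar)[lin]
  dpool <- as.vector(pool_max(Ax, pool, npool, F)$P -
                       pool_max(Ar, pool, npool, F)$P)
  msrc <- ifelse(abs(denom) > 1e-12, as.vector(m_pooled) * dpool / denom, 0)
  out <- matrix(0, n, F)
  out[lin] <- msrc
  out
}

# DeepLIFT rescale contributions at the input, one matrix L x 4.
deeplift_contribs <- function(model, xf) {
  d <- model$dims
  ix <- cnn_indices(d)
  params <- model$params
  rf <- rep(0.25, length(xf)) # uniform reference input
  fx <- cnn_forward(params, xf, d, ix)
  fr <- cnn_forward(params, rf, d, ix)

  m_z <- rescale_mult(fx$p - fr$p, fx$z - fr$z, fx$p * (1 - fx$p))
  m_h <- params$Wd * m_z
  m_A2 <- pool_multipliers(matrix(m_h, d$n2p, d$F2), fx$A2, fr$A2,
                           d$p2, d$n2p, d$F2, d$n2)
  m_Z2 <- ifelse(abs(fx$Z2 - fr$Z2) > .RESCALE_EPS,
                 m_A2 * (fx$A2 - fr$A2) / (fx$Z2 - fr$Z2), 0)
  m_X2 <- m_Z2 %*% t(params$W2)
  m_P1 <- matrix(scatter_add(m_X2, ix$idx2, d$n1p * d$C1), d$n1p, d$C1)
  m_A1 <- pool_multipliers(m_P1, fx$A1, fr$A1, d$p1, d$n1p, d$C1, d$n1)
  m_Z1 <- ifelse(abs(fx$Z1 - fr$Z1) > .RESCALE_EPS,
                 m_A1 * (fx$A1 - fr$A1) / (fx$Z1 - fr$Z1), 0)
  m_X1 <- m_Z1 %*% t(conv1_bank(params, d)$W)
  m_xf <- scatter_add(m_X1, ix$idx1, 4L * d$L)
  contrib <- m_xf * (xf - 0.25)
  list(contrib = matrix(contrib, d$L, 4L), out_x = fx$p, out_ref = fr$p)
}

# Ordinary gradient of the output probability at the input.
input_gradient <- function(model, xf) {
  d <- model$dims
  ix <- cnn_indices(d)
  params <- model$params
  fx <- cnn_forward(params, xf, d, ix)
  gz <- fx$p * (1 - fx$p)
  gh <- params$Wd * gz
  gA2 <- unpool(matrix(gh, d$n2p, d$F2), fx$I2, d$p2, d$n2, d$F2)
  gZ2 <- gA2 * (fx$Z2 > 0)
  gX2 <- gZ2 %*% t(params$W2)
  gP1 <- matrix(scatter_add(gX2, ix$idx2, d$n1p * d$C1), d$n1p, d$C1)
  gA1 <- unpool(gP1, fx$I1, d$p1, d$n1, d$C1)
  gZ1 <- gA1 * (fx$Z1 > 0)
  gX1 <- gZ1 %*% t(conv1_bank(params, d)$W)
  matrix(scatter_add(gX1, ix$idx1, 4L * d$L), d$L, 4L)
}

#' Per-nucleotide importance scores (forward orientation)
#'
#' One signed score per position, computed against the uniform reference
#' input (0.25 at every base). The position score is the total contribution
#' of the four input channels at that position; for the default
#' `deeplift_rescale` method the scores satisfy summation-to-delta:
#' `sum(scores)` equals the model output on the sequence minus the output on
#' the uniform reference, to floating-point accuracy. The `grad_x_input`
#' method multiplies the ordinary input gradient by the input difference and
#' carries no such guarantee.
#'
#' @param model an `enhancer_cnn` or `enhancer_cnn_ensemble`; for an
#'   ensemble, member scores are averaged (summation-to-delta then holds
#'   against the ensemble-mean output, since the mean of the member deltas
#'   is the ensemble delta).
#' @param sequence DNA string of the model's window length.
#' @param method `"deeplift_rescale"` (default) or `"grad_x_input"`.
#' @return numeric vector of length L with attributes `method`,
#'   `reference` (`"uniform"`), and for the rescale method `out_x`/`out_ref`
#'   (the two forward passes).
#' @export
importance_scores <- function(model, sequence,
                              method = c("deeplift_rescale", "grad_x_input")) {
  UseMethod("importance_scores")
}

#' @export
importance_scores.enhancer_cnn <- function(model, sequence,
                                           method = c("deeplift_rescale",
                                                      "grad_x_input")) {
  method <- match.arg(method)
  if (nchar(sequence) != model$dims$L) {
    stop("sequence must have length ", model$dims$L)
  }
  xf <- as.vector(encode_onehot(sequence))
  if (method == "deeplift_rescale") {
    dl <- deeplift_contribs(model, xf)
    structure(rowSums(dl$contrib), method = method, reference = "uniform",
              out_x = dl$out_x, out_ref = dl$out_ref)
  } else {
    g <- input_gradient(model, xf)
    structure(rowSums(g * (matrix(xf, model$dims$L, 4L) - 0.25)),
              method = method, reference = "uniform")
  }
}

#' @export
importance_scores.enhancer_cnn_ensemble <- function(model, sequence,
                                                    method = c("deeplift_rescale",
                                                               "grad_x_input")) {
  method <- match.arg(method)
  per <- lapply(model$members, importance_scores, sequence = sequence,
                method = method)
  out <- Reduce(`+`, lapply(per, as.numeric)) / length(per)
  if (method == "deeplift_rescale") {
    structure(out, method = method, reference = "uniform",
              out_x = mean(vapply(per, attr, numeric(1), "out_x")),
              out_ref = mean(vapply(per, attr, numeric(1), "out_ref")))
  } else {
    structure(out, method = method, reference = "uniform")
  }
}

#' Aggregate importance scores across strands
#'
#' The final score at each position is the absolute maximum of the
#' forward-strand score and the reverse-complement-strand score re-aligned
#' to forward coordinates. Symmetric in its arguments.
#'
#' @param forward_scores scores on the original sequence.
#' @param reverse_scores scores computed on the reverse complement, already
#'   re-aligned to forward coordinates by index reversal.
#' @return non-negative numeric vector of the same length.
#' @examples
#' aggregate_strands(c(-3, 1), c(2, -5))
#' @export
aggregate_strands <- function(forward_scores, reverse_scores) {
  if (length(forward_scores) != length(reverse_scores)) {
    stop("score vectors must have equal length")
  }
  pmax(abs(forward_scores), abs(reverse_scores))
}

#' Strand-aggregated importance track for one window
#'
#' Runs [importance_scores()] on the sequence and its reverse complement,
#' re-aligns the latter by index reversal, and takes the absolute maximum at
#' each position. The result is invariant under reverse-complementing the
#' input (up to index reversal).
#'
#' For an ensemble, each member's strand-aggregated track is computed and
#' the tracks are combined by the elementwise maximum: member outputs are
#' all probabilities so the tracks share a scale, and the maximum keeps
#' every sequence feature that any member's fit discovered, rather than
#' diluting features that only a subset of members exploit.
#'
#' @inheritParams importance_scores
#' @return non-negative numeric vector of length L in forward coordinates.
#' @export
importance_track <- function(model, sequence,
                             method = c("deeplift_rescale", "grad_x_input")) {
  UseMethod("importance_track")
}

#' @export
importance_track.enhancer_cnn <- function(model, sequence,
                                          method = c("deeplift_rescale",
                                                     "grad_x_input")) {
  method <- match.arg(method)
  fwd <- importance_scores(model, sequence, method)
  rev_scores <- importance_scores(model, revcomp(sequence), method)
  aggregate_strands(as.numeric(fwd), rev(as.numeric(rev_scores)))
}

#' @export
importance_track.enhancer_cnn_ensemble <- function(model, sequence,
                                                   method = c("deeplift_rescale",
                                                              "grad_x_input")) {
  method <- match.arg(method)
  tracks <- lapply(model$members, importance_track, sequence = sequence,
                   method = method)
  Reduce(pmax, tracks)
}

#' Top-fraction positions of an importance track
#'
#' Returns the `k = floor(fraction * L)` positions (1-based) with the
#' largest final scores, in ascending coordinate order. For the default 300
#' bp window and fraction 0.2 this is the top 60 positions. Ties at the k-th
#' value are broken by larger score first, then smaller coordinate.
#'
#' @param final_scores numeric vector of aggregated importance scores.
#' @param fraction fraction of positions to keep, in `(0, 1]`.
#' @return integer vector of `k` positions, ascending.
#' @export
top_fraction_positions <- function(final_scores, fraction = 0.2) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  L <- length(final_scores)
  k <- floor(fraction * L)
  if (k < 1L) stop("fraction too small: floor(fraction * L) = 0 positions")
  ord <- order(-final_scores, seq_len(L))
  sort(ord[seq_len(k)])
}
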