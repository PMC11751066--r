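#' Build a position weight matrix from position frequency counts
#'
#' Converts a matrix of per-position nucleotide counts into a probability
#' model with a background-distributed pseudocount. Position `p`'s
#' probability for base `b` is
#' `(counts[b, p] + pseudocount * background[b] * 4) / (sum_b counts[b, p] + 4 * pseudocount)`
#' (with a unit-sum background the pseudocount mass per position is
#' `4 * pseudocount`), so every position sums to 1 and all probabilities are
#' strictly positive whenever `pseudocount > 0`.
#'
#' @param counts numeric matrix of nonnegative counts, 4 rows in A, C, G, T
#'   order (rownames optional), one column per motif position.
#' @param pseudocount nonnegative smoothing mass; must be positive if any
#'   position contains a zero count.
#' @param background length-4 base composition (A, C, G, T), summing to 1.
#' @param tf_id identifier attached to the resulting matrix.
#' @return An object of class `pwm`: a list with `tf_id`, `length`, `probs`
#'   (4 x L probability matrix), `background`, and `pseudocount`.
#' @examples
#' counts <- matrix(c(8, 0, 0, 0, 0, 8, 0, 0), nrow = 4)
#' pfm_to_pwm(counts, pseudocount = 0.25, tf_id = "toyAC")
#' @export
pfm_to_pwm <- function(counts, pseudocount = 0.25,
                       background = rep(0.25, 4), tf_id = "pwm") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("inconsistent matrix width: expected 4 rows (A, C, G, T), got ",
         nrow(counts))
  if (any(counts < 0) || anyNA(counts)) stop("counts must be nonnegative")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  background <- validate_background(background)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    if (pseudocount == 0)
      stop("degenerate position: zero total count at position ",
           paste(which(totals == 0), collapse = ", "),
           " with zero pseudocount")
  }
  add <- pseudocount * background * 4
  probs <- sweep(counts + add, 2, totals + sum(add), "/")
  # guard against tiny drift
  probs <- sweep(probs, 2, colSums(probs), "/")
  if (any(probs <= 0))
    stop("degenerate position: zero probability after pseudocount")
  dimnames(probs) <- list(DNA_BASES, NULL)
  new_pwm(tf_id, probs, background, pseudocount)
}

new_pwm <- function(tf_id, probs, background, pseudocount) {
  stopifnot(nrow(probs) == 4L, ncol(probs) >= 1L)
  if (any(abs(colSums(probs) - 1) > 1e-9))
    stop("pwm positions must sum to 1")
  structure(
    list(tf_id = as.character(tf_id), length = ncol(probs),
         probs = probs, background = background, pseudocount = pseudocount),
    class = "pwm"
  )
}

validate_background <- function(background) {
  background <- as.numeric(background)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0))
    stop("background must be 4 positive probabilities summing to 1")
  names(background) <- DNA_BASES
  background
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$tf_id, ": ", x$length, " positions, consensus ",
      paste(DNA_BASES[apply(x$probs, 2, which.max)], collapse = ""),
      "\n", sep = "")
  invisible(x)
}

# 5 x L log10(motif/background) matrix; fifth row (N) is zero so an N base
# contributes nothing to the score.
logratio_matrix <- function(pwm) {
  lr <- log10(sweep(pwm$probs, 1, pwm$background, "/"))
  rbind(lr, N = 0)
}

#' Score a single window under the Jindex log-likelihood ratio
#'
#' The Jindex of a window is the summed per-position log10 ratio of the
#' motif probability to the background probability,
#' `sum_p log10(probs[base_p, p] / background[base_p])`. A score of 1.0
#' means the window is 10 times more likely under the motif model than
#' under background. `N` bases contribute 0 (neutral).
#'
#' @param pwm a [pfm_to_pwm()] object.
#' @param window DNA string of length `pwm$length` over A, C, G, T, N.
#' @return A single finite numeric score.
#' @examples
#' counts <- matrix(c(8, 0, 0, 0, 0, 8, 0, 0), nrow = 4)
#' p <- pfm_to_pwm(counts, pseudocount = 0.25)
#' jindex_score(p, "AC")
#' @export
jindex_score <- function(pwm, window) {
  stopifnot(inherits(pwm, "pwm"))
  code <- encode_dna(window)
  if (length(code) != pwm$length)
    stop("window length ", length(code), " does not match pwm length ",
         pwm$length)
  lr <- logratio_matrix(pwm)
  sum(lr[cbind(code + 1L, seq_len(pwm$length))])
}

#' Consensus sequence and its Jindex score
#'
#' @param pwm a [pfm_to_pwm()] object.
#' @return A list with `sequence` (the per-position argmax base) and `score`.
#' @export
pwm_consensus <- function(pwm) {
  idx <- apply(pwm$probs, 2, which.max)
  seq <- paste(DNA_BASES[idx], collapse = "")
  list(sequence = seq, score = jindex_score(pwm, seq))
}
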