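#' Scan a promoter for motif occurrences above a Jindex threshold
#'
#' Scores every window of the promoter on the forward strand (and, by
#' default, the reverse complement) with [jindex_score()] and keeps hits
#' with `jindex >= threshold`. Reverse-strand hits are reported at the
#' forward-strand offset of the window they cover. Offsets are 0-based
#' within the promoter.
#'
#' @param pwm a [pfm_to_pwm()] object.
#' @param promoter a DNA string, or a list/row with fields `gene_id` and
#'   `sequence` (as produced by [extract_promoters()]).
#' @param threshold minimum Jindex score for a retained hit (default 1.0,
#'   i.e. 10x more likely under the motif than under background).
#' @param both_strands scan the reverse complement as well (default TRUE).
#' @param gene_id promoter identifier used when `promoter` is a bare string.
#' @return A data.frame with columns `tf_id`, `gene_id`, `offset` (0-based),
#'   `width`, `strand`, `jindex`, sorted by offset then strand. Zero rows
#'   when the promoter is shorter than the motif or nothing passes.
#' @examples
#' p <- pfm_to_pwm(matrix(c(8, 0, 0, 0, 0, 8, 0, 0), nrow = 4), 0.25,
#'                 tf_id = "toyAC")
#' scan_promoter(p, "GGACGG", both_strands = FALSE)
#' @export
scan_promoter <- function(pwm, promoter, threshold = 1.0,
                          both_strands = TRUE, gene_id = "promoter") {
  stopifnot(inherits(pwm, "pwm"))
  if (is.list(promoter) || is.data.frame(promoter)) {
    gene_id <- promoter$gene_id
    promoter <- promoter$sequence
  }
  empty <- data.frame(tf_id = character(), gene_id = character(),
                      offset = integer(), width = integer(),
                      strand = character(), jindex = numeric(),
                      stringsAsFactors = FALSE)
  code <- encode_dna(promoter)
  L <- pwm$length
  n <- length(code)
  if (n < L) return(empty)
  lr <- logratio_matrix(pwm)
  fwd <- cpp_score_windows(lr, code)
  hf <- which(fwd >= threshold)
  res <- list(data.frame(offset = hf - 1L,
                         strand = rep("+", length(hf)),
                         jindex = fwd[hf]))
  if (both_strands) {
    rc <- encode_dna(revcomp(promoter))
    rev <- cpp_score_windows(lr, rc)
    keep <- which(rev >= threshold)
    res[[2]] <- data.frame(offset = n - L - (keep - 1L),
                           strand = rep("-", length(keep)),
                           jindex = rev[keep])
  }
  out <- do.call(rbind, res)
  if (nrow(out) == 0L) return(empty)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  data.frame(tf_id = pwm$tf_id, gene_id = gene_id,
             offset = out$offset, width = L, strand = out$strand,
             jindex = out$jindex, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Scan many promoters with many PWMs
#'
#' @param pwms list of [pfm_to_pwm()] objects.
#' @param promoters named character vector of promoter sequences, or the
#'   data.frame produced by [extract_promoters()].
#' @inheritParams scan_promoter
#' @return One data.frame of retained hits across all (PWM, promoter) pairs.
#' @export
scan_promoters <- function(pwms, promoters, threshold = 1.0,
                           both_strands = TRUE) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.data.frame(promoters))
    promoters <- setNames(promoters$sequence, promoters$gene_id)
  ids <- names(promoters)
  codes <- lapply(promoters, encode_dna)       # encode each promoter once
  acc <- vector("list", length(pwms))
  for (k in seq_along(pwms)) {
    pwm <- pwms[[k]]
    lr <- logratio_matrix(pwm)
    hit <- cpp_scan_codes(lr, revcomp_matrix(lr), codes, threshold,
                          both_strands)
    if (!length(hit$gene)) next
    acc[[k]] <- data.frame(
      tf_id = rep(pwm$tf_id, length(hit$gene)),
      gene_id = ids[hit$gene], offset = hit$offset,
      width = rep(pwm$length, length(hit$gene)),
      strand = c("+", "-")[hit$strand + 1L], jindex = hit$jindex,
      stringsAsFactors = FALSE)
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (!length(acc))
    return(data.frame(tf_id = character(), gene_id = character(),
                      offset = integer(), width = integer(),
                      strand = character(), jindex = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(acc, list(make.row.names = FALSE)))
}

# lr_rc[b, p] = lr[complement(b), L - 1 - p]; scoring a forward window with
# lr_rc equals scoring its reverse complement with lr (N row self-maps)
revcomp_matrix <- function(lr) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  lr[comp, rev(seq_len(ncol(lr))), drop = FALSE]
}

# reverse complement in code space: A<->T (0<->3), C<->G (1<->2), N fixed
rev_code <- function(code) {
  comp <- c(3L, 2L, 1L, 0L, 4L)
  rev(comp[code + 1L])
}
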