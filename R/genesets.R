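#' Collapse TFBS hits into per-TF target gene sets with set ranks
#'
#' A gene belongs to a TF's target set when it carries at least one retained
#' binding site for that TF. Each gene's set score aggregates its hits'
#' Jindex values (default: the maximum, i.e. the most confident single
#' site); set ranks `S_rank` run 1..n by descending set score, ties broken
#' by gene identifier so the ranking is deterministic.
#'
#' @param hits data.frame of retained hits from [scan_promoter()] /
#'   [scan_promoters()] (already thresholded).
#' @param aggregate how to collapse a gene's multiple hits into one set
#'   score: `"max"` (default), `"sum"`, or `"count"`.
#' @return A data.frame with columns `tf_id`, `gene_id`, `set_score`,
#'   `S_rank`, ordered by `tf_id` then `S_rank`. Empty input gives an empty
#'   frame, not an error.
#' @export
build_gene_sets <- function(hits, aggregate = c("max", "sum", "count")) {
  aggregate <- match.arg(aggregate)
  empty <- data.frame(tf_id = character(), gene_id = character(),
                      set_score = numeric(), S_rank = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  agg_fun <- switch(aggregate, max = max, sum = sum, count = length)
  pieces <- lapply(split(hits, hits$tf_id), function(h) {
    score <- vapply(split(h$jindex, h$gene_id), agg_fun, numeric(1))
    g <- names(score)
    ord <- order(-score, g)
    data.frame(tf_id = h$tf_id[1L], gene_id = g[ord],
               set_score = unname(score[ord]),
               S_rank = seq_along(ord), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  out[order(out$tf_id, out$S_rank), , drop = FALSE]
}

# gene set for one TF from the long frame
gene_set_for <- function(gene_sets, tf_id) {
  gs <- gene_sets[gene_sets$tf_id == tf_id, , drop = FALSE]
  gs[order(gs$S_rank), , drop = FALSE]
}
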