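#' Sliding-window profile of Jindex and RDE along a rank ordering
#'
#' Sorts a TF's paired genes by descending RDE (or by the weighted-rank key
#' `v_i * (S_i + R_i) / 2`, a reconstruction of the combined ordering) and
#' slides a window of size `w = ceiling(0.02 * n)` from the top of the
#' ordering to the bottom. Each window retains its member genes' Jindex and
#' RDE values for distribution plots, plus `Saverage` (the v-weighted mean
#' of the gene-set scores, i.e. Jindex) and `Laverage` (the v-weighted mean
#' of the gene-list scores, i.e. RDE).
#'
#' @param joined data.frame with one row per gene: `gene_id`, `jindex` (set
#'   score), `rde`, `weight` (the v_i of [compute_weights()]), and, for the
#'   weighted-rank ordering, `s_rank` and `r_rank`. [join_profile_input()]
#'   builds it from a [pair_ranks()] object and weights.
#' @param order_by `"rde"` (default) or `"weighted_rank"`.
#' @param step window step in genes (default 1).
#' @return An object of class `window_profile`: a list with `order_by`, `n`,
#'   `w`, `step`, `order` (gene ids in profile order), and `windows`, a list
#'   of per-window records (`start`, `end`, `gene_id`, `jindex`, `rde`,
#'   `weight`, `Saverage`, `Laverage`).
#' @export
sliding_profile <- function(joined, order_by = c("rde", "weighted_rank"),
                            step = 1L) {
  order_by <- match.arg(order_by)
  n <- nrow(joined)
  if (n == 0L) stop("empty profile input")
  stopifnot(step >= 1L)
  key <- if (order_by == "rde") joined$rde
         else joined$weight * (joined$s_rank + joined$r_rank) / 2
  ord <- order(-key, joined$gene_id)
  joined <- joined[ord, , drop = FALSE]
  w <- max(1L, as.integer(ceiling(0.02 * n)))
  starts <- seq.int(1L, by = step,
                    length.out = max(1L, (n - w) %/% step + 1L))
  last_end <- starts[length(starts)] + w - 1L
  if (last_end < n) starts <- c(starts, n - w + 1L)  # terminal partial cover
  windows <- lapply(starts, function(s) {
    idx <- s:(s + w - 1L)
    vv <- joined$weight[idx]
    list(start = s, end = s + w - 1L,
         gene_id = joined$gene_id[idx],
         jindex = joined$jindex[idx], rde = joined$rde[idx],
         weight = vv,
         Saverage = weighted.mean(joined$jindex[idx], vv),
         Laverage = weighted.mean(joined$rde[idx], vv))
  })
  structure(list(order_by = order_by, n = n, w = w, step = step,
                 order = joined$gene_id, windows = windows),
            class = "window_profile")
}

#' Assemble the per-gene input for [sliding_profile()]
#'
#' @param paired a [pair_ranks()] object.
#' @param v the weight vector from [compute_weights()].
#' @return A data.frame with `gene_id`, `jindex`, `rde`, `weight`,
#'   `s_rank`, `r_rank`.
#' @export
join_profile_input <- function(paired, v) {
  stopifnot(inherits(paired, "paired_ranks"), length(v) == paired$n)
  data.frame(gene_id = paired$gene_id, jindex = paired$set_score,
             rde = paired$rde, weight = v,
             s_rank = seq_len(paired$n), r_rank = paired$R,
             stringsAsFactors = FALSE)
}

#' Summarise a sliding-window profile
#'
#' @param profile a [sliding_profile()] object.
#' @return A data.frame, one row per window, with member count, quartiles
#'   and mean of the Jindex and RDE distributions, and the weighted
#'   `Saverage` / `Laverage`.
#' @export
profile_summary <- function(profile) {
  stopifnot(inherits(profile, "window_profile"))
  qs <- function(x) unname(quantile(x, c(0.25, 0.5, 0.75)))
  rows <- lapply(seq_along(profile$windows), function(k) {
    wd <- profile$windows[[k]]
    jq <- qs(wd$jindex); rq <- qs(wd$rde)
    data.frame(window = k, start = wd$start, end = wd$end,
               n_genes = length(wd$gene_id),
               jindex_q1 = jq[1], jindex_median = jq[2], jindex_q3 = jq[3],
               jindex_mean = mean(wd$jindex),
               rde_q1 = rq[1], rde_median = rq[2], rde_q3 = rq[3],
               rde_mean = mean(wd$rde),
               Saverage = wd$Saverage, Laverage = wd$Laverage)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
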