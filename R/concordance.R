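#' Pair a TF's set ranks with gene-list ranks
#'
#' Restricts the TF's target set and the ranked gene list to the genes
#' present in both, re-ranks each side 1..n within the intersection
#' preserving the original order, and returns the pairs `(i, R_i)` where
#' `R_i` is the (re-ranked) list rank of the gene holding set rank `i`.
#' Re-ranking within the intersection is what keeps the permutation null
#' exact: under no association, `R` is a uniform random permutation of 1..n.
#'
#' @param gene_set one TF's rows from [build_gene_sets()] (`gene_id`,
#'   `set_score`, `S_rank`).
#' @param gene_list the ranked list from [build_gene_list()].
#' @param min_overlap smallest usable intersection (default 3).
#' @return A list of class `paired_ranks` with `n`, `gene_id` (in set-rank
#'   order), `R` (paired list ranks), `set_score` and `rde` for the
#'   intersection genes — or `NULL`, with a message, when the overlap is
#'   below `min_overlap`.
#' @export
pair_ranks <- function(gene_set, gene_list, min_overlap = 3L) {
  common <- intersect(gene_set$gene_id, gene_list$gene_id)
  if (length(common) < min_overlap) {
    message("TF ", gene_set$tf_id[1L] %||% "?",
            " skipped: insufficient overlap (", length(common), ")")
    return(NULL)
  }
  gs <- gene_set[gene_set$gene_id %in% common, , drop = FALSE]
  gs <- gs[order(gs$S_rank), , drop = FALSE]        # set order preserved
  gl <- gene_list[gene_list$gene_id %in% common, , drop = FALSE]
  gl <- gl[order(gl$L_rank), , drop = FALSE]        # list order preserved
  list_rank <- setNames(seq_len(nrow(gl)), gl$gene_id)
  rde <- setNames(gl$rde, gl$gene_id)
  structure(
    list(n = length(common), gene_id = gs$gene_id,
         R = unname(list_rank[gs$gene_id]),
         set_score = gs$set_score, rde = unname(rde[gs$gene_id])),
    class = "paired_ranks")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pair weights for the weighted Kendall's tau
#'
#' The default `mixed_density` mode follows the pooled-rank-density idea:
#' the normalized set positions `i/n` and list positions `R_i/n` are pooled,
#' each point carrying mass proportional to its gene's |RDE| when RDE values
#' are available (equal mass otherwise); a Gaussian kernel density estimate
#' (Silverman's bandwidth) of the pooled mass is evaluated at `i/n` and
#' rescaled into `(eps, 1 - eps)`. When the differential-expression mass
#' concentrates at the top of the list, top set ranks thus receive more
#' weight. `uniform` gives every pair weight 0.5 (the classical Kendall tau
#' after normalization); `top_linear` decreases linearly from the top of the
#' set ranking, `v_i = (n - i + 1) / (n + 1)`.
#'
#' @param paired a [pair_ranks()] object.
#' @param mode `"mixed_density"` (default), `"uniform"`, or `"top_linear"`.
#' @param eps weights are confined to `(eps, 1 - eps)` (default 1e-6).
#' @return Numeric vector `v` of length `n`, all values in (0, 1).
#' @export
compute_weights <- function(paired,
                            mode = c("mixed_density", "uniform",
                                     "top_linear"),
                            eps = 1e-6) {
  mode <- match.arg(mode)
  n <- paired$n
  if (n < 3L) stop("need at least 3 paired ranks")
  if (mode == "uniform") return(rep(0.5, n))
  if (mode == "top_linear") return((n - seq_len(n) + 1) / (n + 1))
  i <- seq_len(n)
  x <- c(i / n, paired$R / n)
  w <- rep(1, 2L * n)
  if (!is.null(paired$rde) && any(is.finite(paired$rde)) &&
      any(abs(paired$rde) > 0)) {
    m <- abs(paired$rde)
    m[!is.finite(m)] <- 0
    if (sum(m) > 0) w <- c(m, m)
  }
  d <- density(x, weights = w / sum(w), bw = stats::bw.nrd0(x))
  v <- approx(d$x, d$y, xout = i / n, rule = 2)$y
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps) return(rep(0.5, n))
  eps + (1 - 2 * eps) * (v - rng[1]) / diff(rng)
}

#' Weighted Kendall's tau
#'
#' `tau_w = 2 / ((sum v)^2 - sum v^2) * sum_{i>j} v_i v_j sgn(i - j) sgn(R_i - R_j)`.
#' Pairs of top-weighted positions dominate the statistic; with constant
#' weights it reduces exactly to the classical Kendall tau. Bounded in
#' [-1, 1], equal to +1 when `R` is the identity and -1 when `R` is the
#' reversal, for any positive weights.
#'
#' @param v positive pair weights (length n, values in (0, 1)).
#' @param paired a [pair_ranks()] object, or a bare integer vector `R`.
#' @return The weighted tau, a single number in [-1, 1].
#' @export
weighted_kendall_tau <- function(v, paired) {
  R <- if (inherits(paired, "paired_ranks")) paired$R else paired
  n <- length(R)
  if (n < 2L) stop("need at least 2 paired ranks")
  if (length(v) != n) stop("weights and ranks differ in length")
  if (any(v <= 0)) stop("weights must be positive")
  D <- sum(v)^2 - sum(v^2)
  if (D <= 0) stop("degenerate weight vector: (sum v)^2 - sum v^2 <= 0")
  cpp_tau_w(as.numeric(v), as.numeric(R))
}

#' Exact permutation-null variance of the weighted Kendall's tau
#'
#' Variance of `tau_w` when `R` is a uniformly random permutation of 1..n.
#' Writing `tau_w = (2/D) * sum_{i>j} v_i v_j X_ij` with
#' `X_ij = sgn(R_i - R_j)`, the null covariances are `Var(X_ij) = 1`;
#' `Cov = +1/3` for two pairs sharing an index in the same slot (e.g.
#' `(i,j)` and `(i,k)`), `-1/3` when the shared index switches slots (e.g.
#' `(i,j)` and `(j,k)`), and 0 for disjoint pairs. Accumulated via
#' cumulative sums in O(n). For constant weights this reduces to the
#' classical Kendall null variance `2(2n + 5) / (9 n (n - 1))`.
#'
#' @param v positive pair weights (length n >= 3).
#' @return The null variance of `tau_w`, a positive number.
#' @export
null_variance <- function(v) {
  n <- length(v)
  if (n < 3L) stop("need at least 3 weights")
  if (any(v <= 0)) stop("weights must be positive")
  v <- as.numeric(v)
  D <- sum(v)^2 - sum(v^2)
  cs <- cumsum(v)          # sum_{j <= m} v_j
  cs2 <- cumsum(v^2)
  below <- cs - v          # sum_{j < m} v_j
  below2 <- cs2 - v^2
  above <- cs[n] - cs      # sum_{i > m} v_i
  above2 <- cs2[n] - cs2
  a <- v * below           # pair mass with m in the larger slot
  sa <- v^2 * below2
  b <- v * above           # pair mass with m in the smaller slot
  sb <- v^2 * above2
  S2 <- sum(sa)                                  # sum_{i>j} (v_i v_j)^2
  same <- sum((a^2 - sa) / 2 + (b^2 - sb) / 2)   # shared index, same slot
  cross <- sum(a * b)                            # shared index, cross slot
  (2 / D)^2 * (S2 + (2 / 3) * (same - cross))
}

#' Asymptotic p-value for the weighted tau
#'
#' Standardizes `tau_w` by its exact permutation-null standard deviation;
#' the standardized statistic is asymptotically standard normal, giving a
#' two-sided p-value.
#'
#' @param tau_w observed weighted tau.
#' @param var its null variance from [null_variance()].
#' @return A list with `ld` (the standardized statistic) and `p`.
#' @export
asymptotic_p <- function(tau_w, var) {
  if (!is.finite(var) || var <= 0) stop("variance must be positive")
  ld <- tau_w / sqrt(var)
  list(ld = ld, p = min(1, 2 * pnorm(-abs(ld))))
}

#' Permutation p-value for the weighted tau
#'
#' Two-sided empirical p-value against random permutations of `R`:
#' `p = (1 + #{|tau*| >= |tau_obs|}) / (n_perm + 1)`. With
#' `exhaustive = TRUE` (n <= 8) all n! permutations are enumerated and the
#' p-value is exact.
#'
#' @param v positive pair weights.
#' @param paired a [pair_ranks()] object or integer rank vector `R`.
#' @param n_perm number of random permutations (>= 100).
#' @param seed optional RNG seed for reproducibility.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return The p-value, a single number in (0, 1].
#' @export
permutation_p <- function(v, paired, n_perm = 999L, seed = NULL,
                          exhaustive = FALSE) {
  R <- if (inherits(paired, "paired_ranks")) paired$R else paired
  n <- length(R)
  obs <- abs(weighted_kendall_tau(v, R))
  tol <- 1e-12
  if (exhaustive) {
    if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
    taus <- cpp_tau_w_many(as.numeric(v), all_permutations(n))
    return(mean(abs(taus) >= obs - tol))
  }
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  taus <- cpp_perm_taus(as.numeric(v), as.integer(n_perm))
  (1 + sum(abs(taus) >= obs - tol)) / (n_perm + 1)
}

# all n! permutations of 1..n as columns of a matrix (n <= 8)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1L)
  cols <- lapply(seq_len(n), function(pos) {
    rbind(sub[seq_len(pos - 1L), , drop = FALSE],
          n,
          sub[seq(pos, n - 1L)[seq_len(n - pos)], , drop = FALSE])
  })
  do.call(cbind, cols)
}

#' Screen all TF gene sets against a ranked gene list
#'
#' Runs the weighted-tau concordance test for every TF with sufficient
#' overlap with the ranked list, adjusts p-values across TFs by
#' Benjamini-Hochberg, and labels each TF's direction: `positive`
#' (high-scoring targets upregulated, activator-like) or `negative`
#' (high-scoring targets downregulated, the repressor signature).
#'
#' @param gene_sets long data.frame from [build_gene_sets()].
#' @param gene_list ranked list from [build_gene_list()].
#' @param weighting weighting mode passed to [compute_weights()].
#' @param min_overlap smallest usable set/list intersection (default 3).
#' @param n_perm if > 0, also compute permutation p-values with this many
#'   permutations.
#' @param seed RNG seed used for the permutation p-values.
#' @return A data.frame, one row per tested TF, sorted by `p_asym`:
#'   `tf_id`, `n_overlap`, `tau_w`, `ld`, `p_asym`, `p_perm` (NA unless
#'   requested), `q_value`, `direction`, `weighting_mode`.
#' @export
screen_tfs <- function(gene_sets, gene_list,
                       weighting = c("mixed_density", "uniform",
                                     "top_linear"),
                       min_overlap = 3L, n_perm = 0L, seed = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(gene_list) || nrow(gene_list) == 0L)
    stop("empty gene list")
  if (nrow(gene_sets) == 0L) stop("no gene sets to screen")
  if (!is.null(seed)) set.seed(seed)
  tfs <- unique(gene_sets$tf_id)
  rows <- vector("list", length(tfs))
  for (k in seq_along(tfs)) {
    gs <- gene_set_for(gene_sets, tfs[k])
    paired <- pair_ranks(gs, gene_list, min_overlap = min_overlap)
    if (is.null(paired)) next
    v <- compute_weights(paired, mode = weighting)
    tau <- weighted_kendall_tau(v, paired)
    var <- null_variance(v)
    ap <- asymptotic_p(tau, var)
    pp <- if (n_perm > 0L)
      permutation_p(v, paired, n_perm = n_perm) else NA_real_
    rows[[k]] <- data.frame(
      tf_id = tfs[k], n_overlap = paired$n, tau_w = tau, ld = ap$ld,
      p_asym = ap$p, p_perm = pp,
      direction = if (tau >= 0) "positive" else "negative",
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no TF passed the overlap filter")
    return(data.frame(tf_id = character(), n_overlap = integer(),
                      tau_w = numeric(), ld = numeric(),
                      p_asym = numeric(), p_perm = numeric(),
                      q_value = numeric(), direction = character(),
                      weighting_mode = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q_value <- p.adjust(out$p_asym, method = "BH")
  out$weighting_mode <- weighting
  out <- out[order(out$p_asym, out$tf_id),
             c("tf_id", "n_overlap", "tau_w", "ld", "p_asym", "p_perm",
               "q_value", "direction", "weighting_mode")]
  rownames(out) <- NULL
  out
}
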