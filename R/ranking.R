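#' Raw score of differential expression (RDE)
#'
#' Collapses a gene's log2 fold change and FDR into one signed score,
#' `RDE = -sgn(log2FC) * 2^|log2FC| * log10(FDR)`. Since `log10(FDR) <= 0`
#' on (0, 1], upregulated genes get positive RDE and downregulated genes
#' negative RDE; the magnitude grows with both the fold change and the
#' significance. `RDE = 0` when `FDR = 1` or `log2FC = 0`.
#'
#' @param log2fc log2 fold change (vectorised).
#' @param fdr false discovery rate in (0, 1] (vectorised).
#' @return Numeric RDE value(s).
#' @examples
#' compute_rde(1, 0.01)   # 4
#' compute_rde(-1, 0.1)   # -2
#' @export
compute_rde <- function(log2fc, fdr) {
  if (any(!is.finite(fdr)) || any(fdr <= 0) || any(fdr > 1))
    stop("fdr must lie in (0, 1]")
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  -sign(log2fc) * 2^abs(log2fc) * log10(fdr)
}

#' Build the RDE-ranked gene list from a differential-expression table
#'
#' All genes are retained — no significance filter — since the concordance
#' test uses the full ranked transcriptome. Genes are ordered by descending
#' RDE (list rank `L_rank = 1` is the most upregulated); ties are broken by
#' gene identifier for reproducibility. An FDR reported as exactly 0 by an
#' upstream tool is clamped to the smallest positive FDR in the table (or
#' 1e-300 if there is none), with a warning.
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `fdr`.
#' @param descending rank 1 = largest RDE (default); set FALSE to flip.
#' @return The input plus columns `rde` and `L_rank`, sorted by `L_rank`.
#' @export
build_gene_list <- function(table, descending = TRUE) {
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (nrow(table) == 0L) stop("empty differential-expression table")
  dup <- unique(table$gene_id[duplicated(table$gene_id)])
  if (length(dup))
    stop("duplicate gene_id: ", paste(head(dup, 5), collapse = ", "))
  table$fdr <- clamp_fdr(table$fdr)
  table$rde <- compute_rde(table$log2fc, table$fdr)
  key <- if (descending) -table$rde else table$rde
  ord <- order(key, table$gene_id)
  out <- table[ord, , drop = FALSE]
  out$L_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

clamp_fdr <- function(fdr) {
  if (any(!is.finite(fdr)) || any(fdr < 0) || any(fdr > 1))
    stop("fdr must lie in [0, 1] before clamping")
  zero <- fdr == 0
  if (any(zero)) {
    floor_val <- if (any(!zero)) min(fdr[!zero]) else 1e-300
    warning(sum(zero), " FDR value(s) of 0 clamped to ",
            format(floor_val))
    fdr[zero] <- floor_val
  }
  fdr
}
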