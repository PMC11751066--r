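#' Read position frequency matrices from JASPAR-style text
#'
#' Format: a `>ID name` header followed by four rows `A [8 0 ...]`,
#' `C [...]`, `G [...]`, `T [...]` (brackets optional). Counts must be
#' nonnegative and all four rows of a matrix the same width.
#'
#' @param path file path.
#' @return A named list of 4 x L count matrices (rows A, C, G, T), names
#'   being the matrix identifiers. An empty file yields an empty list with
#'   a warning.
#' @export
read_pfm_file <- function(path) {
  if (!file.exists(path)) stop("PFM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) {
    warning("empty PFM file: ", path)
    return(list())
  }
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">"))
      stop("malformed PFM file at line ", i, ": expected '>' header, got '",
           lines[i], "'")
    id <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1]][1]
    if (id %in% names(out)) stop("duplicate matrix id: ", id)
    if (i + 4L > length(lines))
      stop("truncated matrix '", id, "' at line ", i)
    rows <- lapply(1:4, function(r) {
      line <- lines[i + r]
      base <- DNA_BASES[r]
      body <- sub(paste0("^\\s*", base, "?\\s*\\[?"), "", line)
      body <- sub("\\]\\s*$", "", body)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(body),
                                                   "\\s+")[[1]]))
      if (anyNA(vals) || !length(vals))
        stop("malformed count row for matrix '", id, "' at line ", i + r,
             ": '", line, "'")
      if (any(vals < 0))
        stop("negative count for matrix '", id, "' at line ", i + r)
      vals
    })
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L)
      stop("row width mismatch for matrix '", id, "' near line ", i + 1,
           ": widths ", paste(widths, collapse = "/"))
    counts <- do.call(rbind, rows)
    rownames(counts) <- DNA_BASES
    out[[id]] <- counts
    i <- i + 5L
  }
  out
}

#' Write PWMs or count matrices as JASPAR-style text
#'
#' @param x a named list of count matrices, or a list of `pwm` objects
#'   (probabilities are scaled by `scale` and rounded to pseudo-counts).
#' @param path output path.
#' @param scale count scale used when writing `pwm` objects (default 1000).
#' @export
write_pfm_file <- function(x, path, scale = 1000) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(x)) {
    el <- x[[k]]
    if (inherits(el, "pwm")) {
      id <- el$tf_id
      counts <- round(el$probs * scale)
    } else {
      id <- names(x)[k]
      counts <- el
    }
    writeLines(paste0(">", id), con)
    for (r in 1:4)
      writeLines(paste0(DNA_BASES[r], " [",
                        paste(counts[r, ], collapse = " "), "]"), con)
  }
  invisible(path)
}

#' Read a differential-expression table
#'
#' Accepts tab-separated tables with a header. Column names are resolved
#' through `column_map` when given; otherwise both generic
#' (`gene`/`gene_id`, `log2FC`, `FDR`) and limma-style (`logFC`,
#' `adj.P.Val`) headers are recognised. No significance filter is applied —
#' the ranked list uses all genes. FDR values of exactly 0 are clamped (see
#' [build_gene_list()]).
#'
#' @param path file path.
#' @param column_map optional named character vector mapping the internal
#'   names `gene_id`, `log2fc`, `fdr` to the file's column names.
#' @return A data.frame with columns `gene_id`, `log2fc`, `fdr`.
#' @export
read_de_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(internal, candidates) {
    if (!is.null(column_map) && internal %in% names(column_map)) {
      nm <- column_map[[internal]]
      if (!nm %in% names(tab))
        stop("mapped column '", nm, "' (for ", internal, ") not in table")
      return(nm)
    }
    hit <- candidates[candidates %in% names(tab)]
    if (!length(hit))
      stop("cannot find a column for ", internal, "; tried: ",
           paste(candidates, collapse = ", "))
    hit[1]
  }
  gcol <- pick("gene_id", c("gene_id", "gene", "ID", "Gene"))
  fcol <- pick("log2fc", c("log2FC", "log2fc", "logFC", "log2FoldChange"))
  qcol <- pick("fdr", c("FDR", "fdr", "adj.P.Val", "padj", "qvalue"))
  for (col in c(fcol, qcol)) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("non-numeric value in column '", col, "' at data row ", bad,
           ": '", tab[[col]][bad], "'")
    }
    tab[[col]] <- v
  }
  out <- data.frame(gene_id = as.character(tab[[gcol]]),
                    log2fc = tab[[fcol]], fdr = tab[[qcol]],
                    stringsAsFactors = FALSE)
  out$fdr <- clamp_fdr(out$fdr)
  out
}

#' Write TFBS hits as a BED-like table
#'
#' Columns: promoter gene, start, end (0-based half-open within the
#' promoter), tf_id, jindex, strand.
#'
#' @param hits hit table from [scan_promoters()].
#' @param path output path.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(promoter_gene = hits$gene_id, start = hits$offset,
                    end = hits$offset + hits$width, tf_id = hits$tf_id,
                    jindex = hits$jindex, strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write promoter sequences as FASTA
#'
#' @param promoters named character vector or [extract_promoters()] frame.
#' @param path output path.
#' @export
write_promoters_fasta <- function(promoters, path) {
  if (is.data.frame(promoters))
    promoters <- setNames(promoters$sequence, promoters$gene_id)
  dss <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences (names truncated at the
#'   first whitespace).
#' @export
read_promoters_fasta <- function(path) {
  if (!file.exists(path)) stop("promoters: file not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
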