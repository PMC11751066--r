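#' Extract TSS-proximal upstream promoter sequences
#'
#' Takes the region immediately upstream of each gene's transcription start
#' site on the gene's own strand. For a `+` strand gene with TSS at the GFF
#' `start` field the promoter is the 1-based inclusive interval
#' `[TSS - upstream_bp, TSS - 1]`, clipped at position 1; for a `-` strand
#' gene (TSS at `end`) it is the reverse complement of
#' `[TSS + 1, TSS + upstream_bp]`, clipped at the contig end. Promoters may
#' therefore be shorter than `upstream_bp` at contig edges; genes whose
#' promoter clips to zero length are skipped with a warning.
#'
#' @param genome a `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param annotation gene models: a path to a GFF3 file (its `gene` features
#'   are used, with the `ID` attribute as gene identifier), a
#'   `GenomicRanges::GRanges`, or a data.frame with columns `gene_id`,
#'   `contig`, `start`, `end`, `strand` (1-based inclusive, GFF convention).
#' @param upstream_bp promoter length in bp upstream of the TSS
#'   (default 550).
#' @return A data.frame with one row per extracted promoter: `gene_id`,
#'   `sequence` (on the gene's strand), `contig`, `start`, `end` (1-based
#'   inclusive reference coordinates of the extracted interval), `strand`,
#'   `length`.
#' @export
extract_promoters <- function(genome, annotation, upstream_bp = 550) {
  stopifnot(upstream_bp >= 1)
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("promoters: file not found: ", genome)
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  ann <- normalize_annotation(annotation)
  clens <- Biostrings::width(genome)
  names(clens) <- names(genome)
  missing <- setdiff(unique(ann$contig), names(genome))
  if (length(missing))
    stop("contig ", paste(missing, collapse = ", "), " not found")

  rows <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    contig <- ann$contig[i]
    clen <- clens[[contig]]
    if (ann$strand[i] == "+") {
      tss <- ann$start[i]
      lo <- max(1L, tss - upstream_bp)
      hi <- tss - 1L
    } else {
      tss <- ann$end[i]
      lo <- tss + 1L
      hi <- min(clen, tss + upstream_bp)
    }
    if (hi < lo || lo > clen || hi < 1L) {
      warning("skipping gene ", ann$gene_id[i],
              ": zero-length promoter after clipping")
      next
    }
    seq <- as.character(Biostrings::subseq(genome[[contig]], lo, hi))
    if (ann$strand[i] == "-") seq <- revcomp(seq)
    rows[[i]] <- data.frame(gene_id = ann$gene_id[i], sequence = seq,
                            contig = contig, start = lo, end = hi,
                            strand = ann$strand[i], length = hi - lo + 1L,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(gene_id = character(), sequence = character(),
                      contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      length = integer(), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

normalize_annotation <- function(annotation) {
  if (is.character(annotation)) {
    if (!file.exists(annotation))
      stop("annotation: file not found: ", annotation)
    gr <- rtracklayer::import(annotation, format = "gff3")
    gr <- gr[gr$type == "gene"]
    annotation <- data.frame(
      gene_id = as.character(gr$ID),
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  } else if (inherits(annotation, "GRanges")) {
    gr <- annotation
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
      if (!is.null(gr$gene_id)) as.character(gr$gene_id) else
        as.character(seq_along(gr))
    annotation <- data.frame(
      gene_id = ids,
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  }
  need <- c("gene_id", "contig", "start", "end", "strand")
  if (!all(need %in% names(annotation)))
    stop("annotation must provide columns: ", paste(need, collapse = ", "))
  if (!all(annotation$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  annotation
}
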