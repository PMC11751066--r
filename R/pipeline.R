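#' Pipeline configuration
#'
#' Collects the run settings with the study defaults: 550-bp promoters,
#' Jindex threshold 1.0, mixed-density weighting, max aggregation,
#' BH alpha 0.05. The configuration is serialized into every run's
#' metadata so results can be replayed exactly.
#'
#' @param promoter_length upstream promoter length in bp.
#' @param jindex_threshold minimum Jindex of a retained binding site.
#' @param weighting_mode pair-weighting mode for the concordance test.
#' @param aggregation per-gene hit aggregation for set scores.
#' @param both_strands scan both promoter strands.
#' @param min_overlap smallest usable set/list intersection.
#' @param n_perm permutation count for permutation p-values (0 = skip).
#' @param alpha BH significance threshold.
#' @param seed RNG seed for the run.
#' @param pfm_file,promoter_fasta,genome_fasta,annotation_gff,de_table
#'   input paths; give either `promoter_fasta` or `genome_fasta` +
#'   `annotation_gff`.
#' @param column_map DE-table column mapping (see [read_de_table()]).
#' @param out_dir output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(promoter_length = 550L, jindex_threshold = 1.0,
                       weighting_mode = "mixed_density",
                       aggregation = "max", both_strands = TRUE,
                       min_overlap = 3L, n_perm = 0L, alpha = 0.05,
                       seed = 1L, pfm_file = NULL, promoter_fasta = NULL,
                       genome_fasta = NULL, annotation_gff = NULL,
                       de_table = NULL, column_map = NULL,
                       out_dir = NULL) {
  structure(list(promoter_length = promoter_length,
                 jindex_threshold = jindex_threshold,
                 weighting_mode = weighting_mode,
                 aggregation = aggregation, both_strands = both_strands,
                 min_overlap = min_overlap, n_perm = n_perm, alpha = alpha,
                 seed = seed, pfm_file = pfm_file,
                 promoter_fasta = promoter_fasta,
                 genome_fasta = genome_fasta,
                 annotation_gff = annotation_gff, de_table = de_table,
                 column_map = column_map, out_dir = out_dir),
            class = "run_config")
}

#' Run the full screening pipeline
#'
#' Promoter acquisition (FASTA, or genome + GFF3 extraction), PWM scanning,
#' gene-set construction, RDE ranking, the weighted-tau screen across all
#' TFs, and a sliding-window profile of the top hit. When `out_dir` is set
#' in the config, writes `hits.bed.tsv`, `gene_sets.tsv`, `gene_list.tsv`,
#' `results.tsv`, `top_hit_profile.tsv`, and `run_metadata.json`.
#'
#' @param config a [run_config()] object.
#' @return Invisibly, a list with `hits`, `gene_sets`, `gene_list`,
#'   `results`, `top_profile` (profile summary of the most significant TF,
#'   or NULL), and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  promoters <- if (!is.null(config$promoter_fasta)) {
    read_promoters_fasta(config$promoter_fasta)
  } else if (!is.null(config$genome_fasta)) {
    prom <- extract_promoters(config$genome_fasta, config$annotation_gff,
                              upstream_bp = config$promoter_length)
    setNames(prom$sequence, prom$gene_id)
  } else stop("promoters: no promoter_fasta or genome_fasta given")

  if (is.null(config$pfm_file)) stop("pfm_file: no PFM input given")
  counts <- read_pfm_file(config$pfm_file)
  pwms <- lapply(names(counts), function(id)
    pfm_to_pwm(counts[[id]], tf_id = id))

  if (is.null(config$de_table)) stop("de_table: no DE input given")
  de <- read_de_table(config$de_table, column_map = config$column_map)

  hits <- scan_promoters(pwms, promoters,
                         threshold = config$jindex_threshold,
                         both_strands = config$both_strands)
  gene_sets <- build_gene_sets(hits, aggregate = config$aggregation)
  gene_list <- build_gene_list(de)
  results <- screen_tfs(gene_sets, gene_list,
                        weighting = config$weighting_mode,
                        min_overlap = config$min_overlap,
                        n_perm = config$n_perm, seed = config$seed)

  top_profile <- NULL
  if (nrow(results) > 0L) {
    top <- results$tf_id[1L]
    paired <- pair_ranks(gene_set_for(gene_sets, top), gene_list,
                         min_overlap = config$min_overlap)
    v <- compute_weights(paired, mode = config$weighting_mode)
    prof <- sliding_profile(join_profile_input(paired, v),
                            order_by = "weighted_rank")
    top_profile <- profile_summary(prof)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_hits_bed(hits, p("hits.bed.tsv"))
    write_tsv(gene_sets, p("gene_sets.tsv"))
    write_tsv(gene_list, p("gene_list.tsv"))
    write_tsv(results, p("results.tsv"))
    if (!is.null(top_profile)) write_tsv(top_profile,
                                         p("top_hit_profile.tsv"))
    meta <- list(
      package = "tfconcord",
      version = as.character(utils::packageVersion("tfconcord")),
      seed = config$seed,
      config = config[!vapply(config, is.null, logical(1))],
      n_pwms = length(pwms), n_promoters = length(promoters),
      n_hits = nrow(hits), n_genes = nrow(gene_list),
      input_digests = list(
        pfm_file = file_digest(config$pfm_file),
        de_table = file_digest(config$de_table),
        promoter_fasta = file_digest(config$promoter_fasta)))
    jsonlite::write_json(meta, p("run_metadata.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
  }
  invisible(list(hits = hits, gene_sets = gene_sets,
                 gene_list = gene_list, results = results,
                 top_profile = top_profile, config = config))
}

# lightweight content digest (sum of a simple rolling hash), avoids an
# external digest dependency; used only to fingerprint inputs in metadata
file_digest <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NULL)
  bytes <- readBin(path, "raw", file.info(path)$size)
  x <- as.integer(bytes)
  h <- 0
  m <- 2^31 - 1
  for (chunk in split(x, ceiling(seq_along(x) / 4096)))
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% m
  sprintf("%d:%d", length(bytes), h)
}
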