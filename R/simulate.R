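#' Generate random position weight matrices
#'
#' Each position's base probabilities are drawn from a symmetric Dirichlet.
#' Low concentration gives informative, near-consensus motifs; high
#' concentration gives near-uniform (uninformative) positions.
#'
#' @param k number of matrices.
#' @param length motif length in bp (>= 4).
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param seed RNG seed.
#' @param prefix identifier prefix; matrices are named `prefix1..prefixk`.
#' @param background base composition attached to the matrices.
#' @return A list of `pwm` objects.
#' @export
generate_pwms <- function(k, length = 12L, concentration = 0.5,
                          seed = NULL, prefix = "TF",
                          background = rep(0.25, 4)) {
  stopifnot(k >= 1L, length >= 4L, concentration > 0)
  background <- validate_background(background)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(k), function(i) {
    g <- matrix(rgamma(4L * length, shape = concentration), nrow = 4L)
    probs <- sweep(g, 2, colSums(g), "/")
    # keep probabilities bounded away from 0 so log-ratios stay finite
    probs <- sweep(probs + 1e-4, 2, colSums(probs + 1e-4), "/")
    dimnames(probs) <- list(DNA_BASES, NULL)
    new_pwm(paste0(prefix, i), probs, background, 0)
  })
}

#' Generate promoters with planted motif occurrences
#'
#' Background bases are i.i.d. from `base_comp`. A `planted_fraction` of the
#' genes receive one occurrence of the focal motif at a uniformly random
#' offset; the occurrence is sampled with a per-gene "strength" drawn
#' uniformly from `strength_range` — at each motif position the consensus
#' base is emitted with probability equal to the strength, otherwise a base
#' is drawn from the motif column with the consensus excluded. Strength
#' therefore tunes each planted gene's expected Jindex, creating the graded
#' site quality the concordance test ranks on. Decoy matrices are accepted
#' for interface symmetry but nothing is planted for them: decoys collect
#' targets only through chance background matches.
#'
#' @param n_genes number of promoters.
#' @param length promoter length in bp (default 550).
#' @param focal the focal `pwm` to plant.
#' @param planted_fraction fraction of genes receiving a planted site.
#' @param strength_range two-element range in (0, 1] for per-gene strength.
#' @param decoys optional list of decoy `pwm`s (not planted).
#' @param seed RNG seed.
#' @param base_comp background base composition (A, C, G, T).
#' @return A list with `sequences` (named character vector, `gene_1..`) and
#'   `truth` (data.frame `gene_id`, `planted`, `strength`, `offset`).
#' @export
generate_promoters <- function(n_genes, length = 550L, focal,
                               planted_fraction = 0.15,
                               strength_range = c(0.7, 0.95),
                               decoys = NULL, seed = NULL,
                               base_comp = rep(0.25, 4)) {
  stopifnot(n_genes >= 1L, planted_fraction >= 0, planted_fraction <= 1,
            inherits(focal, "pwm"))
  if (focal$length > length) stop("motif longer than promoter")
  base_comp <- validate_background(base_comp)
  if (!is.null(seed)) set.seed(seed)
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  n_plant <- round(planted_fraction * n_genes)
  planted <- logical(n_genes)
  if (n_plant > 0) planted[sample.int(n_genes, n_plant)] <- TRUE
  strength <- rep(NA_real_, n_genes)
  offset <- rep(NA_integer_, n_genes)
  consensus <- apply(focal$probs, 2, which.max)
  # all background bases in one draw; planting then edits the few needed
  bg <- matrix(sample.int(4L, n_genes * length, replace = TRUE,
                          prob = base_comp),
               nrow = n_genes)
  for (g in which(planted)) {
    s <- runif(1, strength_range[1], strength_range[2])
    occ <- vapply(seq_len(focal$length), function(p) {
      if (runif(1) < s) return(consensus[p])
      pr <- focal$probs[, p]
      pr[consensus[p]] <- 0
      sample.int(4L, 1L, prob = pr / sum(pr))
    }, integer(1))
    off <- sample.int(length - focal$length + 1L, 1L)
    bg[g, off:(off + focal$length - 1L)] <- occ
    strength[g] <- s
    offset[g] <- off - 1L
  }
  alphabet <- paste(DNA_BASES, collapse = "")
  seqs <- vapply(seq_len(n_genes), function(g)
    rawToChar(charToRaw(alphabet)[bg[g, ]]), character(1))
  list(sequences = setNames(seqs, gene_ids),
       truth = data.frame(gene_id = gene_ids, planted = planted,
                          strength = strength, offset = offset,
                          stringsAsFactors = FALSE))
}

#' Describe the planted regulator of a synthetic dataset
#'
#' @param focal_tf identifier of the planted TF.
#' @param effect_size mean RDE latent shift per standardized Jindex unit
#'   for the focal TF's targets (>= 0).
#' @param direction `"repressor"` (high-Jindex targets downregulated) or
#'   `"activator"`.
#' @param decoy_tfs identifiers of the decoy TFs.
#' @param seed RNG seed recorded for replay.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(focal_tf, effect_size = 1.0,
                            direction = c("repressor", "activator"),
                            decoy_tfs = character(), seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(effect_size >= 0)
  structure(list(focal_tf = focal_tf, effect_size = effect_size,
                 direction = direction, decoy_tfs = decoy_tfs,
                 seed = seed),
            class = "synthetic_truth")
}

#' Generate a differential-expression table with a planted regulator effect
#'
#' Each focal target gene (a gene with a finite entry in `gene_jindex`)
#' gets a latent score
#' `z = sign(direction) * effect_size * standardized Jindex + N(0, noise_sd)`;
#' every other gene is pure noise `N(0, noise_sd)`. The latent score is
#' mapped monotonically to a limma-style table: `log2fc = z` and
#' `fdr = 2 * pnorm(-|z| / noise_sd)` clamped to (1e-12, 1], so the RDE
#' ordering of the table reflects the latent ordering.
#'
#' @param truth a [synthetic_truth()] object.
#' @param gene_jindex named numeric vector of per-gene focal Jindex scores
#'   (only the focal TF's target genes; others omitted or NA).
#' @param gene_ids identifiers of all genes in the table.
#' @param noise_sd latent noise standard deviation (> 0).
#' @param seed RNG seed.
#' @return A data.frame with `gene_id`, `log2fc`, `fdr`.
#' @export
generate_de_table <- function(truth, gene_jindex, gene_ids,
                              noise_sd = 1.0, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), noise_sd > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(gene_ids)
  z <- rnorm(n, 0, noise_sd)
  gene_jindex <- gene_jindex[is.finite(gene_jindex)]
  idx <- match(names(gene_jindex), gene_ids)
  keep <- !is.na(idx)
  idx <- idx[keep]
  if (length(idx) && truth$effect_size > 0) {
    j <- gene_jindex[keep]
    js <- if (length(j) > 1L && sd(j) > 0) (j - mean(j)) / sd(j)
          else rep(0, length(j))
    dir_sign <- if (truth$direction == "repressor") -1 else 1
    z[idx] <- z[idx] + dir_sign * truth$effect_size * js
  }
  fdr <- pmin(pmax(2 * pnorm(-abs(z) / noise_sd), 1e-12), 1)
  data.frame(gene_id = gene_ids, log2fc = z, fdr = fdr,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic screening dataset
#'
#' Convenience bundle tying the generators together in the way the study
#' design assumes: random motifs (one focal, `n_decoys` decoys), promoters
#' with graded planted occurrences of the focal motif, a focal-PWM scan to
#' obtain each target's Jindex, and a differential-expression table whose
#' latent signal follows the planted Jindex with the requested direction.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_decoys number of decoy PWMs (default 24).
#' @param motif_length motif length in bp (default 12).
#' @param promoter_length promoter length in bp (default 550).
#' @param planted_fraction fraction of genes with a planted focal site
#'   (default 0.15).
#' @param effect_size latent shift per standardized Jindex (default 1.0).
#' @param direction `"repressor"` (default) or `"activator"`.
#' @param noise_sd latent noise SD (default 1.0).
#' @param concentration Dirichlet concentration for motif generation
#'   (default 0.5; informative motifs).
#' @param strength_range planted-site strength range (default 0.7-0.95).
#' @param threshold Jindex threshold used for the focal target definition
#'   (default 1.0).
#' @param seed RNG seed for the whole bundle.
#' @return A list with `pwms` (focal first), `promoters`, `de_table`,
#'   `truth`, `focal_jindex` (named vector over focal target genes), and
#'   the `seed`.
#' @export
simulate_dataset <- function(n_genes = 2000L, n_decoys = 24L,
                             motif_length = 12L, promoter_length = 550L,
                             planted_fraction = 0.15, effect_size = 1.0,
                             direction = "repressor", noise_sd = 1.0,
                             concentration = 0.5,
                             strength_range = c(0.7, 0.95),
                             threshold = 1.0, seed = 1L) {
  set.seed(seed)
  pwms <- generate_pwms(n_decoys + 1L, length = motif_length,
                        concentration = concentration)
  names(pwms) <- vapply(pwms, `[[`, character(1), "tf_id")
  focal <- pwms[[1L]]
  focal$tf_id <- "FOCAL"
  pwms[[1L]] <- focal
  names(pwms)[1L] <- "FOCAL"
  prom <- generate_promoters(n_genes, length = promoter_length,
                             focal = focal,
                             planted_fraction = planted_fraction,
                             strength_range = strength_range)
  hits <- scan_promoters(list(focal), prom$sequences,
                         threshold = threshold)
  focal_jindex <- if (nrow(hits))
    vapply(split(hits$jindex, hits$gene_id), max, numeric(1))
  else setNames(numeric(0), character(0))
  truth <- synthetic_truth("FOCAL", effect_size = effect_size,
                           direction = direction,
                           decoy_tfs = names(pwms)[-1L], seed = seed)
  de <- generate_de_table(truth, focal_jindex,
                          gene_ids = names(prom$sequences),
                          noise_sd = noise_sd)
  list(pwms = pwms, promoters = prom, de_table = de, truth = truth,
       focal_jindex = focal_jindex, seed = seed)
}
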