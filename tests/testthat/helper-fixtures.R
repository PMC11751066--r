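# Shared fixtures, built in code.

# two-position toy motif: position 1 all-A, position 2 all-C
toy_ac_pwm <- function(pseudocount = 0.25) {
  pfm_to_pwm(matrix(c(8, 0, 0, 0,
                      0, 8, 0, 0), nrow = 4),
             pseudocount = pseudocount, tf_id = "toyAC")
}

# a pwm whose probabilities equal the background at every position
flat_pwm <- function(length = 3) {
  pfm_to_pwm(matrix(2, nrow = 4, ncol = length), pseudocount = 0.25,
             tf_id = "flat")
}

random_pwm <- function(length = 6, tf_id = "rnd") {
  counts <- matrix(sample(0:9, 4 * length, replace = TRUE), nrow = 4)
  counts[1, colSums(counts) == 0] <- 1
  pfm_to_pwm(counts, pseudocount = 0.25, tf_id = tf_id)
}

# restrict a pwm to a subset of positions (for additivity checks)
new_sub_pwm <- function(pwm, positions) {
  tfconcord:::new_pwm(pwm$tf_id, pwm$probs[, positions, drop = FALSE],
                      pwm$background, pwm$pseudocount)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent brute-force rescan: scores every window with jindex_score()
# and string operations only (no shared code with the C++ scan path)
brute_force_scan <- function(pwm, seq, threshold = 1.0,
                             both_strands = TRUE) {
  rc_chr <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  L <- pwm$length
  n <- nchar(seq)
  rows <- list()
  for (off in seq_len(max(0, n - L + 1)) - 1L) {
    win <- substr(seq, off + 1, off + L)
    sc <- jindex_score(pwm, win)
    if (sc >= threshold)
      rows[[length(rows) + 1]] <- data.frame(
        offset = off, strand = "+", jindex = sc,
        stringsAsFactors = FALSE)
    if (both_strands) {
      sc <- jindex_score(pwm, rc_chr(win))
      if (sc >= threshold)
        rows[[length(rows) + 1]] <- data.frame(
          offset = off, strand = "-", jindex = sc,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(offset = integer(), strand = character(),
                      jindex = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# independent O(n^2) weighted tau by direct pairwise enumeration
brute_force_tau <- function(v, R) {
  n <- length(R)
  num <- 0
  for (i in 2:n) for (j in 1:(i - 1))
    num <- num + v[i] * v[j] * sign(i - j) * sign(R[i] - R[j])
  2 * num / (sum(v)^2 - sum(v^2))
}

# a paired_ranks object built directly (bypasses pair_ranks)
make_paired <- function(R, rde = NULL, set_score = NULL) {
  n <- length(R)
  structure(list(n = n, gene_id = sprintf("g%04d", seq_len(n)), R = R,
                 set_score = set_score %||% sort(runif(n),
                                                 decreasing = TRUE),
                 rde = rde),
            class = "paired_ranks")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# a small end-to-end synthetic screen, scaled down for unit tests
small_screen <- function(seed, effect_size = 1.0, n_genes = 400,
                         n_decoys = 6, direction = "repressor") {
  sim <- simulate_dataset(n_genes = n_genes, n_decoys = n_decoys,
                          effect_size = effect_size,
                          direction = direction, seed = seed)
  hits <- scan_promoters(sim$pwms, sim$promoters$sequences)
  gs <- build_gene_sets(hits)
  gl <- build_gene_list(sim$de_table)
  list(sim = sim, hits = hits, gene_sets = gs, gene_list = gl,
       results = screen_tfs(gs, gl))
}
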