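test_that("pfm_to_pwm smooths counts with a background pseudocount", {
  p <- toy_ac_pwm()
  expect_equal(unname(p$probs[, 1]),
               c(8.25 / 9, 0.25 / 9, 0.25 / 9, 0.25 / 9), tolerance = 1e-9)
  expect_equal(colSums(p$probs), rep(1, 2), tolerance = 1e-12)

  even <- pfm_to_pwm(matrix(2, nrow = 4, ncol = 3), pseudocount = 0.7)
  expect_equal(unname(even$probs), matrix(0.25, 4, 3), tolerance = 1e-12)

  expect_error(pfm_to_pwm(matrix(1, nrow = 3, ncol = 2)),
               "inconsistent matrix width")
  expect_error(pfm_to_pwm(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), nrow = 4),
                          pseudocount = 0),
               "degenerate position")
})

test_that("jindex_score is the summed log10 likelihood ratio", {
  p <- toy_ac_pwm()
  expect_equal(jindex_score(p, "AC"), 2 * log10((8.25 / 9) / 0.25),
               tolerance = 1e-9)
  expect_equal(jindex_score(p, "TT"), 2 * log10((0.25 / 9) / 0.25),
               tolerance = 1e-9)
  expect_equal(jindex_score(flat_pwm(), "ACG"), 0, tolerance = 1e-12)
  # N is neutral
  expect_equal(jindex_score(p, "NC"), log10((8.25 / 9) / 0.25),
               tolerance = 1e-12)
  expect_error(jindex_score(p, "ACG"), "length")
  expect_error(jindex_score(p, "AX"), "non-DNA")
})

test_that("jindex_score is additive over positions", {
  set.seed(41)
  for (rep in 1:20) {
    L <- sample(4:10, 1)
    p <- random_pwm(L)
    split_at <- sample(seq_len(L - 1), 1)
    win <- substr(random_dna(20), 1, L)
    left <- new_sub_pwm(p, 1:split_at)
    right <- new_sub_pwm(p, (split_at + 1):L)
    expect_equal(jindex_score(p, win),
                 jindex_score(left, substr(win, 1, split_at)) +
                   jindex_score(right, substr(win, split_at + 1, L)),
                 tolerance = 1e-12)
  }
})

test_that("replacing a base by a higher-probability base never lowers the score", {
  set.seed(42)
  for (rep in 1:20) {
    p <- random_pwm(6)
    win <- strsplit(substr(random_dna(6), 1, 6), "")[[1]]
    pos <- sample(6, 1)
    cur <- match(win[pos], c("A", "C", "G", "T"))
    better <- which.max(p$probs[, pos])
    win2 <- win
    win2[pos] <- c("A", "C", "G", "T")[better]
    expect_gte(jindex_score(p, paste(win2, collapse = "")) -
                 jindex_score(p, paste(win, collapse = "")), -1e-12)
  }
})

test_that("scan_promoter finds the toy site and respects the threshold", {
  p <- toy_ac_pwm()
  hit <- scan_promoter(p, "GGACGG", both_strands = FALSE)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$offset, 2L)
  expect_equal(hit$jindex, 2 * log10((8.25 / 9) / 0.25), tolerance = 1e-6)
  expect_equal(hit$jindex, 1.1287, tolerance = 1e-3)

  # background-equal pwm scores 0 everywhere: nothing passes threshold 1
  expect_equal(nrow(scan_promoter(flat_pwm(), random_dna(50))), 0L)
  # promoter shorter than motif
  expect_equal(nrow(scan_promoter(p, "G")), 0L)
  expect_error(scan_promoter(p, "GGAXGG"), "non-DNA")
})

test_that("scan_promoter matches an independent brute-force rescan", {
  set.seed(7)
  for (rep in 1:50) {
    p <- random_pwm(sample(5:10, 1), tf_id = paste0("R", rep))
    seq <- random_dna(200)
    got <- scan_promoter(p, seq, threshold = 0.5)
    want <- brute_force_scan(p, seq, threshold = 0.5)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$jindex, want$jindex, tolerance = 1e-9)
  }
})

test_that("batch scanning agrees with per-promoter scanning", {
  set.seed(8)
  pwms <- lapply(1:3, function(i) random_pwm(6, tf_id = paste0("T", i)))
  proms <- setNames(vapply(1:5, function(i) random_dna(80), character(1)),
                    paste0("g", 1:5))
  batch <- scan_promoters(pwms, proms, threshold = 0.5)
  single <- do.call(rbind, unlist(lapply(pwms, function(p)
    lapply(names(proms), function(g)
      scan_promoter(p, unname(proms[g]), threshold = 0.5, gene_id = g))),
    recursive = FALSE))
  ord <- function(d) {
    d <- d[order(d$tf_id, d$gene_id, d$offset, d$strand), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(batch), ord(single))
})

test_that("build_gene_sets aggregates hits and ranks deterministically", {
  hits <- data.frame(
    tf_id = c("TF1", "TF1", "TF1"),
    gene_id = c("g1", "g1", "g2"),
    offset = c(0L, 5L, 2L), width = 2L,
    strand = "+", jindex = c(1.2, 2.0, 1.5), stringsAsFactors = FALSE)
  gs <- build_gene_sets(hits)
  expect_equal(gs$gene_id, c("g1", "g2"))
  expect_equal(gs$set_score, c(2.0, 1.5))
  expect_equal(gs$S_rank, c(1L, 2L))

  # single hit
  one <- build_gene_sets(hits[3, ])
  expect_equal(one$S_rank, 1L)

  # equal scores break ties by gene id
  tie <- data.frame(tf_id = "TF1", gene_id = c("gB", "gA"), offset = 0L,
                    width = 2L, strand = "+", jindex = c(1.5, 1.5),
                    stringsAsFactors = FALSE)
  gs_tie <- build_gene_sets(tie)
  expect_equal(gs_tie$gene_id, c("gA", "gB"))
  expect_equal(gs_tie$S_rank, c(1L, 2L))

  # empty input is not an error
  expect_equal(nrow(build_gene_sets(hits[0, ])), 0L)

  # alternative aggregations
  expect_equal(build_gene_sets(hits, "sum")$set_score, c(3.2, 1.5))
  expect_equal(build_gene_sets(hits, "count")$set_score, c(2, 1))
})

test_that("gene-set size equals distinct (tf, gene) pairs with a hit", {
  set.seed(9)
  pwms <- lapply(1:4, function(i) random_pwm(5, tf_id = paste0("T", i)))
  proms <- setNames(vapply(1:30, function(i) random_dna(120),
                           character(1)), paste0("g", 1:30))
  hits <- scan_promoters(pwms, proms, threshold = 0.8)
  gs <- build_gene_sets(hits)
  expect_equal(nrow(gs), nrow(unique(hits[, c("tf_id", "gene_id")])))
  # S ranks are a permutation within each set
  for (tf in unique(gs$tf_id)) {
    s <- gs$S_rank[gs$tf_id == tf]
    expect_setequal(s, seq_along(s))
  }
})
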