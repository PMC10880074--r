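test_that("a constructed consensus placement is found with exact geometry", {
  withr::local_seed(406)
  pair <- fixture_pair()
  c35 <- consensus(pair$pssm35); c10 <- consensus(pair$pssm10)
  # -35 box, 16 nt spacer, -10 box, 3 intervening bases, then the TSS base
  seq <- paste0(c35, random_dna(16), c10, random_dna(3), "A")
  w <- sequence_window(seq, anchor_tss_offset = nchar(seq))
  h <- all_hits(w, pair)
  top <- h[which.max(h$total), ]
  expect_equal(top$pos35, 1L)
  expect_equal(top$spacer, 16L)
  expect_equal(top$tss_distance, 3L)
  expect_equal(top$total,
               score_subsequence(pair$pssm35, c35) +
                 score_subsequence(pair$pssm10, c10))
  expect_equal(top$total, max(h$total))

  # too short for the minimal spacer: empty, not an error
  short <- sequence_window(random_dna(7 + 14 + 6))
  expect_equal(nrow(all_hits(short, pair)), 0L)
  expect_null(best_hit(short, pair))
  expect_error(all_hits(sequence_window("ACGTNACGT"), pair), "non-ACGT")
})

test_that("unanchored placement counts match the closed form", {
  withr::local_seed(407)
  pair <- fixture_pair()
  L <- pair$pssm35$length + pair$pssm10$length
  for (N in seq(40, 80, by = 8)) {
    w <- sequence_window(random_dna(N))
    expected <- sum(pmax(0, N - L - (pair$spacer_min:pair$spacer_max) + 1))
    expect_equal(nrow(all_hits(w, pair)), expected)
  }
})

test_that("every emitted hit satisfies the placement geometry", {
  withr::local_seed(408)
  pair <- random_pair()
  for (i in 1:20) {
    anchored <- i %% 2 == 0
    n <- sample(35:70, 1)
    w <- sequence_window(random_dna(n),
                         anchor_tss_offset = if (anchored) n else NA)
    h <- all_hits(w, pair)
    if (!nrow(h)) next
    expect_true(all(h$spacer >= 15 & h$spacer <= 17))
    expect_true(all(h$pos10 == h$pos35 + pair$pssm35$length + h$spacer))
    if (anchored)
      expect_true(all(h$tss_distance >= 3 & h$tss_distance <= 6))
    expect_equal(h$total, h$s35 + h$s10, tolerance = 1e-12)
    expect_true(all(h$total <=
                      score_subsequence(pair$pssm35, consensus(pair$pssm35)) +
                      score_subsequence(pair$pssm10, consensus(pair$pssm10)) +
                      1e-12))
  }
})

test_that("best_hit maximizes the total with documented tie-breaks", {
  withr::local_seed(409)
  pair <- random_pair()
  for (i in 1:50) {
    w <- sequence_window(random_dna(60),
                         anchor_tss_offset = if (i %% 2) 60 else NA)
    h <- all_hits(w, pair)
    b <- best_hit(w, pair)
    if (!nrow(h)) { expect_null(b); next }
    expect_equal(b$total, max(h$total))
    ref <- naive_enumerate(w$seq, pair, anchor = w$anchor_tss_offset)
    expect_equal(b$total, max(ref$total), tolerance = 1e-9)
  }
  # all placements tie under uniform matrices: smallest spacer wins, then
  # the placement closest to the 3' end
  unif35 <- pssm_from_probs(matrix(0.25, 4, 4), box = "minus35",
                            pseudocount = 0)
  unif10 <- pssm_from_probs(matrix(0.25, 4, 4), box = "minus10",
                            pseudocount = 0)
  upair <- pssm_pair("U", unif35, unif10)
  w <- sequence_window(random_dna(50))
  b <- best_hit(w, upair)
  expect_equal(b$spacer, 15L)
  expect_equal(b$pos35, 50L - 4L - 15L - 4L + 1L)
})

test_that("empirical E-values hit the trivial bounds and are seeded", {
  withr::local_seed(410)
  pair <- fixture_pair()
  w <- sequence_window(random_dna(45))
  # any positive total beats every (<= 0) shuffled score; -Inf loses to all
  expect_equal(empirical_evalue(w, pair, 1, n = 50), 0)
  expect_equal(empirical_evalue(w, pair, -Inf, n = 50), 1)
  expect_equal(empirical_evalue(w, pair, -Inf, n = 49, laplace = TRUE), 1)
  e1 <- empirical_evalue(w, pair, -20, n = 200, seed = 99)
  e2 <- empirical_evalue(w, pair, -20, n = 200, seed = 99)
  expect_identical(e1, e2)
  expect_gte(e1, 0); expect_lte(e1, 1)
})

test_that("E-values are invariant under joint base relabelling", {
  withr::local_seed(411)
  pair <- random_pair()
  perm <- c(G = "A", T = "C", A = "G", C = "T")  # relabelling map
  relabel_pssm <- function(p) {
    lp <- p$logprob[match(c("A", "C", "G", "T"), perm[c("A","C","G","T")]), ,
                    drop = FALSE]
    rownames(lp) <- c("A", "C", "G", "T")
    pssm(lp, p$motif_id, p$box)
  }
  seq <- random_dna(50)
  seq2 <- chartr("ACGT", paste(perm[c("A", "C", "G", "T")], collapse = ""),
                 seq)
  pair2 <- pssm_pair("P2", relabel_pssm(pair$pssm35),
                     relabel_pssm(pair$pssm10))
  w1 <- sequence_window(seq); w2 <- sequence_window(seq2)
  b1 <- best_hit(w1, pair); b2 <- best_hit(w2, pair2)
  expect_equal(b1$total, b2$total, tolerance = 1e-12)
  expect_identical(empirical_evalue(w1, pair, b1, n = 300, seed = 7),
                   empirical_evalue(w2, pair2, b2, n = 300, seed = 7))
})

test_that("minus-strand scanning mirrors the plus strand", {
  withr::local_seed(412)
  pair <- fixture_pair()
  site <- sample_site(pair)
  d <- 4L
  fwd <- paste0(random_dna(25), site$seq, random_dna(d), "A", random_dna(25))
  tss_fwd <- 25L + nchar(site$seq) + d + 1L
  L <- nchar(fwd)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  g1 <- Biostrings::DNAStringSet(c(ctg = fwd))  # site on + strand
  g2 <- Biostrings::DNAStringSet(c(ctg = rc))   # same site on - strand
  w1 <- tss_upstream_window(g1, "ctg", "+", tss_fwd)
  w2 <- tss_upstream_window(g2, "ctg", "-", L - tss_fwd + 1L)
  expect_identical(w1$seq, w2$seq)  # transcription orientation is shared
  b1 <- best_hit(w1, pair); b2 <- best_hit(w2, pair)
  expect_equal(b1[c("s35", "s10", "total", "spacer", "tss_distance")],
               b2[c("s35", "s10", "total", "spacer", "tss_distance")])
  # genomic box coordinates mirror across the contig
  expect_equal(b2$g35_end, L - b1$g35_start + 1L)
  expect_equal(b2$g10_start, L - b1$g10_end + 1L)
})

test_that("TSS-anchored scans recover planted promoters and clip edges", {
  withr::local_seed(413)
  pair <- fixture_pair()
  site <- sample_site(pair)  # consensus site
  d <- 3L
  left <- random_dna(30)
  seq <- paste0(left, site$seq, random_dna(d), "G", random_dna(10))
  tss_pos <- nchar(left) + nchar(site$seq) + d + 1L
  genome <- Biostrings::DNAStringSet(c(ctg = seq))
  tss <- data.frame(contig = "ctg", strand = "+", pos = tss_pos)
  hits <- tss_anchored_scan(tss, genome, pair, n_null = 200)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$tss_distance, d)
  expect_equal(hits$g35_start, nchar(left) + 1L)
  expect_lte(hits$evalue, 0.05)

  # a TSS too close to the 5' edge gives a clipped window and no hit
  near <- data.frame(contig = "ctg", strand = "+", pos = 5L)
  expect_equal(nrow(tss_anchored_scan(near, genome, pair, n_null = 10)), 0L)
  off <- data.frame(contig = "ctg", strand = "+", pos = nchar(seq) + 10L)
  expect_error(tss_anchored_scan(off, genome, pair), "outside")
})
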