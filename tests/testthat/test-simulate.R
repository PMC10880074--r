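test_that("sampled sites respect the geometry and score bounds", {
  withr::local_seed(423)
  pair <- fixture_pair()
  cons_total <- score_subsequence(pair$pssm35, consensus(pair$pssm35)) +
    score_subsequence(pair$pssm10, consensus(pair$pssm10))
  for (i in 1:30) {
    s <- sample_site(pair, strength = "sampled")
    expect_true(s$spacer %in% 15:17)
    expect_equal(nchar(s$seq),
                 pair$pssm35$length + s$spacer + pair$pssm10$length)
    tot <- score_subsequence(pair$pssm35, s$box35) +
      score_subsequence(pair$pssm10, s$box10)
    expect_lte(tot, cons_total + 1e-12)
  }
  s <- sample_site(pair, strength = "consensus", seed = 1)
  expect_equal(s$box35, consensus(pair$pssm35))
  expect_equal(s$box10, consensus(pair$pssm10))
})

test_that("sampled-site mean score approaches the negative motif entropy", {
  withr::local_seed(424)
  pair <- fixture_pair()
  # closed form: E[score] = sum over columns of sum_b p_b * log2 p_b
  expected <- sum(vapply(list(pair$pssm35, pair$pssm10), function(p)
    sum(2^p$logprob * p$logprob), numeric(1)))
  draws <- replicate(400, {
    s <- sample_site(pair, strength = "sampled")
    score_subsequence(pair$pssm35, s$box35) +
      score_subsequence(pair$pssm10, s$box10)
  })
  # Monte-Carlo tolerance: 4 standard errors
  expect_lt(abs(mean(draws) - expected), 4 * sd(draws) / sqrt(length(draws)))
})

test_that("generated genomes honour GC, packing and ground truth", {
  pair <- fixture_pair()
  sim0 <- generate_genome(pair, n_features = 10, contig_len = 8000,
                          n_regulated = 0, seed = 71)
  expect_null(sim0$truth$planted_promoters)

  sim <- generate_genome(pair, n_features = 60, contig_len = 100000,
                         gc = 0.62, n_regulated = 10, seed = 72)
  freq <- Biostrings::alphabetFrequency(sim$genome[[1]])
  gc <- sum(freq[c("C", "G")]) / sum(freq[c("A", "C", "G", "T")])
  expect_lt(abs(gc - 0.62), 0.01)

  # every planted consensus site is recovered exactly by best_hit
  ws <- extract_feature_windows(sim$genome, sim$features)
  tr <- sim$truth$planted_promoters
  for (i in seq_len(nrow(tr))) {
    b <- best_hit(ws[[tr$feature_id[i]]], pair)
    expect_equal(b$g35_start, tr$g35_start[i])
    expect_equal(b$g10_start, tr$g10_start[i])
    expect_equal(b$spacer, tr$spacer[i])
  }
  # planted TSS geometry: 3-6 intervening bases after the -10 box
  expect_true(all(tr$tss_dist >= 3 & tr$tss_dist <= 6))
  expect_true(all(tr$spacer >= 15 & tr$spacer <= 17))

  expect_error(generate_genome(pair, n_features = 100, contig_len = 5000),
               "infeasible packing")
  # seed determinism
  a <- generate_genome(pair, n_features = 10, contig_len = 8000,
                       n_regulated = 2, seed = 73)
  b <- generate_genome(pair, n_features = 10, contig_len = 8000,
                       n_regulated = 2, seed = 73)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$planted_promoters, b$truth$planted_promoters)
})

test_that("simulated count tracks carry signal at planted TSS only in the treatment", {
  pair <- fixture_pair()
  sim <- generate_genome(pair, n_features = 40, contig_len = 30000,
                         n_regulated = 5, seed = 81)
  tracks <- simulate_tss_counts(sim$truth, depth = 3e5, seed = 82)
  expect_equal(tracks$treatment$rt, 3e5)
  expect_equal(tracks$control$rt, 3e5)

  pt <- sim$truth$planted_tss
  near_mass <- function(track, pos, strand) {
    d <- track$counts
    sum(d$count[d$strand == strand & abs(d$pos - pos) <= 1])
  }
  t_mass <- mapply(near_mass, pos = pt$pos, strand = pt$strand,
                   MoreArgs = list(track = tracks$treatment))
  c_mass <- mapply(near_mass, pos = pt$pos, strand = pt$strand,
                   MoreArgs = list(track = tracks$control))
  expect_true(all(t_mass > 1000))   # ~6000 reads expected per TSS
  expect_true(all(c_mass <= 3))     # scatter only near planted TSS
  # signal jitter stays within +/-1 nt: the dominant call is the exact TSS
  called <- select_tss(cluster_tss_all(compute_rrs(tracks$treatment)),
                       min_rrs = 3)
  expect_true(all(paste(pt$strand, pt$pos) %in%
                    paste(called$strand, called$pos)))

  empty <- simulate_tss_counts(sim$truth, depth = 0, seed = 83)
  expect_error(compute_rrs(empty$treatment), "empty sample")
})

test_that("with no planted signal almost nothing is strain-specific", {
  pair <- fixture_pair()
  sim <- generate_genome(pair, n_features = 40, contig_len = 50000,
                         n_regulated = 5, seed = 91)
  tracks <- simulate_tss_counts(sim$truth, depth = 1e6,
                                signal_fraction = 0, seed = 92)
  call <- function(tr) select_tss(cluster_tss_all(compute_rrs(tr)), 3)
  spec <- strain_specific_tss(call(tracks$treatment), call(tracks$control))
  # only rare uniform-scatter coincidences (P(Pois(0.1) >= 3) ~ 1.5e-4/base)
  expect_lt(nrow(spec), 60)
})

test_that("the DE table flags exactly the planted units when the effect passes the filter", {
  pair <- fixture_pair()
  sim <- generate_genome(pair, n_features = 30, contig_len = 20000,
                         n_regulated = 4, seed = 101)
  de4 <- simulate_de_table(sim$truth, sim$features, effect_log2fc = 4,
                           seed = 102)
  reg <- regulated_units(de4)
  expect_setequal(sub("^unit_", "", reg$unit_id),
                  sim$truth$planted_regulated_units)

  de1 <- simulate_de_table(sim$truth, sim$features, effect_log2fc = 1,
                           seed = 103)
  expect_equal(nrow(regulated_units(de1)), 0L)  # filter is log2fc > 2
})

test_that("a written simulation directory is complete and readable", {
  pair <- fixture_pair()
  sim <- generate_genome(pair, n_features = 12, contig_len = 10000,
                         n_regulated = 2, seed = 111)
  tracks <- simulate_tss_counts(sim$truth, depth = 1e5, seed = 112)
  de <- simulate_de_table(sim$truth, sim$features, seed = 113)
  dir <- withr::local_tempdir()
  write_simulation(sim, tracks, de, dir)
  expect_setequal(
    list.files(dir),
    c("genome.fa", "features.gff3", "treatment_fwd.bedgraph",
      "treatment_rev.bedgraph", "control_fwd.bedgraph",
      "control_rev.bedgraph", "de_table.tsv", "truth.json"))
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(sim$genome))
  f <- read_features(file.path(dir, "features.gff3"))
  expect_equal(f$feature_id, sim$features$feature_id)
  expect_equal(f$start, sim$features$start)
  tr <- read_start_counts(fwd = file.path(dir, "treatment_fwd.bedgraph"),
                          rev = file.path(dir, "treatment_rev.bedgraph"))
  expect_equal(tr$counts, tracks$treatment$counts)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$planted_tss$pos, sim$truth$planted_tss$pos)
})
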