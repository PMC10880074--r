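# Independent brute-force oracles and small fixture builders shared by the
# tests. The oracles deliberately avoid every code path of the package
# functions they check.

# random PSSM with smoothed continuous column probabilities
random_pssm <- function(L, box, rng_round = FALSE) {
  probs <- matrix(runif(4 * L, 0.02, 1), nrow = 4)
  pssm_from_probs(probs, motif_id = paste0("rand_", box), box = box,
                  pseudocount = 0)
}

random_pair <- function(L35 = 7, L10 = 6, ...) {
  pssm_pair("RAND", random_pssm(L35, "minus35"), random_pssm(L10, "minus10"),
            ...)
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# score one subsequence by direct per-column lookup (no package scan code)
naive_score <- function(logprob, seq_chars, from) {
  L <- ncol(logprob)
  idx <- match(seq_chars[from:(from + L - 1)], c("A", "C", "G", "T"))
  sum(logprob[cbind(idx, seq_len(L))])
}

# exhaustive enumeration of every bipartite placement in a window;
# returns a data.frame of (pos35, pos10, spacer, tss_distance, total)
naive_enumerate <- function(seq, pair, anchor = NA) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  L35 <- pair$pssm35$length
  L10 <- pair$pssm10$length
  out <- list()
  for (pos35 in seq_len(max(0, n - L35 + 1))) {
    for (sp in pair$spacer_min:pair$spacer_max) {
      pos10 <- pos35 + L35 + sp
      if (pos10 + L10 - 1 > n) next
      tssd <- NA_integer_
      if (!is.na(anchor)) {
        tssd <- anchor - (pos10 + L10 - 1) - 1
        if (tssd < pair$tss_dist_min || tssd > pair$tss_dist_max) next
      }
      out[[length(out) + 1]] <- data.frame(
        pos35 = pos35, pos10 = pos10, spacer = sp, tss_distance = tssd,
        total = naive_score(pair$pssm35$logprob, chars, pos35) +
          naive_score(pair$pssm10$logprob, chars, pos10))
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# transitive-closure clustering oracle: positions belong to one cluster iff
# connected through pairwise gaps <= max_gap (graph components)
oracle_clusters <- function(pos, max_gap = 3) {
  adj <- abs(outer(pos, pos, "-")) <= max_gap
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# O(n^2) Pareto dominance oracle (maximization of s35 and s10)
oracle_pareto <- function(hits) {
  n <- nrow(hits)
  keep <- vapply(seq_len(n), function(i) {
    !any(hits$s35 >= hits$s35[i] & hits$s10 >= hits$s10[i] &
           (hits$s35 > hits$s35[i] | hits$s10 > hits$s10[i]))
  }, logical(1))
  hits[keep, , drop = FALSE]
}

# minimal hits frame for calibration tests
hits_frame <- function(s35, s10, evalue = 0.02) {
  data.frame(window_id = "w", contig = NA, strand = "+",
             pos35 = seq_along(s35), pos10 = seq_along(s35) + 20L,
             spacer = 15L, s35 = s35, s10 = s10, total = s35 + s10,
             tss_distance = NA_integer_, g35_start = NA_integer_,
             g35_end = NA_integer_, g10_start = NA_integer_,
             g10_end = NA_integer_, evalue = evalue)
}

# canonical low-entropy pair used across the simulation tests
fixture_pair <- function() toy_pssm_pair()
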