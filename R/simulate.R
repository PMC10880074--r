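#' A low-entropy toy PSSM pair for simulation and testing
#'
#' Builds a -35/-10 pair in which each column gives probability `dominance`
#' to the consensus base and splits the remainder over the other three. With
#' `dominance` close to 1 the motif is strongly informative, mimicking the
#' concentrated base preferences of ECF promoter boxes.
#'
#' @param ecf_group group label.
#' @param consensus35,consensus10 consensus strings for the two boxes.
#' @param dominance probability of the consensus base per column.
#' @inheritParams pssm_pair
#' @return a [pssm_pair()].
#' @export
toy_pssm_pair <- function(ecf_group = "ECFtoy", consensus35 = "GGAACTT",
                          consensus10 = "GTCAAA", dominance = 0.85,
                          spacer_min = 15L, spacer_max = 17L,
                          tss_dist_min = 3L, tss_dist_max = 6L) {
  stopifnot(dominance > 0.25, dominance < 1)
  build <- function(cons, box) {
    codes <- encode_dna(cons)
    probs <- matrix((1 - dominance) / 3, nrow = 4L, ncol = length(codes))
    probs[cbind(codes, seq_along(codes))] <- dominance
    pssm_from_probs(probs, motif_id = paste0(ecf_group, "_", box), box = box,
                    pseudocount = 0)
  }
  pssm_pair(ecf_group, build(consensus35, "minus35"),
            build(consensus10, "minus10"),
            spacer_min = spacer_min, spacer_max = spacer_max,
            tss_dist_min = tss_dist_min, tss_dist_max = tss_dist_max)
}

#' Draw one bipartite promoter site from a PSSM pair
#'
#' In `consensus` mode the site is consensus(-35) + a uniform-random spacer
#' (length drawn uniformly from the pair's spacer range) + consensus(-10),
#' i.e. the maximally scoring site. In `sampled` mode each box is drawn
#' column-wise from the PSSM probabilities instead.
#'
#' @param pair a [pssm_pair()].
#' @param strength `"consensus"` or `"sampled"`.
#' @param seed optional local RNG seed.
#' @return list with `seq` (the site string), `spacer`, `box35`, `box10`.
#' @export
sample_site <- function(pair, strength = c("consensus", "sampled"),
                        seed = NULL) {
  strength <- match.arg(strength)
  stopifnot(inherits(pair, "pssm_pair"))
  with_rng_seed(seed, {
    spacer <- sample(pair$spacer_min:pair$spacer_max, 1L)
    draw_box <- function(p) {
      if (strength == "consensus") return(consensus(p))
      probs <- 2^p$logprob
      decode_dna(vapply(seq_len(p$length), function(j)
        sample.int(4L, 1L, prob = probs[, j]), integer(1L)))
    }
    b35 <- draw_box(pair$pssm35)
    b10 <- draw_box(pair$pssm10)
    sp <- decode_dna(sample.int(4L, spacer, replace = TRUE))
    list(seq = paste0(b35, sp, b10), spacer = spacer, box35 = b35,
         box10 = b10)
  })
}

#' Generate a synthetic genome with planted promoter sites
#'
#' Emits an i.i.d. background sequence at the requested GC content with
#' `n_features` short gene features evenly spaced on alternating strands.
#' For `n_regulated` randomly chosen features a promoter site drawn from the
#' PSSM pair is planted upstream so that its TSS lies 3-6 intervening bases
#' downstream of the -10 box, 20-40 nt upstream of the feature start (a
#' short 5' UTR), and therefore well inside the feature's 500-up/100-down
#' window. All planted coordinates are recorded as ground truth.
#'
#' @param pair a [pssm_pair()].
#' @param n_features number of gene features.
#' @param contig_len contig length in bp.
#' @param gc background GC fraction.
#' @param n_regulated number of features receiving a planted promoter.
#' @param strength site strength passed to [sample_site()].
#' @param feature_len gene body length in bp.
#' @param seed optional local RNG seed (recorded in the truth).
#' @return list with `genome` (`DNAStringSet`), `features` (data.frame as
#'   from [read_features()]) and `truth` (class `synthetic_truth`: planted
#'   promoters, planted TSS, planted regulated feature ids, contig metadata,
#'   seed).
#' @export
generate_genome <- function(pair, n_features = 200L, contig_len = 100000L,
                            gc = 0.62, n_regulated = 10L,
                            strength = c("consensus", "sampled"),
                            feature_len = 120L, seed = NULL) {
  strength <- match.arg(strength)
  stopifnot(inherits(pair, "pssm_pair"), n_regulated <= n_features,
            gc > 0, gc < 1)
  L35 <- pair$pssm35$length; L10 <- pair$pssm10$length
  site_max <- L35 + pair$spacer_max + L10
  interval <- contig_len %/% n_features
  margin <- (interval - feature_len) %/% 2L
  if (margin < 40L + pair$tss_dist_max + site_max + 5L)
    stop("infeasible packing: ", n_features, " features of ", feature_len,
         " bp plus promoter clearance do not fit in ", contig_len, " bp")
  contig <- "synth_contig_1"
  with_rng_seed(seed, {
    base_probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    codes <- sample.int(4L, contig_len, replace = TRUE, prob = base_probs)
    starts <- (seq_len(n_features) - 1L) * interval + margin + 1L
    strands <- rep(c("+", "-"), length.out = n_features)
    features <- data.frame(
      feature_id = sprintf("gene_%03d", seq_len(n_features)),
      contig = contig, strand = strands,
      start = starts, end = starts + feature_len - 1L,
      feature_type = "gene")
    reg_idx <- sort(sample.int(n_features, n_regulated))
    promoters <- list(); tss <- list()
    for (i in reg_idx) {
      site <- sample_site(pair, strength = strength)
      slen <- nchar(site$seq)
      d <- sample(pair$tss_dist_min:pair$tss_dist_max, 1L)
      utr <- sample(20:40, 1L)
      f <- features[i, ]
      if (f$strand == "+") {
        t <- f$start - utr
        s_start <- t - d - slen      # forward-strand start of the -35 box
        codes[s_start:(s_start + slen - 1L)] <- encode_dna(site$seq)
        g35 <- c(s_start, s_start + L35 - 1L)
        g10 <- c(t - d - L10, t - d - 1L)
      } else {
        t <- f$end + utr
        s_end <- t + d + slen        # forward-strand end of the -35 box
        rc <- encode_dna(as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(site$seq))))
        codes[(t + d + 1L):s_end] <- rc
        g35 <- c(s_end - L35 + 1L, s_end)
        g10 <- c(t + d + 1L, t + d + L10)
      }
      promoters[[length(promoters) + 1L]] <- data.frame(
        feature_id = f$feature_id, contig = contig, strand = f$strand,
        g35_start = g35[1L], g35_end = g35[2L],
        g10_start = g10[1L], g10_end = g10[2L],
        spacer = site$spacer, tss_dist = d, tss_pos = t,
        site = site$seq, strength = strength)
      tss[[length(tss) + 1L]] <- data.frame(
        feature_id = f$feature_id, contig = contig, strand = f$strand,
        pos = t)
    }
    genome <- Biostrings::DNAStringSet(stats::setNames(decode_dna(codes),
                                                       contig))
    truth <- structure(list(
      planted_promoters = if (length(promoters)) do.call(rbind, promoters)
                          else NULL,
      planted_tss = if (length(tss)) do.call(rbind, tss) else NULL,
      planted_regulated_units = features$feature_id[reg_idx],
      contig = contig, contig_len = contig_len, seed = seed),
      class = "synthetic_truth")
    list(genome = genome, features = features, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  np <- if (is.null(x$planted_promoters)) 0L else nrow(x$planted_promoters)
  cat(sprintf("synthetic_truth: %d planted promoter(s) on %s (%d bp)\n",
              np, x$contig, x$contig_len))
  invisible(x)
}

#' Simulate 5'-end read-start count tracks for two samples
#'
#' Emulates a Cappable-seq pair of an overexpression (treatment) and a
#' control sample. A fraction `signal_fraction` of the treatment's reads is
#' assigned multinomially to the planted TSS with +/-1 nt positional jitter
#' (80/10/10 mass). The remaining reads of both samples are background
#' noise shared by the strains: most fall on a common set of `n_background`
#' spurious start positions (e.g. RNA-processing sites) with heavy-tailed
#' weights shared between samples, and a thin uniform per-base scatter of
#' about `noise_rate` reads per base covers the rest. The control carries
#' noise only. Rt of each track is its emitted total.
#'
#' @param truth a `synthetic_truth` from [generate_genome()].
#' @param depth total reads per sample.
#' @param signal_fraction fraction of treatment reads at planted TSS.
#' @param noise_rate expected uniform-scatter reads per base.
#' @param n_background number of shared background start positions.
#' @param seed optional local RNG seed.
#' @return list with `treatment` and `control` [start_count_track()]s.
#' @export
simulate_tss_counts <- function(truth, depth = 1e6, signal_fraction = 0.1,
                                noise_rate = 0.1, n_background = 300L,
                                seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), depth >= 0)
  clen <- truth$contig_len
  grid <- 2L * clen  # strand-position grid: 1..clen = "+", rest = "-"
  to_pos <- function(idx) {
    data.frame(strand = ifelse(idx > clen, "-", "+"),
               pos = ifelse(idx > clen, idx - clen, idx))
  }
  with_rng_seed(seed, {
    empty <- data.frame(contig = character(0), strand = character(0),
                        pos = integer(0), count = integer(0))
    if (depth == 0) {
      return(list(
        treatment = start_count_track(empty, "treatment", rt = 0),
        control = start_count_track(empty, "control", rt = 0)))
    }
    pt <- truth$planted_tss
    n_tss <- if (is.null(pt)) 0L else nrow(pt)
    # background positions avoid the planted TSS neighbourhoods
    forbidden <- integer(0)
    if (n_tss) {
      off <- -10:10
      idx <- ifelse(pt$strand == "-", pt$pos + clen, pt$pos)
      forbidden <- unique(as.vector(outer(idx, off, "+")))
    }
    bg_idx <- sample(setdiff(seq_len(grid), forbidden), n_background)
    bg_w <- rexp(n_background)  # heavy-tailed weights shared by both samples
    signal <- if (n_tss) round(depth * signal_fraction) else 0L
    scatter_n <- min(round(noise_rate * grid), depth - signal)

    emit <- function(signal_reads, scatter_reads, site_reads, sample_id) {
      rows <- list()
      if (signal_reads > 0 && n_tss) {
        per_tss <- rmultinom(1L, signal_reads, rep(1, n_tss))[, 1L]
        for (i in seq_len(n_tss)) {
          jit <- rmultinom(1L, per_tss[i], c(0.1, 0.8, 0.1))[, 1L]
          rows[[length(rows) + 1L]] <- data.frame(
            strand = pt$strand[i], pos = pt$pos[i] + (-1:1), count = jit)
        }
      }
      if (site_reads > 0) {
        cnt <- rmultinom(1L, site_reads, bg_w)[, 1L]
        rows[[length(rows) + 1L]] <-
          cbind(to_pos(bg_idx), data.frame(count = cnt))
      }
      if (scatter_reads > 0) {
        hit <- tabulate(sample.int(grid, scatter_reads, replace = TRUE),
                        nbins = grid)
        nz <- which(hit > 0)
        rows[[length(rows) + 1L]] <-
          cbind(to_pos(nz), data.frame(count = hit[nz]))
      }
      d <- if (length(rows)) do.call(rbind, rows) else empty
      d$contig <- truth$contig
      start_count_track(d[c("contig", "strand", "pos", "count")],
                        sample_id = sample_id)
    }
    treatment <- emit(signal, scatter_n, depth - signal - scatter_n,
                      "treatment")
    control <- emit(0L, scatter_n, depth - scatter_n, "control")
    list(treatment = treatment, control = control)
  })
}

#' Simulate a differential-expression table matching the ground truth
#'
#' One monocistronic unit per feature. Planted regulated units get
#' `log2fc = effect_log2fc` and `padj = 1e-6`; all other units get small
#' Gaussian log2fc noise and `padj` drawn uniformly from
#' `[null_padj, 1]`. With `effect_log2fc > 2` the pipeline's DE filter
#' (`log2fc > 2`, `padj < 0.05`) recovers exactly the planted set.
#'
#' @param truth a `synthetic_truth`.
#' @param features the features data.frame from [generate_genome()].
#' @param effect_log2fc log2 fold change of planted units.
#' @param null_padj lower bound of the null adjusted p-values (> 0.05 keeps
#'   unregulated units below the filter).
#' @param seed optional local RNG seed.
#' @return DE data.frame (`unit_id`, `members` list-column, `log2fc`,
#'   `padj`).
#' @export
simulate_de_table <- function(truth, features, effect_log2fc = 4,
                              null_padj = 0.2, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_rng_seed(seed, {
    n <- nrow(features)
    planted <- features$feature_id %in% truth$planted_regulated_units
    de <- data.frame(
      unit_id = paste0("unit_", features$feature_id),
      log2fc = ifelse(planted, effect_log2fc, rnorm(n, 0, 0.3)),
      padj = ifelse(planted, 1e-6, runif(n, null_padj, 1)))
    de$members <- as.list(features$feature_id)
    de[c("unit_id", "members", "log2fc", "padj")]
  })
}

#' Write a full synthetic dataset to a directory
#'
#' Emits `genome.fa`, `features.gff3`, bedGraph pairs
#' `<sample>_{fwd,rev}.bedgraph` for both samples, `de_table.tsv` and
#' `truth.json`.
#'
#' @param sim result of [generate_genome()].
#' @param tracks result of [simulate_tss_counts()].
#' @param de result of [simulate_de_table()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, tracks, de, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  f <- sim$features
  gr <- GenomicRanges::GRanges(f$contig,
                               IRanges::IRanges(f$start, f$end),
                               strand = f$strand)
  gr$type <- f$feature_type
  gr$ID <- f$feature_id
  rtracklayer::export(gr, p("features.gff3"), format = "gff3")
  for (s in names(tracks))
    write_start_counts(tracks[[s]], p(paste0(s, "_fwd.bedgraph")),
                       p(paste0(s, "_rev.bedgraph")))
  de_out <- de
  de_out$members <- vapply(de$members, paste, character(1L), collapse = ",")
  write.table(de_out[c("unit_id", "members", "log2fc", "padj")],
              p("de_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(planted_promoters = sim$truth$planted_promoters,
         planted_tss = sim$truth$planted_tss,
         planted_regulated_units = sim$truth$planted_regulated_units,
         contig = sim$truth$contig, contig_len = sim$truth$contig_len,
         seed = sim$truth$seed),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
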