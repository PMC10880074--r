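#' A DNA window in transcription orientation
#'
#' Windows are the unit every scan operates on. `seq` is always given in
#' transcription orientation: for a minus-strand window it is the reverse
#' complement of the forward-strand genomic slice, so the box order within
#' `seq` is always -35, spacer, -10, (TSS). `genomic_start`/`genomic_end` are
#' 1-based inclusive forward-strand coordinates. Offsets within `seq`
#' (including `anchor_tss_offset`) are 1-based.
#'
#' @param seq DNA string (transcription orientation).
#' @param window_id identifier.
#' @param source one of `"tss_upstream"`, `"feature_window"`,
#'   `"genome_tile"`, `"synthetic"`.
#' @param contig,strand,genomic_start,genomic_end genomic placement
#'   (optional for purely synthetic windows).
#' @param anchor_tss_offset 1-based index of the TSS base within `seq`, or
#'   `NA` for an unanchored window. For `tss_upstream` windows this is the
#'   last base of the window.
#' @param clipped whether the window was truncated at a contig edge.
#' @return an object of class `sequence_window`.
#' @export
sequence_window <- function(seq, window_id = "window",
                            source = c("synthetic", "tss_upstream",
                                       "feature_window", "genome_tile"),
                            contig = NA_character_, strand = "+",
                            genomic_start = NA_integer_,
                            genomic_end = NA_integer_,
                            anchor_tss_offset = NA_integer_,
                            clipped = FALSE) {
  source <- match.arg(source)
  stopifnot(is.character(seq), length(seq) == 1L, strand %in% c("+", "-"))
  n <- nchar(seq)
  if (!is.na(genomic_start) && !is.na(genomic_end) &&
      genomic_end - genomic_start + 1L != n)
    stop("window '", window_id, "': sequence length ", n,
         " does not match genomic span")
  if (!is.na(anchor_tss_offset) &&
      (anchor_tss_offset < 1L || anchor_tss_offset > n))
    stop("window '", window_id, "': anchor TSS offset outside the sequence")
  structure(
    list(window_id = window_id, source = source, contig = contig,
         strand = strand, genomic_start = genomic_start,
         genomic_end = genomic_end, seq = toupper(seq),
         anchor_tss_offset = as.integer(anchor_tss_offset),
         clipped = clipped),
    class = "sequence_window")
}

#' @export
print.sequence_window <- function(x, ...) {
  cat(sprintf("sequence_window '%s' (%s): %d nt, %s%s%s\n",
              x$window_id, x$source, nchar(x$seq),
              if (is.na(x$contig)) "unplaced"
              else sprintf("%s:%d-%d(%s)", x$contig, x$genomic_start,
                           x$genomic_end, x$strand),
              if (is.na(x$anchor_tss_offset)) ""
              else sprintf(", TSS at offset %d", x$anchor_tss_offset),
              if (isTRUE(x$clipped)) ", clipped" else ""))
  invisible(x)
}

# map a 1-based offset within window$seq to a forward-strand genomic position
window_offset_to_genomic <- function(window, offset) {
  if (is.na(window$genomic_start)) return(rep(NA_integer_, length(offset)))
  if (window$strand == "+") window$genomic_start + offset - 1L
  else window$genomic_end - offset + 1L
}

empty_hits <- function() {
  data.frame(window_id = character(0), contig = character(0),
             strand = character(0), pos35 = integer(0), pos10 = integer(0),
             spacer = integer(0), s35 = numeric(0), s10 = numeric(0),
             total = numeric(0), tss_distance = integer(0),
             g35_start = integer(0), g35_end = integer(0),
             g10_start = integer(0), g10_end = integer(0),
             evalue = numeric(0))
}

#' All bipartite promoter placements in a window
#'
#' Enumerates every -35/-10 placement whose spacer lies within the pair's
#' range and, when the window carries a TSS anchor, whose number of bases
#' strictly between the end of the -10 box and the TSS base lies within the
#' pair's TSS-distance range. Each placement is scored: `s35` and `s10` are
#' the box log-probability scores and `total = s35 + s10`. A window too short
#' for any placement yields an empty frame (not an error). Offsets `pos35`
#' and `pos10` are 1-based box starts within `window$seq`; `g35_*`/`g10_*`
#' are the corresponding forward-strand genomic ranges when the window is
#' placed.
#'
#' @param window a [sequence_window()].
#' @param pair a [pssm_pair()].
#' @return data.frame of hits ordered by `pos35`, then spacer; `evalue` is
#'   `NA` until attached by [empirical_evalue()] or a scan driver.
#' @export
all_hits <- function(window, pair) {
  stopifnot(inherits(window, "sequence_window"), inherits(pair, "pssm_pair"))
  codes <- encode_dna(window$seq)
  n <- length(codes)
  L35 <- pair$pssm35$length
  L10 <- pair$pssm10$length
  if (n < min_placement_len(pair)) return(empty_hits())
  sc35 <- box_scores_cpp(pair$pssm35$logprob, codes)
  sc10 <- box_scores_cpp(pair$pssm10$logprob, codes)
  anchored <- !is.na(window$anchor_tss_offset)
  rows <- list()
  for (sp in pair$spacer_min:pair$spacer_max) {
    nmax <- n - L35 - sp - L10 + 1L
    if (nmax < 1L) next
    pos35 <- seq_len(nmax)
    pos10 <- pos35 + L35 + sp
    tssd <- rep(NA_integer_, nmax)
    if (anchored) {
      tssd <- window$anchor_tss_offset - (pos10 + L10 - 1L) - 1L
      ok <- tssd >= pair$tss_dist_min & tssd <= pair$tss_dist_max
      if (!any(ok)) next
      pos35 <- pos35[ok]; pos10 <- pos10[ok]; tssd <- tssd[ok]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pos35 = pos35, pos10 = pos10, spacer = sp,
      s35 = sc35[pos35], s10 = sc10[pos10], tss_distance = tssd)
  }
  if (!length(rows)) return(empty_hits())
  h <- do.call(rbind, rows)
  h <- h[order(h$pos35, h$spacer), , drop = FALSE]
  fwd <- window$strand == "+"
  g35 <- window_offset_to_genomic(window, h$pos35)
  g35e <- window_offset_to_genomic(window, h$pos35 + L35 - 1L)
  g10 <- window_offset_to_genomic(window, h$pos10)
  g10e <- window_offset_to_genomic(window, h$pos10 + L10 - 1L)
  out <- data.frame(
    window_id = window$window_id, contig = window$contig,
    strand = window$strand, pos35 = h$pos35, pos10 = h$pos10,
    spacer = h$spacer, s35 = h$s35, s10 = h$s10, total = h$s35 + h$s10,
    tss_distance = h$tss_distance,
    g35_start = if (fwd) g35 else g35e, g35_end = if (fwd) g35e else g35,
    g10_start = if (fwd) g10 else g10e, g10_end = if (fwd) g10e else g10,
    evalue = NA_real_)
  rownames(out) <- NULL
  out
}

#' Best bipartite promoter placement in a window
#'
#' The placement maximizing the total score. Ties are broken by smaller
#' spacer, then by the placement closest to the anchor/3' end of the window.
#'
#' @inheritParams all_hits
#' @return a one-row hit data.frame, or `NULL` when no placement fits.
#' @export
best_hit <- function(window, pair) {
  h <- all_hits(window, pair)
  if (!nrow(h)) return(NULL)
  ord <- order(-h$total, h$spacer, -h$pos35)
  h[ord[1L], , drop = FALSE]
}

#' Null distribution of the best promoter score under base shuffling
#'
#' Generates `n` exact shuffles of the window's bases (uniform random
#' permutations, so the mononucleotide counts are preserved exactly) and
#' records the best bipartite total of each under the same scan mode
#' (anchored or free) as the window itself. A shuffle admitting no valid
#' placement contributes `-Inf`.
#'
#' @inheritParams all_hits
#' @param n number of shuffles.
#' @param seed optional seed applied locally (the caller's RNG state is
#'   restored); with `seed = NULL` the global RNG stream is used.
#' @return numeric vector of length `n`.
#' @export
null_best_scores <- function(window, pair, n = 1000L, seed = NULL) {
  stopifnot(inherits(window, "sequence_window"), inherits(pair, "pssm_pair"),
            n >= 1L)
  codes <- encode_dna(window$seq)
  anchored <- !is.na(window$anchor_tss_offset)
  with_rng_seed(seed, null_best_totals_cpp(
    codes, pair$pssm35$logprob, pair$pssm10$logprob,
    pair$spacer_min, pair$spacer_max,
    anchored, if (anchored) window$anchor_tss_offset - 1L else -1L,
    pair$tss_dist_min, pair$tss_dist_max, as.integer(n)))
}

#' Empirical E-value of an observed promoter score
#'
#' The fraction `k/n` of composition-matched random sequences (exact shuffles
#' of the window) whose best promoter total is at least as extreme (>=) as
#' the observed total: the probability of observing a score at least as good
#' by chance in a sequence of the same mononucleotide composition. The plain
#' `k/n` estimator can reach 0; set `laplace = TRUE` for the `(k+1)/(n+1)`
#' variant.
#'
#' @inheritParams null_best_scores
#' @param observed an observed hit row (from [all_hits()]/[best_hit()]) or a
#'   bare numeric total score.
#' @param laplace use the `(k+1)/(n+1)` estimator.
#' @return E-value in `[0, 1]`.
#' @export
empirical_evalue <- function(window, pair, observed, n = 1000L, seed = NULL,
                             laplace = FALSE) {
  total <- if (is.data.frame(observed)) observed$total[1L]
           else as.numeric(observed)
  nulls <- null_best_scores(window, pair, n = n, seed = seed)
  k <- sum(nulls >= total)
  if (laplace) (k + 1) / (n + 1) else k / n
}

# extract a window sequence in transcription orientation from a genome
# (DNAStringSet); forward-strand coordinates, 1-based inclusive
extract_window_seq <- function(genome, contig, strand, gstart, gend) {
  if (!contig %in% names(genome)) stop("unknown contig '", contig, "'")
  s <- Biostrings::subseq(genome[[contig]], start = gstart, end = gend)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Build the TSS-anchored upstream window of one TSS
#'
#' The window is `window_len` nt ending at (and including) the TSS base, in
#' transcription orientation. Windows running off the contig 5' edge are
#' clipped and flagged.
#'
#' @param genome a `DNAStringSet` (or FASTA path, see [read_genome()]).
#' @param contig,strand,pos TSS location (1-based).
#' @param window_len window length in nt including the TSS.
#' @param window_id identifier.
#' @return a [sequence_window()] with the anchor on its last base.
#' @export
tss_upstream_window <- function(genome, contig, strand, pos,
                                window_len = 40L, window_id = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (!contig %in% names(genome)) stop("unknown contig '", contig, "'")
  clen <- Biostrings::width(genome[names(genome) == contig])[1L]
  if (pos < 1L || pos > clen)
    stop("TSS at ", contig, ":", pos, " is outside the contig (length ",
         clen, ")")
  if (strand == "+") {
    gstart <- max(1L, pos - window_len + 1L); gend <- pos
  } else {
    gstart <- pos; gend <- min(clen, pos + window_len - 1L)
  }
  clipped <- (gend - gstart + 1L) < window_len
  if (is.null(window_id))
    window_id <- sprintf("tss_%s_%s_%d", contig, strand, pos)
  sequence_window(extract_window_seq(genome, contig, strand, gstart, gend),
                  window_id = window_id, source = "tss_upstream",
                  contig = contig, strand = strand,
                  genomic_start = gstart, genomic_end = gend,
                  anchor_tss_offset = gend - gstart + 1L, clipped = clipped)
}

#' Scan TSS-anchored upstream windows for promoter motifs
#'
#' For each TSS, extracts the upstream window (default 40 nt including the
#' TSS), finds the best anchored bipartite placement, attaches its empirical
#' E-value, and retains hits with E-value <= `max_evalue` (default 0.05).
#' Windows clipped too short for the placement geometry yield no hit.
#'
#' @param tss data.frame of TSS records (`contig`, `strand`, `pos`).
#' @param genome `DNAStringSet` or FASTA path.
#' @param pair a [pssm_pair()].
#' @param window_len upstream window length including the TSS.
#' @param n_null shuffles per E-value.
#' @param max_evalue retention threshold (inclusive).
#' @param keep_all return all scored hits with a `retained` column instead of
#'   dropping the failures.
#' @param seed optional local RNG seed.
#' @return data.frame of hits with columns of [all_hits()] plus `tss_pos`,
#'   `clipped` and `evalue` (and `retained` if `keep_all`).
#' @export
tss_anchored_scan <- function(tss, genome, pair, window_len = 40L,
                              n_null = 1000L, max_evalue = 0.05,
                              keep_all = FALSE, seed = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  with_rng_seed(seed, {
    rows <- vector("list", nrow(tss))
    for (i in seq_len(nrow(tss))) {
      w <- tss_upstream_window(genome, tss$contig[i], tss$strand[i],
                               tss$pos[i], window_len = window_len)
      h <- best_hit(w, pair)
      if (is.null(h)) next
      h$evalue <- empirical_evalue(w, pair, h, n = n_null)
      h$tss_pos <- tss$pos[i]
      h$clipped <- w$clipped
      rows[[i]] <- h
    }
    hits <- do.call(rbind, rows)
    if (is.null(hits)) {
      hits <- empty_hits()
      hits$tss_pos <- integer(0); hits$clipped <- logical(0)
    }
    if (keep_all) hits$retained <- hits$evalue <= max_evalue
    else hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
    rownames(hits) <- NULL
    hits
  })
}

#' Write promoter hits as TSV and optionally GFF3
#'
#' @param hits a hits data.frame.
#' @param tsv output TSV path.
#' @param gff optional GFF3 path; each hit becomes a `promoter` feature
#'   spanning the -35 box through the -10 box on the forward strand.
#' @export
write_hits <- function(hits, tsv, gff = NULL) {
  write.table(hits, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gff) && nrow(hits)) {
    gr <- GenomicRanges::GRanges(
      hits$contig,
      IRanges::IRanges(start = pmin(hits$g35_start, hits$g10_start),
                       end = pmax(hits$g35_end, hits$g10_end)),
      strand = hits$strand)
    gr$type <- "promoter"
    gr$ID <- paste0("promoter_", seq_along(gr))
    gr$score <- hits$total
    gr$Note <- sprintf("s35=%.3f;s10=%.3f;evalue=%s", hits$s35, hits$s10,
                       format(hits$evalue))
    rtracklayer::export(gr, gff, format = "gff3")
  }
  invisible(tsv)
}
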