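#' Position-specific scoring matrices for ECF promoter boxes
#'
#' A `pssm` stores per-column base log-probabilities (base 2) for one promoter
#' box (-35 or -10) of an ECF sigma factor group. Scores produced from it are
#' sums of log-probabilities and therefore always <= 0; scores closer to 0
#' indicate greater similarity to the motif. Rows are in the fixed alphabet
#' order A, C, G, T.
#'
#' @param logprob 4 x L numeric matrix of base-2 log-probabilities; each
#'   column must satisfy `sum(2^column) == 1` (within 1e-9) and every entry
#'   must be <= 0.
#' @param motif_id identifier for the motif.
#' @param box which promoter box the matrix describes, `"minus35"` or
#'   `"minus10"`.
#' @param pseudocount the pseudocount fraction used when the matrix was
#'   derived from counts or frequencies (`NA` if constructed directly).
#' @return an object of class `pssm`.
#' @seealso [pssm_from_probs()], [load_pssm()], [score_subsequence()],
#'   [consensus()]
#' @export
pssm <- function(logprob, motif_id = "pssm", box = c("minus35", "minus10"),
                 pseudocount = NA_real_) {
  box <- match.arg(box)
  logprob <- as.matrix(logprob)
  mode(logprob) <- "double"
  if (nrow(logprob) != 4L)
    stop("a PSSM must have exactly 4 rows (A, C, G, T); got ", nrow(logprob))
  if (ncol(logprob) < 1L) stop("a PSSM must have at least one column")
  if (any(!is.finite(logprob)))
    stop("non-finite log-probability; use a pseudocount > 0 for sparse columns")
  if (any(logprob > 1e-12))
    stop("log-probabilities must be <= 0")
  colsum <- colSums(2^logprob)
  off <- which(abs(colsum - 1) > 1e-9)
  if (length(off))
    stop("column(s) ", paste(off, collapse = ", "),
         " do not renormalize: sum(2^logprob) != 1")
  dimnames(logprob) <- list(DNA_ALPHABET, NULL)
  structure(
    list(motif_id = motif_id, box = box, length = ncol(logprob),
         logprob = logprob, pseudocount = pseudocount),
    class = "pssm")
}

#' Build a PSSM from base probabilities or counts
#'
#' Columns are normalized to frequencies `f` and converted to base-2
#' log-probabilities as `log2((f + eps) / (1 + 4 * eps))` with
#' `eps = pseudocount`, which renormalizes each column exactly. With
#' `pseudocount = 0` a zero frequency is a hard error (its log-probability
#' would be -Inf), so sparse matrices require a positive pseudocount.
#'
#' @param x 4 x L non-negative matrix of per-column base counts or
#'   frequencies, rows in A, C, G, T order.
#' @param pseudocount per-column pseudocount fraction `eps` (default 0.01).
#' @inheritParams pssm
#' @return a [pssm()].
#' @examples
#' m <- matrix(c(8, 0, 0, 0), nrow = 4)
#' p <- pssm_from_probs(m, pseudocount = 0.01)
#' p$logprob[, 1]  # ~ -0.042 for A, ~ -6.70 for the rest
#' @export
pssm_from_probs <- function(x, motif_id = "pssm",
                            box = c("minus35", "minus10"),
                            pseudocount = 0.01) {
  box <- match.arg(box)
  x <- as.matrix(x)
  mode(x) <- "double"
  if (nrow(x) != 4L)
    stop("a PSSM must have exactly 4 rows (A, C, G, T); got ", nrow(x))
  if (any(x < 0)) {
    bad <- which(apply(x < 0, 2L, any))
    stop("negative value(s) in column(s) ", paste(bad, collapse = ", "))
  }
  cs <- colSums(x)
  if (any(cs == 0)) {
    bad <- which(cs == 0)
    stop("column(s) ", paste(bad, collapse = ", "), " sum to zero")
  }
  f <- sweep(x, 2L, cs, "/")
  eps <- pseudocount
  if (eps < 0) stop("pseudocount must be >= 0")
  if (eps == 0 && any(f == 0)) {
    bad <- which(apply(f == 0, 2L, any))
    stop("zero frequency in column(s) ", paste(bad, collapse = ", "),
         " with pseudocount 0: log-probability undefined")
  }
  lp <- log2((f + eps) / (1 + 4 * eps))
  pssm(lp, motif_id = motif_id, box = box, pseudocount = eps)
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM '%s' (%s box), %d columns, consensus %s\n",
              x$motif_id, sub("minus", "-", x$box), x$length, consensus(x)))
  invisible(x)
}

#' A -35/-10 PSSM pair with placement geometry
#'
#' Bundles the two box matrices of one ECF group together with the bipartite
#' placement geometry: the spacer between the boxes (15-17 nt by default) and
#' the number of bases strictly between the end of the -10 box and the
#' transcription start site (3-6 by default).
#'
#' @param ecf_group group label, e.g. `"ECF02"` or `"ECF11"`.
#' @param pssm35,pssm10 the [pssm()] objects for the -35 and -10 boxes.
#' @param spacer_min,spacer_max allowed spacer length range in nt.
#' @param tss_dist_min,tss_dist_max allowed number of bases strictly between
#'   the last base of the -10 box and the TSS base.
#' @return an object of class `pssm_pair`.
#' @export
pssm_pair <- function(ecf_group, pssm35, pssm10,
                      spacer_min = 15L, spacer_max = 17L,
                      tss_dist_min = 3L, tss_dist_max = 6L) {
  stopifnot(inherits(pssm35, "pssm"), inherits(pssm10, "pssm"))
  if (pssm35$box != "minus35" || pssm10$box != "minus10")
    stop("pssm35 must be a minus35 box and pssm10 a minus10 box")
  geom <- c(spacer_min, spacer_max, tss_dist_min, tss_dist_max)
  if (any(geom < 0) || spacer_min > spacer_max || tss_dist_min > tss_dist_max)
    stop("invalid placement geometry")
  structure(
    list(ecf_group = ecf_group, pssm35 = pssm35, pssm10 = pssm10,
         spacer_min = as.integer(spacer_min),
         spacer_max = as.integer(spacer_max),
         tss_dist_min = as.integer(tss_dist_min),
         tss_dist_max = as.integer(tss_dist_max)),
    class = "pssm_pair")
}

#' @export
print.pssm_pair <- function(x, ...) {
  cat(sprintf(
    "PSSM pair %s: -35 %s [%d nt], spacer %d-%d, -10 %s [%d nt], TSS %d-%d nt downstream\n",
    x$ecf_group, consensus(x$pssm35), x$pssm35$length,
    x$spacer_min, x$spacer_max,
    consensus(x$pssm10), x$pssm10$length,
    x$tss_dist_min, x$tss_dist_max))
  invisible(x)
}

# minimal bipartite placement length within a window (no TSS distance)
min_placement_len <- function(pair) {
  pair$pssm35$length + pair$spacer_min + pair$pssm10$length
}

#' Load a PSSM from a tab-delimited matrix file
#'
#' The native dialect is 4 rows (A, C, G, T) of L tab-separated columns, with
#' an optional header line `#type=counts|freqs|logprobs` (and optionally
#' `#motif_id=...`). Without a header the value type is auto-detected:
#' any negative entry means log-probabilities, columns of non-negative values
#' summing to ~1 mean frequencies, anything else counts. Counts and
#' frequencies go through the pseudocount conversion of [pssm_from_probs()];
#' log-probabilities are exponentiated first so the same conversion (and the
#' same pseudocount) applies.
#'
#' @param path file path.
#' @inheritParams pssm_from_probs
#' @return a [pssm()].
#' @export
load_pssm <- function(path, box = c("minus35", "minus10"),
                      pseudocount = 0.01) {
  box <- match.arg(box)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  type <- NA_character_
  motif_id <- sub("\\.[^.]*$", "", basename(path))
  for (m in meta) {
    kv <- strsplit(sub("^#\\s*", "", m), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) {
      if (trimws(kv[1L]) == "type") type <- trimws(kv[2L])
      if (trimws(kv[1L]) == "motif_id") motif_id <- trimws(kv[2L])
    }
  }
  if (length(body) != 4L)
    stop("expected 4 matrix rows (A, C, G, T) in ", path,
         "; found ", length(body))
  rows <- lapply(strsplit(body, "\t", fixed = TRUE),
                 function(r) suppressWarnings(as.numeric(r)))
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) stop("ragged matrix rows in ", path)
  x <- do.call(rbind, rows)
  if (anyNA(x)) stop("non-numeric matrix entry in ", path)
  if (is.na(type)) {
    type <- if (any(x < 0)) "logprobs"
            else if (all(x <= 1) && all(abs(colSums(x) - 1) < 1e-6)) "freqs"
            else "counts"
  }
  if (!type %in% c("counts", "freqs", "logprobs"))
    stop("unknown matrix type '", type, "' in ", path)
  probs <- if (type == "logprobs") 2^x else x
  pssm_from_probs(probs, motif_id = motif_id, box = box,
                  pseudocount = pseudocount)
}

#' Write a PSSM in the native tab-delimited dialect
#'
#' @param x a [pssm()].
#' @param path output file path.
#' @param type value type to write, `"logprobs"` (exact) or `"freqs"`.
#' @export
write_pssm <- function(x, path, type = c("logprobs", "freqs")) {
  type <- match.arg(type)
  stopifnot(inherits(x, "pssm"))
  m <- if (type == "logprobs") x$logprob else 2^x$logprob
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#type=", type), paste0("#motif_id=", x$motif_id)), con)
  writeLines(apply(m, 1L, function(r) paste(format(r, digits = 15),
                                            collapse = "\t")), con)
  invisible(path)
}

#' Load a -35/-10 pair from two matrix files
#'
#' @param path35,path10 matrix files for the -35 and -10 boxes.
#' @param ecf_group group label.
#' @inheritParams pssm_pair
#' @inheritParams pssm_from_probs
#' @return a [pssm_pair()].
#' @export
load_pssm_pair <- function(path35, path10, ecf_group = "ECF",
                           pseudocount = 0.01,
                           spacer_min = 15L, spacer_max = 17L,
                           tss_dist_min = 3L, tss_dist_max = 6L) {
  pssm_pair(ecf_group,
            load_pssm(path35, box = "minus35", pseudocount = pseudocount),
            load_pssm(path10, box = "minus10", pseudocount = pseudocount),
            spacer_min = spacer_min, spacer_max = spacer_max,
            tss_dist_min = tss_dist_min, tss_dist_max = tss_dist_max)
}

#' Read PSSMs from a MEME minimal motif file
#'
#' Accepts the MEME minimal text format (`MEME version`, `ALPHABET= ACGT`,
#' `MOTIF`, `letter-probability matrix`). Each motif's probability matrix is
#' transposed into the native 4 x L layout and converted with the usual
#' pseudocount rule.
#'
#' @param path MEME minimal file.
#' @inheritParams pssm_from_probs
#' @return named list of [pssm()] objects (box set to `"minus35"`; reassign
#'   via [pssm()] fields as needed).
#' @export
read_meme_pssms <- function(path, box = c("minus35", "minus10"),
                            pseudocount = 0.01) {
  box <- match.arg(box)
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF entries in ", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    h <- s + grep("^letter-probability matrix", lines[(s + 1):length(lines)])[1L]
    if (is.na(h)) stop("motif ", name, " has no letter-probability matrix")
    rows <- list()
    i <- h + 1L
    while (i <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines[i])) {
      rows[[length(rows) + 1L]] <-
        as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]])
      i <- i + 1L
    }
    probs <- t(do.call(rbind, rows))  # MEME rows are positions; ours columns
    out[[name]] <- pssm_from_probs(probs, motif_id = name, box = box,
                                   pseudocount = pseudocount)
  }
  out
}

#' Score a sequence of exactly the motif length
#'
#' The score is the sum over columns of the log-probability of the observed
#' base: a base-2 log-probability of the sequence under the motif model.
#' It is always <= 0, and 0 only when every observed base has probability 1.
#'
#' @param pssm a [pssm()].
#' @param seq DNA string of length `pssm$length`.
#' @return score in bits (<= 0).
#' @export
score_subsequence <- function(pssm, seq) {
  stopifnot(inherits(pssm, "pssm"))
  codes <- encode_dna(seq)
  if (length(codes) != pssm$length)
    stop("sequence length ", length(codes),
         " does not match motif length ", pssm$length)
  sum(pssm$logprob[cbind(codes, seq_len(pssm$length))])
}

#' Consensus sequence of a PSSM
#'
#' Per column the maximal-probability base; ties are broken by alphabet order
#' A < C < G < T. The consensus maximizes [score_subsequence()] over all
#' sequences of the motif length.
#'
#' @param pssm a [pssm()].
#' @return DNA string.
#' @export
consensus <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  decode_dna(apply(pssm$logprob, 2L, which.max))
}
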