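#' Per-base 5'-end read-start counts for one sample
#'
#' Holds the sparse per-base tallies of read 5' ends (Rns) for one sequencing
#' sample across all contigs and both strands, together with the sample total
#' Rt (total mapped TSS reads). Rt defaults to the sum of the stored counts
#' but may be larger, e.g. when positions were dropped upstream.
#'
#' @param counts data.frame with columns `contig`, `strand` (`"+"`/`"-"`),
#'   `pos` (1-based), `count` (non-negative integer Rns).
#' @param sample_id sample label.
#' @param rt total mapped TSS reads of the sample; default `sum(counts$count)`.
#' @return an object of class `start_count_track`.
#' @export
start_count_track <- function(counts, sample_id = "sample",
                              rt = sum(counts$count)) {
  stopifnot(is.data.frame(counts),
            all(c("contig", "strand", "pos", "count") %in% names(counts)))
  counts <- counts[counts$count > 0, , drop = FALSE]
  if (nrow(counts)) {
    stopifnot(all(counts$strand %in% c("+", "-")), all(counts$pos >= 1))
    dup <- duplicated(counts[c("contig", "strand", "pos")])
    if (any(dup)) {  # merge duplicate positions
      key <- paste(counts$contig, counts$strand, counts$pos)
      agg <- rowsum(counts$count, key)
      parts <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
      counts <- data.frame(contig = parts[, 1L], strand = parts[, 2L],
                           pos = as.integer(parts[, 3L]), count = agg[, 1L])
    }
    counts <- counts[order(counts$contig, counts$strand, counts$pos), ,
                     drop = FALSE]
    rownames(counts) <- NULL
  }
  if (rt < sum(counts$count))
    stop("rt (", rt, ") is smaller than the stored count total (",
         sum(counts$count), ")")
  structure(list(sample_id = sample_id, counts = counts, rt = rt),
            class = "start_count_track")
}

#' @export
print.start_count_track <- function(x, ...) {
  cat(sprintf("start_count_track '%s': %d nonzero positions, Rt = %s\n",
              x$sample_id, nrow(x$counts), format(x$rt, big.mark = ",")))
  invisible(x)
}

#' Read 5'-end counts from bedGraph files or a 4-column TSV
#'
#' bedGraph input is one file per strand (value = 5'-end count at each base;
#' 0-based half-open intervals per the bedGraph standard, expanded to per-base
#' 1-based positions internally). TSV input is a single headerless file with
#' columns contig, strand, 1-based position, count.
#'
#' @param fwd,rev bedGraph paths for the + and - strand (bedGraph mode).
#' @param tsv path of a 4-column TSV (TSV mode; overrides `fwd`/`rev`).
#' @inheritParams start_count_track
#' @param rt sample total Rt; default is the sum of all read counts.
#' @return a [start_count_track()].
#' @export
read_start_counts <- function(fwd = NULL, rev = NULL, tsv = NULL,
                              sample_id = "sample", rt = NULL) {
  if (!is.null(tsv)) {
    df <- read.delim(tsv, header = FALSE,
                     col.names = c("contig", "strand", "pos", "count"),
                     colClasses = c("character", "character", "integer",
                                    "integer"))
  } else {
    if (is.null(fwd) && is.null(rev))
      stop("provide either tsv= or bedGraph fwd=/rev= paths")
    read_bg <- function(path, strand) {
      if (is.null(path)) return(NULL)
      gr <- rtracklayer::import(path, format = "bedGraph")
      st <- GenomicRanges::start(gr)
      w <- GenomicRanges::width(gr)
      pos <- unlist(lapply(seq_along(gr),
                           function(i) st[i]:(st[i] + w[i] - 1L)),
                    use.names = FALSE)
      data.frame(
        contig = rep(as.character(GenomicRanges::seqnames(gr)), w),
        strand = strand, pos = as.integer(pos),
        count = rep(as.integer(round(gr$score)), w))
    }
    df <- rbind(read_bg(fwd, "+"), read_bg(rev, "-"))
  }
  if (is.null(rt)) rt <- sum(df$count)
  start_count_track(df, sample_id = sample_id, rt = rt)
}

#' Write a track as a pair of bedGraph files
#'
#' @param track a [start_count_track()].
#' @param fwd,rev output paths for the + and - strand.
#' @export
write_start_counts <- function(track, fwd, rev) {
  stopifnot(inherits(track, "start_count_track"))
  for (s in c("+", "-")) {
    d <- track$counts[track$counts$strand == s, , drop = FALSE]
    path <- if (s == "+") fwd else rev
    gr <- GenomicRanges::GRanges(
      d$contig, IRanges::IRanges(start = d$pos, width = 1L), score = d$count)
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  invisible(c(fwd, rev))
}

#' Relative read scores (RRS) for every nonzero position
#'
#' For each position with a nonzero 5'-end count Rns the relative read score
#' is `RRS = (Rns / Rt) * 1e6`, Rt being the sample's total mapped TSS reads.
#' The sum of RRS over all emitted records is 1e6 exactly when Rt equals the
#' stored count total.
#'
#' @param track a [start_count_track()].
#' @return data.frame of TSS records: `contig`, `strand`, `pos`, `rns`, `rrs`.
#' @export
compute_rrs <- function(track) {
  stopifnot(inherits(track, "start_count_track"))
  if (track$rt <= 0) stop("empty sample: Rt is 0 for '", track$sample_id, "'")
  d <- track$counts
  data.frame(contig = d$contig, strand = d$strand, pos = d$pos,
             rns = d$count, rrs = d$count / track$rt * 1e6)
}

# split key used for per-contig/strand processing
.cs_key <- function(df) paste(df$contig, df$strand, sep = "\r")

#' Cluster neighbouring TSS positions
#'
#' A local accumulation of TSS forms one cluster when the gap between two
#' neighbouring TSS (the positional difference) does not exceed `max_gap` nt:
#' a difference of 3 joins, 4 splits, at the default. Within each cluster the
#' member with the maximal Rns is the dominant TSS (ties go to the most
#' upstream member, i.e. 5'-most on the strand). Records must come from a
#' single contig and strand; use [cluster_tss_all()] for a full record set.
#'
#' @param records TSS records as from [compute_rrs()], one contig/strand.
#' @param max_gap maximal positional difference joining neighbours (nt).
#' @return the records, sorted by position, with `cluster_id` (integer) and
#'   `dominant` (logical) columns added.
#' @export
cluster_tss <- function(records, max_gap = 3L) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) {
    records$cluster_id <- integer(0)
    records$dominant <- logical(0)
    return(records)
  }
  if (length(unique(.cs_key(records))) > 1L)
    stop("records span multiple contigs/strands; cluster per contig/strand ",
         "or use cluster_tss_all()")
  records <- records[order(records$pos), , drop = FALSE]
  rownames(records) <- NULL
  gaps <- diff(records$pos)
  records$cluster_id <- cumsum(c(1L, as.integer(gaps > max_gap)))
  # dominant = max Rns; ties go to the 5'-most member on the strand
  upstream <- if (records$strand[1L] == "-") -records$pos else records$pos
  ord <- order(records$cluster_id, -records$rns, upstream)
  records$dominant <- FALSE
  records$dominant[ord[!duplicated(records$cluster_id[ord])]] <- TRUE
  records
}

#' Cluster TSS records across all contigs and strands
#'
#' Applies [cluster_tss()] independently per contig/strand (strands never
#' cluster together) and renumbers cluster ids globally.
#'
#' @inheritParams cluster_tss
#' @return clustered records with globally unique `cluster_id`.
#' @export
cluster_tss_all <- function(records, max_gap = 3L) {
  parts <- split(records, .cs_key(records))
  offset <- 0L
  out <- lapply(parts, function(p) {
    cl <- cluster_tss(p, max_gap = max_gap)
    cl$cluster_id <- cl$cluster_id + offset
    offset <<- max(cl$cluster_id)
    cl
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select dominant TSS passing a minimal RRS
#'
#' Keeps the dominant member of each cluster whose RRS is at least `min_rrs`
#' ("minimal RRS" is inclusive). The study's extraction thresholds were 1.5,
#' 3.0 and 7.5, with 3.0 used downstream; any positive value is accepted.
#'
#' @param clustered clustered records from [cluster_tss()]/[cluster_tss_all()].
#' @param min_rrs minimal relative read score (default 3.0).
#' @return data.frame of selected dominant TSS records.
#' @export
select_tss <- function(clustered, min_rrs = 3.0) {
  stopifnot(is.data.frame(clustered))
  if (!nrow(clustered)) return(clustered)
  if (is.null(clustered$dominant)) stop("records are not clustered")
  out <- clustered[clustered$dominant & clustered$rrs >= min_rrs, ,
                   drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TSS specific to one sample relative to another
#'
#' Returns the members of `a` for which `b` has no TSS on the same contig and
#' strand within `tolerance` nt. Both inputs should be threshold-passing
#' dominant TSS from the same reference; the +/-3 nt default mirrors the
#' cluster gap rule.
#'
#' @param a,b data.frames of TSS records (`contig`, `strand`, `pos`, ...).
#' @param tolerance positional tolerance in nt.
#' @return subset of `a`.
#' @export
strain_specific_tss <- function(a, b, tolerance = 3L) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  if (!nrow(a) || !nrow(b)) return(a)
  bk <- split(b$pos, .cs_key(b))
  keep <- vapply(seq_len(nrow(a)), function(i) {
    near <- bk[[.cs_key(a[i, , drop = FALSE])]]
    is.null(near) || !any(abs(near - a$pos[i]) <= tolerance)
  }, logical(1L))
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write TSS records as TSV and the dominant TSS as BED6
#'
#' @param records clustered TSS records.
#' @param tsv output TSV path (all records).
#' @param bed optional BED6 path (dominant records only; scores are RRS).
#' @export
write_tss <- function(records, tsv, bed = NULL) {
  write.table(records, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed)) {
    dom <- if (is.null(records$dominant)) records
           else records[records$dominant, , drop = FALSE]
    bed6 <- data.frame(dom$contig, dom$pos - 1L, dom$pos,
                       paste0("TSS_", seq_len(nrow(dom))),
                       round(dom$rrs, 3), dom$strand)
    write.table(bed6, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv)
}
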