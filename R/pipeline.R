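#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return a `Biostrings::DNAStringSet` with names truncated to the first
#'   whitespace-delimited token.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read genome features from GFF3
#'
#' @param path GFF3 path.
#' @param feature_types feature types to keep (`NULL` keeps all).
#' @return data.frame with `feature_id`, `contig`, `strand`, `start`, `end`
#'   (1-based inclusive) and `feature_type`.
#' @export
read_features <- function(path, feature_types = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(feature_types))
    gr <- gr[as.character(gr$type) %in% feature_types]
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  if (anyNA(ids)) {
    fallback <- if (!is.null(gr$Name)) gr$Name else NULL
    ids[is.na(ids)] <- if (!is.null(fallback)) fallback[is.na(ids)] else NA
    ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  }
  data.frame(feature_id = as.character(ids),
             contig = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             feature_type = as.character(gr$type))
}

#' Extract strand-aware windows around annotated features
#'
#' For each feature the window runs from `up` nt upstream to `down` nt
#' downstream of the feature's transcriptional start (the strand-aware start
#' coordinate): on the + strand genomic `[start - up, start + down]`, on the
#' - strand genomic `[end - down, end + up]` reverse-complemented. Windows
#' are clipped at contig edges and flagged.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param features data.frame as from [read_features()].
#' @param up,down extent in nt upstream/downstream of the feature start.
#' @return list of [sequence_window()] (source `"feature_window"`), named by
#'   feature id.
#' @export
extract_feature_windows <- function(genome, features, up = 500L,
                                    down = 100L) {
  if (is.character(genome)) genome <- read_genome(genome)
  clens <- stats::setNames(Biostrings::width(genome), names(genome))
  out <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    if (!f$contig %in% names(genome))
      stop("feature '", f$feature_id, "': unknown contig '", f$contig, "'")
    clen <- clens[[f$contig]]
    if (f$start < 1L || f$end > clen || f$start > f$end)
      stop("feature '", f$feature_id, "' lies outside contig '", f$contig,
           "'")
    if (f$strand == "+") {
      gstart <- f$start - up; gend <- f$start + down
    } else {
      gstart <- f$end - down; gend <- f$end + up
    }
    clipped <- gstart < 1L || gend > clen
    gstart <- max(1L, gstart); gend <- min(clen, gend)
    out[[i]] <- sequence_window(
      extract_window_seq(genome, f$contig, f$strand, gstart, gend),
      window_id = f$feature_id, source = "feature_window",
      contig = f$contig, strand = f$strand,
      genomic_start = gstart, genomic_end = gend, clipped = clipped)
  }
  stats::setNames(out, features$feature_id)
}

#' Background distribution of best promoter scores across a genome
#'
#' Scans overlapping tiles over every contig on both strands and records the
#' best unanchored bipartite total per tile. The default tile length matches
#' the feature-window length (601 nt) with half-overlapping steps.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param pair a [pssm_pair()].
#' @param tile_len tile length in nt.
#' @param step step between tile starts in nt.
#' @return list with `tiles` (data.frame contig/strand/start/end/total) and
#'   `summary` (n, mean, sd, quantiles, histogram).
#' @export
genome_background_scan <- function(genome, pair, tile_len = 601L,
                                   step = 300L) {
  if (is.character(genome)) genome <- read_genome(genome)
  stopifnot(tile_len >= min_placement_len(pair))
  rows <- list()
  for (contig in names(genome)) {
    clen <- Biostrings::width(genome[names(genome) == contig])[1L]
    starts <- seq(1L, max(1L, clen - tile_len + 1L), by = step)
    for (strand in c("+", "-")) {
      for (s in starts) {
        e <- min(clen, s + tile_len - 1L)
        codes <- encode_dna(extract_window_seq(genome, contig, strand, s, e))
        tot <- best_total_cpp(codes, pair$pssm35$logprob,
                              pair$pssm10$logprob, pair$spacer_min,
                              pair$spacer_max, FALSE, -1L,
                              pair$tss_dist_min, pair$tss_dist_max)
        rows[[length(rows) + 1L]] <- data.frame(
          contig = contig, strand = strand, start = s, end = e, total = tot)
      }
    }
  }
  tiles <- do.call(rbind, rows)
  tot <- tiles$total[is.finite(tiles$total)]
  br <- pretty(tot, n = 30)
  hs <- graphics::hist(tot, breaks = br, plot = FALSE)
  list(tiles = tiles,
       summary = list(
         n = length(tot), mean = mean(tot), sd = sd(tot),
         quantiles = quantile(tot, c(0, .25, .5, .75, .9, .95, .99, 1)),
         histogram = data.frame(mid = hs$mids, count = hs$counts)))
}

# strand-aware 5'-most member of a unit defines its upstream region
unit_lead_feature <- function(members, features) {
  f <- features[features$feature_id %in% members, , drop = FALSE]
  if (!nrow(f)) return(NULL)
  if (f$strand[1L] == "+") f[which.min(f$start), , drop = FALSE]
  else f[which.max(f$end), , drop = FALSE]
}

#' Run the genome-wide off-target promoter prediction pipeline
#'
#' Orchestrates the full flow for one PSSM pair: TSS calling from 5'-end
#' count tracks (when given), extraction of TSS specific to the
#' overexpression sample, TSS-anchored promoter scanning with empirical
#' E-values, collection of promoter hits upstream of DE-regulated units,
#' Pareto/worst-value cutoff calibration, scanning of windows around all
#' annotated features, conjunctive cutoff filtering (E-values are computed
#' for the score-passing candidates), optional intersection with a
#' low-duplex-stability interval list, and reporting. Fully reproducible
#' given `config$seed`.
#'
#' @param config a named list (or path of a YAML/JSON file) with entries:
#'   \describe{
#'     \item{genome}{`DNAStringSet` or FASTA path (required).}
#'     \item{annotation}{features data.frame or GFF3 path (required).}
#'     \item{pair}{a [pssm_pair()] (required).}
#'     \item{treatment, control}{[start_count_track()]s, or lists with
#'       `fwd`/`rev`/`tsv` paths for [read_start_counts()] (optional; when
#'       absent the TSS stages are skipped).}
#'     \item{de_table}{DE data.frame or TSV path (optional; when absent, or
#'       when `calibrate = FALSE`, filtering uses `max_evalue` only).}
#'     \item{min_rrs}{minimal RRS for TSS selection (default 3.0).}
#'     \item{tss_tolerance}{strain-specificity tolerance in nt (default 3).}
#'     \item{window_len}{anchored upstream window length (default 40).}
#'     \item{up, down}{feature window extent (defaults 500/100).}
#'     \item{n_null}{shuffles per E-value (default 1000).}
#'     \item{max_evalue}{anchored-scan retention threshold (default 0.05).}
#'     \item{relax}{cutoff relaxation fraction (default 0.05).}
#'     \item{calibrate}{calibrate cutoffs from the DE table (default `TRUE`
#'       when a DE table is given).}
#'     \item{background}{run the genome background scan (default `TRUE`).}
#'     \item{stability_bed}{optional BED path of low-duplex-stability
#'       intervals; retained hits gain a `low_stability` flag.}
#'     \item{seed}{integer seed for all randomness (default 1).}
#'     \item{out_dir}{optional directory for artifacts (TSV/GFF3/JSON).}
#'   }
#' @return an object of class `prediction_report`.
#' @export
run_offtarget_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(
    list(min_rrs = 3.0, tss_tolerance = 3L, window_len = 40L,
         up = 500L, down = 100L, n_null = 1000L, max_evalue = 0.05,
         relax = 0.05, calibrate = TRUE, background = TRUE,
         stability_bed = NULL, seed = 1L, out_dir = NULL),
    config)
  for (req in c("genome", "annotation", "pair"))
    if (is.null(cfg[[req]])) stop("config entry '", req, "' is missing")
  genome <- if (is.character(cfg$genome)) read_genome(cfg$genome)
            else cfg$genome
  features <- if (is.character(cfg$annotation)) read_features(cfg$annotation)
              else cfg$annotation
  pair <- cfg$pair
  stopifnot(inherits(pair, "pssm_pair"))
  de <- cfg$de_table
  if (is.character(de)) de <- read_de_table(de)
  as_track <- function(x, id) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "start_count_track")) return(x)
    do.call(read_start_counts, c(x, list(sample_id = id)))
  }
  treatment <- as_track(cfg$treatment, "treatment")
  control <- as_track(cfg$control, "control")

  set.seed(cfg$seed)
  stages <- list()

  # -- TSS calling and strain-specific extraction ---------------------------
  specific_tss <- NULL
  if (!is.null(treatment) && !is.null(control)) {
    call_one <- function(track) {
      select_tss(cluster_tss_all(compute_rrs(track)), min_rrs = cfg$min_rrs)
    }
    tss_t <- call_one(treatment)
    tss_c <- call_one(control)
    specific_tss <- strain_specific_tss(tss_t, tss_c,
                                        tolerance = cfg$tss_tolerance)
    stages$tss <- list(treatment = tss_t, control = tss_c,
                       specific = specific_tss)
  }

  # -- TSS-anchored promoter scan ------------------------------------------
  anchored_hits <- NULL
  if (!is.null(specific_tss)) {
    anchored_hits <- tss_anchored_scan(
      specific_tss, genome, pair, window_len = cfg$window_len,
      n_null = cfg$n_null, max_evalue = cfg$max_evalue)
    stages$anchored_hits <- anchored_hits
  }

  # -- cutoff calibration from DE-supported units --------------------------
  cutoffs <- NULL
  windows <- extract_feature_windows(genome, features, up = cfg$up,
                                     down = cfg$down)
  if (isTRUE(cfg$calibrate) && !is.null(de)) {
    reg <- regulated_units(de)
    hits_by_unit <- list()
    for (i in seq_len(nrow(reg))) {
      lead <- unit_lead_feature(reg$members[[i]], features)
      if (is.null(lead)) next
      w <- windows[[lead$feature_id]]
      h <- all_hits(w, pair)
      if (!nrow(h)) { hits_by_unit[[reg$unit_id[i]]] <- h; next }
      fr <- pareto_front(h)
      nulls <- null_best_scores(w, pair, n = cfg$n_null)
      fr$evalue <- vapply(fr$total, function(t) mean(nulls >= t), numeric(1))
      hits_by_unit[[reg$unit_id[i]]] <- fr
    }
    cutoffs <- calibrate_cutoffs(reg, hits_by_unit, relax = cfg$relax)
    stages$cutoffs <- cutoffs
  }

  # -- genome-wide feature-window scan + filtering -------------------------
  retained <- list()
  for (fid in names(windows)) {
    w <- windows[[fid]]
    h <- all_hits(w, pair)
    if (!nrow(h)) next
    if (!is.null(cutoffs)) {
      h <- h[h$s35 >= cutoffs$min_s35 & h$s10 >= cutoffs$min_s10 &
               h$total >= cutoffs$min_total, , drop = FALSE]
      max_e <- cutoffs$max_evalue
    } else max_e <- cfg$max_evalue
    if (!nrow(h)) next
    # E-values are only needed for the score-passing candidates; one null
    # simulation of the window serves every candidate
    nulls <- null_best_scores(w, pair, n = cfg$n_null)
    h$evalue <- vapply(h$total, function(t) mean(nulls >= t), numeric(1))
    h <- if (!is.null(cutoffs)) apply_cutoffs(h, cutoffs)
         else h[h$evalue <= max_e, , drop = FALSE]
    if (nrow(h)) retained[[fid]] <- h
  }
  retained <- if (length(retained)) do.call(rbind, retained) else empty_hits()
  rownames(retained) <- NULL
  # adjacent features can attribute the same genomic promoter twice: both
  # attributions are listed, duplicates flagged by genomic coordinates
  if (nrow(retained)) {
    key <- paste(retained$contig, retained$strand, retained$g35_start,
                 retained$g10_start)
    retained$duplicate_of <- NA_character_
    first <- !duplicated(key)
    idx <- match(key, key[first])
    dupof <- retained$window_id[first][idx]
    retained$duplicate_of[!first] <- dupof[!first]
  }

  # -- optional low-duplex-stability intersection --------------------------
  if (!is.null(cfg$stability_bed) && nrow(retained)) {
    bed <- rtracklayer::import(cfg$stability_bed, format = "bed")
    gr <- GenomicRanges::GRanges(
      retained$contig,
      IRanges::IRanges(pmin(retained$g35_start, retained$g10_start),
                       pmax(retained$g35_end, retained$g10_end)))
    retained$low_stability <-
      IRanges::overlapsAny(gr, bed, ignore.strand = TRUE)
  }

  background <- if (isTRUE(cfg$background))
    genome_background_scan(genome, pair) else NULL

  n_feat <- length(unique(retained$window_id))
  report <- structure(list(
    config = list(seed = cfg$seed, pssm_pair = pair$ecf_group,
                  min_rrs = cfg$min_rrs, tss_tolerance = cfg$tss_tolerance,
                  window_len = cfg$window_len, up = cfg$up, down = cfg$down,
                  n_null = cfg$n_null, max_evalue = cfg$max_evalue,
                  relax = cfg$relax, calibrated = !is.null(cutoffs)),
    tss = stages$tss,
    anchored_hits = anchored_hits,
    cutoffs = cutoffs,
    retained_hits = retained,
    n_features_with_promoter = n_feat,
    background = background$summary),
    class = "prediction_report")
  if (!is.null(cfg$out_dir)) write_prediction_report(report, cfg$out_dir)
  report
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("Off-target promoter prediction report\n")
  cat(sprintf("  PSSM pair: %s (seed %d)\n", x$config$pssm_pair,
              x$config$seed))
  if (!is.null(x$tss))
    cat(sprintf("  TSS: %d treatment, %d control, %d specific\n",
                nrow(x$tss$treatment), nrow(x$tss$control),
                nrow(x$tss$specific)))
  if (!is.null(x$anchored_hits))
    cat(sprintf("  TSS-anchored promoters retained (E <= %.2g): %d\n",
                x$config$max_evalue, nrow(x$anchored_hits)))
  if (!is.null(x$cutoffs)) print(x$cutoffs)
  cat(sprintf("  retained hits: %d across %d feature(s)\n",
              nrow(x$retained_hits), x$n_features_with_promoter))
  if (!is.null(x$background))
    cat(sprintf("  background: %d tiles, median best total %.3f\n",
                x$background$n, unname(x$background$quantiles["50%"])))
  invisible(x)
}

#' Write all report artifacts to a directory
#'
#' Emits `report.json` (config echo, counts, cutoffs, background summary),
#' `retained_hits.tsv`/`retained_hits.gff3`, and when present
#' `tss_specific.tsv`, `anchored_hits.tsv`, `cutoffs.json` and
#' `background_histogram.tsv`. Byte-identical across reruns with the same
#' config and seed.
#'
#' @param report a `prediction_report`.
#' @param dir output directory (created if needed).
#' @export
write_prediction_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_hits(report$retained_hits, p("retained_hits.tsv"),
             p("retained_hits.gff3"))
  if (!is.null(report$tss))
    write_tss(report$tss$specific, p("tss_specific.tsv"))
  if (!is.null(report$anchored_hits))
    write_hits(report$anchored_hits, p("anchored_hits.tsv"))
  if (!is.null(report$cutoffs)) write_cutoffs(report$cutoffs, p("cutoffs.json"))
  if (!is.null(report$background))
    write.table(report$background$histogram, p("background_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  js <- list(
    config = report$config,
    n_features_with_promoter = report$n_features_with_promoter,
    n_retained_hits = nrow(report$retained_hits),
    n_specific_tss = if (is.null(report$tss)) NULL
                     else nrow(report$tss$specific),
    n_anchored_hits = if (is.null(report$anchored_hits)) NULL
                      else nrow(report$anchored_hits),
    cutoffs = if (is.null(report$cutoffs)) NULL else {
      cs <- unclass(report$cutoffs); cs$provenance <- NULL; cs
    },
    background_quantiles = if (is.null(report$background)) NULL
                           else as.list(report$background$quantiles))
  jsonlite::write_json(js, p("report.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(dir)
}
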