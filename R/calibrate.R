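#' Read a differential-expression table of transcription units
#'
#' Tab-separated with header columns `unit_id`, `members` (comma-separated
#' feature ids of the operon or monocistronic unit), `log2fc`, `padj`.
#'
#' @param path TSV path.
#' @return data.frame with a list-column `members`.
#' @export
read_de_table <- function(path) {
  de <- read.delim(path, colClasses = c(unit_id = "character",
                                        members = "character"))
  stopifnot(all(c("unit_id", "members", "log2fc", "padj") %in% names(de)))
  de$members <- strsplit(de$members, ",", fixed = TRUE)
  de
}

#' Filter units regulated by ECF overexpression
#'
#' Keeps units with `log2fc > min_log2fc` (strict) and `padj < max_padj`
#' (strict), the DE-evidence filter used to select calibration units.
#'
#' @param de a DE table (see [read_de_table()]).
#' @param min_log2fc lower log2 fold-change bound (default 2, exclusive).
#' @param max_padj upper adjusted-p bound (default 0.05, exclusive).
#' @return the regulated subset of `de`.
#' @export
regulated_units <- function(de, min_log2fc = 2, max_padj = 0.05) {
  out <- de[de$log2fc > min_log2fc & de$padj < max_padj, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pareto-optimal promoter hits in the (-35, -10) score plane
#'
#' A hit is Pareto-optimal when no other hit is at least as good on both the
#' -35 and the -10 score with at least one strict improvement (maximization
#' of both coordinates; scores are negative, closer to 0 is better).
#' Duplicates with identical `(s35, s10)` are all retained. Implemented as a
#' sort-and-sweep over descending `s35`.
#'
#' @param hits data.frame of hits with `s35` and `s10` columns.
#' @return the Pareto-optimal subset, ordered by descending `s35`.
#' @export
pareto_front <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (!nrow(hits)) return(hits)
  ord <- order(-hits$s35, -hits$s10)
  s35 <- hits$s35[ord]; s10 <- hits$s10[ord]
  keep <- logical(length(ord))
  best10 <- -Inf; front35 <- NA_real_
  for (i in seq_along(ord)) {
    if (s10[i] > best10) {
      keep[i] <- TRUE; best10 <- s10[i]; front35 <- s35[i]
    } else if (s10[i] == best10 && s35[i] == front35) {
      keep[i] <- TRUE  # exact duplicate of the current front point
    }
  }
  out <- hits[ord[keep], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrated genome-scan cutoffs
#'
#' Container for the four conjunctive cutoffs derived from DE-supported
#' promoters: minimal -35, -10 and total scores and maximal E-value, with
#' the relaxation already applied.
#'
#' @param min_s35,min_s10,min_total minimal scores in bits (<= 0).
#' @param max_evalue maximal E-value in `[0, 1]`.
#' @param relax_factor relaxation fraction that was applied.
#' @param provenance list with `units_used` and `units_excluded`.
#' @return an object of class `cutoff_set`.
#' @export
cutoff_set <- function(min_s35, min_s10, min_total, max_evalue,
                       relax_factor = 0.05, provenance = list()) {
  structure(list(min_s35 = min_s35, min_s10 = min_s10, min_total = min_total,
                 max_evalue = max_evalue, relax_factor = relax_factor,
                 provenance = provenance),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf(paste0("cutoff_set: s35 >= %.4f, s10 >= %.4f, ",
                     "total >= %.4f, E <= %.4g (relax %.0f%%, %d unit(s))\n"),
              x$min_s35, x$min_s10, x$min_total, x$max_evalue,
              100 * x$relax_factor,
              length(x$provenance$units_used %||% character(0))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate score cutoffs from DE-supported promoter hits
#'
#' For each regulated unit the Pareto-optimal hits in the (-35, -10) score
#' plane are identified; over the union of all fronts the worst values of the
#' -35 score, the -10 score, the total score (most negative) and the E-value
#' (largest) become the cutoffs. To combat overfitting each cutoff is relaxed
#' by the uncertainty factor: negative score cutoffs are multiplied by
#' `1 + relax` (moving away from 0, i.e. more permissive) and the E-value
#' cutoff by `1 + relax`, capped at 1. Every hit that entered the calibration
#' therefore passes [apply_cutoffs()] afterwards.
#'
#' @param units data.frame of regulated units (already DE-filtered, or raw:
#'   the `log2fc > 2`, `padj < 0.05` filter is re-applied here).
#' @param hits_by_unit named list mapping `unit_id` to a hits data.frame for
#'   that unit's upstream region; hits must carry E-values unless
#'   `fixed_max_evalue` is given.
#' @param relax uncertainty relaxation fraction (default 0.05).
#' @param min_log2fc,max_padj DE thresholds, as in [regulated_units()].
#' @param fixed_max_evalue if non-`NULL`, use this fixed E-value cutoff
#'   instead of the worst front E-value.
#' @return a [cutoff_set()].
#' @export
calibrate_cutoffs <- function(units, hits_by_unit, relax = 0.05,
                              min_log2fc = 2, max_padj = 0.05,
                              fixed_max_evalue = NULL) {
  units <- regulated_units(units, min_log2fc, max_padj)
  if (!nrow(units)) stop("no regulated units to calibrate from")
  fronts <- list(); used <- character(0); excluded <- character(0)
  for (uid in units$unit_id) {
    h <- hits_by_unit[[uid]]
    if (is.null(h) || !nrow(h)) {
      warning("regulated unit '", uid, "' has no promoter hits; excluded ",
              "from calibration")
      excluded <- c(excluded, uid)
      next
    }
    fronts[[uid]] <- pareto_front(h)
    used <- c(used, uid)
  }
  if (!length(fronts)) stop("no regulated unit contributed hits")
  front <- do.call(rbind, fronts)
  if (is.null(fixed_max_evalue)) {
    if (anyNA(front$evalue))
      stop("front hits lack E-values; compute them or pass fixed_max_evalue")
    max_e <- max(front$evalue)
  } else max_e <- fixed_max_evalue
  cutoff_set(
    min_s35 = min(front$s35) * (1 + relax),
    min_s10 = min(front$s10) * (1 + relax),
    min_total = min(front$total) * (1 + relax),
    max_evalue = min(1, max_e * (1 + relax)),
    relax_factor = relax,
    provenance = list(units_used = used, units_excluded = excluded))
}

#' Filter promoter hits by calibrated cutoffs
#'
#' Keeps a hit iff it simultaneously satisfies all four conditions:
#' `s35 >= min_s35`, `s10 >= min_s10`, `total >= min_total` and
#' `evalue <= max_evalue` (all boundaries inclusive).
#'
#' @param hits hits data.frame; every row must carry an E-value.
#' @param cutoffs a [cutoff_set()].
#' @return the passing subset.
#' @export
apply_cutoffs <- function(hits, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  if (!nrow(hits)) return(hits)
  if (anyNA(hits$evalue))
    stop("hit(s) without an E-value; compute E-values before filtering")
  keep <- hits$s35 >= cutoffs$min_s35 & hits$s10 >= cutoffs$min_s10 &
    hits$total >= cutoffs$min_total & hits$evalue <= cutoffs$max_evalue
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a cutoff set as JSON
#'
#' @param cutoffs a [cutoff_set()].
#' @param path output path.
#' @export
write_cutoffs <- function(cutoffs, path) {
  jsonlite::write_json(unclass(cutoffs), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
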