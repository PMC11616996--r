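# Cross-referencing of peaks with splicing and expression results:
# condition-unique peaks, the exon +/- flank high-confidence overlap rule,
# three-way set intersection, and the PSI / isoform-ratio arithmetic used
# in validation experiments.

#' Condition-unique peaks
#'
#' A peak is unique to its condition iff no same-strand peak of the other
#' condition overlaps it by at least 1 nt.
#'
#' @param peaks_a,peaks_b Peak data.frames of the two conditions.
#' @return A list with `unique_a` and `unique_b` (row subsets).
#' @export
condition_unique_peaks <- function(peaks_a, peaks_b) {
  overlap_any <- function(x, y) {
    if (nrow(x) == 0L) return(logical(0))
    if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
    hits <- GenomicRanges::findOverlaps(peaks_gr(x), peaks_gr(y),
                                        ignore.strand = FALSE)
    seq_len(nrow(x)) %in% S4Vectors::queryHits(hits)
  }
  list(unique_a = peaks_a[!overlap_any(peaks_a, peaks_b), , drop = FALSE],
       unique_b = peaks_b[!overlap_any(peaks_b, peaks_a), , drop = FALSE])
}

#' High-confidence peak / splicing-event overlap calls
#'
#' A peak hits an event when it overlaps the window
#' `[exon_start - flank, exon_end + flank)` (half-open; flanks truncated to
#' the length of the actual flanking intron so they never reach the
#' neighboring exon) on the same strand. The relation records whether the
#' peak touches the exon itself (`within_exon`, distance 0) or only the
#' transcript-orientation upstream/downstream intronic flank, with the
#' distance from the peak edge to the nearer exon boundary.
#'
#' @param peaks Peak data.frame (typically condition-unique peaks).
#' @param events Filtered `as_table` of significant events.
#' @param flank_nt Flank width in nt (default 250).
#' @return data.frame: `event_id`, `peak_id`, `relation`, `distance_nt`.
#' @export
highconf_overlap <- function(peaks, events, flank_nt = 250L) {
  rows <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    iv <- event_introns(ev)
    up_len <- max(0L, iv$up[2] - iv$up[1])
    down_len <- max(0L, iv$down[2] - iv$down[1])
    fu <- min(flank_nt, up_len)
    fd <- min(flank_nt, down_len)
    if (ev$strand == "+") {
      win <- c(ev$exon_start - fu, ev$exon_end + fd)
    } else {
      win <- c(ev$exon_start - fd, ev$exon_end + fu)
    }
    p <- peaks[peaks$contig == ev$contig & peaks$strand == ev$strand &
                 peaks$start < win[2] & peaks$end > win[1], , drop = FALSE]
    for (j in seq_len(nrow(p))) {
      pk <- p[j, ]
      if (pk$start < ev$exon_end && pk$end > ev$exon_start) {
        rel <- "within_exon"; dist <- 0L
      } else if (pk$end <= ev$exon_start) {
        rel <- if (ev$strand == "+") "upstream_flank" else
          "downstream_flank"
        dist <- ev$exon_start - pk$end
      } else {
        rel <- if (ev$strand == "+") "downstream_flank" else
          "upstream_flank"
        dist <- pk$start - ev$exon_end
      }
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = ev$event_id, peak_id = pk$peak_id, relation = rel,
        distance_nt = as.integer(dist), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(event_id = integer(), peak_id = character(),
                      relation = character(), distance_nt = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Three-way DE / AS / peak-bearing gene cross-reference
#'
#' Collapses everything to the gene level and reports all seven Venn cells
#' of the three sets plus the percentage of DE genes and of alternatively
#' spliced genes that carry a peak.
#'
#' @param de_genes,as_genes,peak_genes Character vectors of gene ids
#'   (duplicates are collapsed).
#' @return A list of class `crossref_summary`: `n_de`, `n_as`, `n_peak`,
#'   `cells` (named 7-vector: de_only, as_only, peak_only, de_as, de_peak,
#'   as_peak, de_as_peak), `pct_de_with_peak`, `pct_as_with_peak`.
#' @export
three_way_crossref <- function(de_genes, as_genes, peak_genes) {
  de <- unique(as.character(de_genes))
  as_ <- unique(as.character(as_genes))
  pk <- unique(as.character(peak_genes))
  all_ids <- union(union(de, as_), pk)
  in_de <- all_ids %in% de
  in_as <- all_ids %in% as_
  in_pk <- all_ids %in% pk
  cells <- c(
    de_only = sum(in_de & !in_as & !in_pk),
    as_only = sum(!in_de & in_as & !in_pk),
    peak_only = sum(!in_de & !in_as & in_pk),
    de_as = sum(in_de & in_as & !in_pk),
    de_peak = sum(in_de & !in_as & in_pk),
    as_peak = sum(!in_de & in_as & in_pk),
    de_as_peak = sum(in_de & in_as & in_pk))
  out <- list(n_de = length(de), n_as = length(as_), n_peak = length(pk),
              cells = cells,
              pct_de_with_peak = if (length(de) > 0)
                100 * sum(in_de & in_pk) / length(de) else NA_real_,
              pct_as_with_peak = if (length(as_) > 0)
                100 * sum(in_as & in_pk) / length(as_) else NA_real_)
  class(out) <- "crossref_summary"
  out
}

#' @export
print.crossref_summary <- function(x, ...) {
  cat(sprintf("crossref_summary: DE=%d AS=%d peak=%d\n", x$n_de, x$n_as,
              x$n_peak))
  print(x$cells)
  cat(sprintf("  DE genes with peak: %.1f%%; AS genes with peak: %.1f%%\n",
              x$pct_de_with_peak, x$pct_as_with_peak))
  invisible(x)
}

#' Percent spliced in from isoform abundances
#'
#' PSI of a two-(or more-)isoform measurement: 100 times the abundance of
#' the larger isoform (the first element) divided by the total abundance.
#'
#' @param abundances Non-negative numeric vector (length >= 2, not all
#'   zero) with the larger isoform first.
#' @return PSI percentage in `[0, 100]`.
#' @export
psi_from_abundances <- function(abundances) {
  if (length(abundances) < 2L) stop("need >= 2 isoform abundances")
  if (any(abundances < 0)) stop("negative abundance")
  total <- sum(abundances)
  if (total == 0) stop("all abundances are zero")
  100 * abundances[1] / total
}

#' Larger:smaller isoform ratio with loading-control normalization
#'
#' @param larger,smaller Isoform fractions (smaller must be > 0).
#' @param larger_control,smaller_control Loading-control values each
#'   fraction is divided by before the ratio (a shared control cancels).
#' @return The normalized ratio.
#' @export
isoform_ratio <- function(larger, smaller, larger_control = 1,
                          smaller_control = larger_control) {
  if (smaller <= 0) stop("smaller fraction must be > 0")
  if (larger_control <= 0 || smaller_control <= 0) {
    stop("control values must be > 0")
  }
  (larger / larger_control) / (smaller / smaller_control)
}
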