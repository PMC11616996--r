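# Cassette-exon and flanking-intron sequence features, and nonparametric
# group comparisons of feature distributions.

# Strand-aware flanking-intron intervals of one SE event row.
event_introns <- function(ev) {
  if (ev$strand == "+") {
    list(up = c(ev$upstream_end, ev$exon_start),
         down = c(ev$exon_end, ev$downstream_start))
  } else {
    list(up = c(ev$exon_end, ev$upstream_start),
         down = c(ev$downstream_end, ev$exon_start))
  }
}

#' Sequence features of cassette exons and their flanking introns
#'
#' For each skipped-exon event computes the target-exon GC percentage, the
#' GC percentage of the transcript-orientation upstream and downstream
#' introns (full intron length), the downstream-intron:exon GC ratio, and
#' the upstream/downstream intron:exon length ratios. Events whose flanking
#' intron is missing or zero-length, or whose exon GC is 0% (undefined
#' ratio), are skipped with a message.
#'
#' @param events An `as_table` (only `event_type == "SE"` rows are used
#'   unless `all_types = TRUE`).
#' @param genome A `genome_seq`.
#' @param group Optional vector of group labels (recycled onto the used
#'   rows) stored in the output.
#' @param all_types Include non-SE events (default `FALSE`).
#' @return data.frame: `event_id`, `group`, `exon_gc`, `up_intron_gc`,
#'   `down_intron_gc`, `down_intron_to_exon_gc_ratio`,
#'   `up_intron_to_exon_length_ratio`, `down_intron_to_exon_length_ratio`.
#' @export
compute_features <- function(events, genome, group = NA_character_,
                             all_types = FALSE) {
  use <- if (all_types) seq_len(nrow(events))
         else which(events$event_type == "SE")
  grp <- rep_len(group, length(use))
  out <- vector("list", length(use))
  skipped <- 0L
  for (j in seq_along(use)) {
    ev <- events[use[j], ]
    iv <- event_introns(ev)
    up_len <- iv$up[2] - iv$up[1]
    down_len <- iv$down[2] - iv$down[1]
    if (is.na(up_len) || is.na(down_len) || up_len <= 0 || down_len <= 0) {
      skipped <- skipped + 1L
      next
    }
    exon_seq <- get_seq(genome, ev$contig, ev$exon_start, ev$exon_end,
                        ev$strand)
    up_seq <- get_seq(genome, ev$contig, iv$up[1], iv$up[2], ev$strand)
    down_seq <- get_seq(genome, ev$contig, iv$down[1], iv$down[2],
                        ev$strand)
    exon_gc <- 100 * gc_content(exon_seq)
    if (exon_gc == 0) {
      warning("event ", ev$event_id, " has 0% exon GC; ratio undefined, ",
              "event skipped")
      skipped <- skipped + 1L
      next
    }
    exon_len <- ev$exon_end - ev$exon_start
    out[[j]] <- data.frame(
      event_id = ev$event_id, group = grp[j],
      exon_gc = exon_gc,
      up_intron_gc = 100 * gc_content(up_seq),
      down_intron_gc = 100 * gc_content(down_seq),
      down_intron_to_exon_gc_ratio = 100 * gc_content(down_seq) / exon_gc,
      up_intron_to_exon_length_ratio = up_len / exon_len,
      down_intron_to_exon_length_ratio = down_len / exon_len,
      stringsAsFactors = FALSE)
  }
  if (skipped > 0L) {
    message(skipped, " event(s) skipped (missing/zero-length flanking ",
            "intron or undefined GC ratio)")
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(event_id = integer(), group = character(),
                      exon_gc = numeric(), up_intron_gc = numeric(),
                      down_intron_gc = numeric(),
                      down_intron_to_exon_gc_ratio = numeric(),
                      up_intron_to_exon_length_ratio = numeric(),
                      down_intron_to_exon_length_ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mann-Whitney comparison of two feature groups
#'
#' Reports group medians, the Mann-Whitney U statistic of the first group,
#' and the two-sided p-value: exact by enumeration for combined n <= 20
#' (and no ties), normal approximation with tie correction otherwise.
#'
#' @param x,y Numeric vectors (each nonempty).
#' @return A list: `n_a`, `n_b`, `median_a`, `median_b`, `U`, `p`.
#' @export
group_compare <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  exact <- (length(x) + length(y)) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(n_a = length(x), n_b = length(y),
       median_a = stats::median(x), median_b = stats::median(y),
       U = unname(wt$statistic), p = wt$p.value)
}

#' Compare one feature between two labeled groups
#'
#' @param records Feature data.frame from [compute_features()] or
#'   [bound_vs_unbound_features()].
#' @param feature Feature column name.
#' @param group_a,group_b Group labels to compare.
#' @return [group_compare()] output plus the group labels.
#' @export
compare_feature_groups <- function(records, feature, group_a, group_b) {
  x <- records[[feature]][records$group == group_a]
  y <- records[[feature]][records$group == group_b]
  c(list(feature = feature, group_a = group_a, group_b = group_b),
    group_compare(x, y))
}

#' GC features of internal exons grouped by peak binding
#'
#' Labels every internal exon (neither first nor last) of every coding
#' transcript by whether a same-strand peak of each condition overlaps it:
#' `unbound`, `bound_minus` (first condition only), `bound_plus` (second
#' only), or `bound` (both).
#'
#' @param peaks Peak data.frame with a `condition` column (two conditions).
#' @param db A `transcript_db`.
#' @param genome A `genome_seq`.
#' @param conditions Length-2 condition labels; defaults to the order of
#'   first appearance in `peaks`.
#' @return data.frame: `transcript_id`, `exon_index`, `start`, `end`,
#'   `exon_gc`, `group`.
#' @export
bound_vs_unbound_features <- function(peaks, db, genome,
                                      conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(peaks$condition)
  tx <- db$transcripts[db$transcripts$coding, ]
  rows <- list()
  for (i in seq_len(nrow(tx))) {
    ex <- db$exons[db$exons$transcript_id == tx$transcript_id[i], ]
    if (nrow(ex) < 3L) next
    internal <- 2:(nrow(ex) - 1L)
    p <- peaks[peaks$contig == tx$contig[i] &
                 peaks$strand == tx$strand[i], , drop = FALSE]
    for (j in internal) {
      hit <- p$start < ex$end[j] & p$end > ex$start[j]
      ha <- any(hit & p$condition == conditions[1])
      hb <- length(conditions) > 1L &&
        any(hit & p$condition == conditions[2])
      group <- if (ha && hb) "bound" else if (ha) "bound_minus"
               else if (hb) "bound_plus" else "unbound"
      seqs <- get_seq(genome, tx$contig[i], ex$start[j], ex$end[j],
                      tx$strand[i])
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx$transcript_id[i], exon_index = j,
        start = ex$start[j], end = ex$end[j],
        exon_gc = 100 * gc_content(seqs), group = group,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(transcript_id = character(), exon_index = integer(),
                      start = integer(), end = integer(),
                      exon_gc = numeric(), group = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
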