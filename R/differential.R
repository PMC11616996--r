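# Filtering and cross-condition summaries of differential-expression and
# differential-splicing tables.

#' Read a differential-expression table
#'
#' Expects a TSV with at least a gene identifier, a log2 fold change, and an
#' adjusted p-value (column names `gene_id`/`gene`, `log2FoldChange`/
#' `log2FC`/`log2fc`, `padj`).
#'
#' @param path TSV path.
#' @return data.frame with columns `gene_id`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(d))
    if (length(hit) == 0L) stop("missing column: one of ",
                                paste(cands, collapse = "/"))
    d[[hit[1]]]
  }
  out <- data.frame(gene_id = as.character(pick(c("gene_id", "gene"))),
                    log2fc = as.numeric(pick(c("log2FoldChange", "log2FC",
                                               "log2fc"))),
                    padj = as.numeric(pick("padj")),
                    stringsAsFactors = FALSE)
  if (any(out$padj < 0 | out$padj > 1, na.rm = TRUE)) {
    stop("padj outside [0, 1]")
  }
  out
}

parse_num_list <- function(x) {
  lapply(strsplit(as.character(x), ","), function(v) {
    v <- suppressWarnings(as.numeric(v))
    v
  })
}

#' Read a splicing event table in the rMATS tab-separated dialect
#'
#' Parses comma-separated per-replicate inclusion levels and junction
#' counts into list columns and carries the table's delta-PSI
#' (`IncLevelDifference`) and FDR. Delta-PSI is taken from the table, never
#' recomputed from inclusion levels; a validation warning is emitted when
#' the two disagree by more than `dpsi_warn_tol`.
#'
#' @param path TSV path.
#' @param dpsi_warn_tol Tolerance for the delta-PSI consistency warning.
#' @return data.frame of class `as_table`: identifiers, `event_type`,
#'   coordinates (0-based half-open), list columns `inc1`, `inc2`, `ijc1`,
#'   `sjc1`, `ijc2`, `sjc2`, and numeric `delta_psi`, `fdr`.
#' @export
read_as_table <- function(path, dpsi_warn_tol = 0.05) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("GeneID", "chr", "strand", "exonStart_0base", "exonEnd",
            "upstreamES", "upstreamEE", "downstreamES", "downstreamEE",
            "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
            "FDR", "IncLevel1", "IncLevel2", "IncLevelDifference")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) stop("missing column(s): ",
                              paste(miss, collapse = ", "))
  out <- data.frame(
    event_id = if ("ID" %in% names(d)) d$ID else seq_len(nrow(d)),
    gene_id = as.character(d$GeneID),
    event_type = if ("event_type" %in% names(d)) d$event_type else "SE",
    contig = as.character(d$chr),
    strand = as.character(d$strand),
    exon_start = as.integer(d$exonStart_0base),
    exon_end = as.integer(d$exonEnd),
    upstream_start = as.integer(d$upstreamES),
    upstream_end = as.integer(d$upstreamEE),
    downstream_start = as.integer(d$downstreamES),
    downstream_end = as.integer(d$downstreamEE),
    delta_psi = as.numeric(d$IncLevelDifference),
    fdr = as.numeric(d$FDR),
    stringsAsFactors = FALSE)
  out$inc1 <- parse_num_list(d$IncLevel1)
  out$inc2 <- parse_num_list(d$IncLevel2)
  out$ijc1 <- parse_num_list(d$IJC_SAMPLE_1)
  out$sjc1 <- parse_num_list(d$SJC_SAMPLE_1)
  out$ijc2 <- parse_num_list(d$IJC_SAMPLE_2)
  out$sjc2 <- parse_num_list(d$SJC_SAMPLE_2)
  if (any(out$fdr < 0 | out$fdr > 1, na.rm = TRUE)) {
    stop("FDR outside [0, 1]")
  }
  if (any(abs(out$delta_psi) > 1, na.rm = TRUE)) {
    stop("|delta_psi| > 1")
  }
  recomputed <- vapply(seq_len(nrow(out)), function(i) {
    mean(out$inc1[[i]], na.rm = TRUE) - mean(out$inc2[[i]], na.rm = TRUE)
  }, numeric(1))
  bad <- which(abs(recomputed - out$delta_psi) > dpsi_warn_tol)
  if (length(bad) > 0L) {
    warning(length(bad), " event(s) whose delta-PSI differs from the mean ",
            "of the replicate inclusion levels by more than ", dpsi_warn_tol)
  }
  class(out) <- c("as_table", "data.frame")
  out
}

#' Filter a differential-expression table
#'
#' Retains records with `padj < padj_max` (strict) and fold change
#' `|2^log2fc| >= min_abs_fc` (inclusive; at the default of 2 this is
#' `|log2fc| >= 1`). Records with missing `padj` are dropped.
#'
#' @param records data.frame from [read_de_table()].
#' @param padj_max Adjusted-p threshold (strict `<`).
#' @param min_abs_fc Minimum absolute (linear) fold change (inclusive).
#' @return The retained rows.
#' @export
filter_de <- function(records, padj_max = 0.05, min_abs_fc = 2) {
  stopifnot(is.data.frame(records))
  keep <- !is.na(records$padj) & !is.na(records$log2fc) &
    records$padj < padj_max &
    2^abs(records$log2fc) >= min_abs_fc
  records[keep, , drop = FALSE]
}

#' Filter a splicing event table
#'
#' Retains events with `fdr <= fdr_max` (inclusive), `|delta_psi| >=
#' min_abs_dpsi` (inclusive), and at least `min_reads` junction reads
#' (inclusion + skipping) in either condition. By default replicate counts
#' are summed within a condition; `per_replicate = TRUE` instead requires a
#' single replicate to reach the threshold.
#'
#' @param records An `as_table` from [read_as_table()].
#' @param fdr_max FDR threshold (inclusive).
#' @param min_abs_dpsi Minimum |delta-PSI| (inclusive).
#' @param min_reads Minimum junction reads in either condition.
#' @param per_replicate Apply the read rule per replicate instead of to the
#'   per-condition sum.
#' @return The retained rows.
#' @export
filter_as <- function(records, fdr_max = 0.05, min_abs_dpsi = 0.05,
                      min_reads = 10, per_replicate = FALSE) {
  stopifnot(is.data.frame(records))
  reads_ok <- vapply(seq_len(nrow(records)), function(i) {
    r1 <- records$ijc1[[i]] + records$sjc1[[i]]
    r2 <- records$ijc2[[i]] + records$sjc2[[i]]
    if (per_replicate) {
      any(r1 >= min_reads) || any(r2 >= min_reads)
    } else {
      sum(r1) >= min_reads || sum(r2) >= min_reads
    }
  }, logical(1))
  keep <- !is.na(records$fdr) & records$fdr <= fdr_max &
    !is.na(records$delta_psi) & abs(records$delta_psi) >= min_abs_dpsi &
    reads_ok
  records[keep, , drop = FALSE]
}

#' Coordinate-based event identity key
#'
#' rMATS event IDs are not stable across runs, so cross-comparison overlap
#' uses (event type, contig, strand, full coordinate tuple) as identity.
#'
#' @param events An `as_table`.
#' @return Character vector of keys.
#' @export
as_event_key <- function(events) {
  paste(events$event_type, events$contig, events$strand,
        events$exon_start, events$exon_end,
        events$upstream_start, events$upstream_end,
        events$downstream_start, events$downstream_end, sep = ":")
}

#' Overlap and directionality summary of two significant sets
#'
#' Intersects two filtered tables by key, reports intersection/union sizes,
#' the intersection as a percentage of the union, and (among shared items)
#' the count and percentage whose direction sign agrees between the two
#' comparisons.
#'
#' @param set_a,set_b data.frames of significant records.
#' @param key Column (or vector) of identity keys; defaults to `gene_id`.
#' @param direction Column holding the signed effect (`log2fc` or
#'   `delta_psi`).
#' @return A list of class `comparison_summary`: `n_a`, `n_b`,
#'   `n_intersection`, `n_union`, `pct_shared`, `n_concordant`,
#'   `pct_concordant`, `n_shared_up`, `n_shared_down`.
#' @export
overlap_summary <- function(set_a, set_b, key = "gene_id",
                            direction = "log2fc") {
  ka <- if (length(key) == 1L && key %in% names(set_a)) set_a[[key]]
        else as_event_key(set_a)
  kb <- if (length(key) == 1L && key %in% names(set_b)) set_b[[key]]
        else as_event_key(set_b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    stop("duplicate keys within one set")
  }
  shared <- intersect(ka, kb)
  n_union <- length(union(ka, kb))
  da <- sign(set_a[[direction]][match(shared, ka)])
  db <- sign(set_b[[direction]][match(shared, kb)])
  conc <- da == db
  out <- list(n_a = length(ka), n_b = length(kb),
              n_intersection = length(shared), n_union = n_union,
              pct_shared = if (n_union > 0) 100 * length(shared) / n_union
                           else 0,
              n_concordant = sum(conc),
              pct_concordant = if (length(shared) > 0)
                100 * sum(conc) / length(shared) else NA_real_,
              n_shared_up = sum(da > 0 & db > 0),
              n_shared_down = sum(da < 0 & db < 0))
  class(out) <- "comparison_summary"
  out
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf(
    "comparison_summary: |A|=%d |B|=%d shared=%d union=%d (%.1f%%)\n",
    x$n_a, x$n_b, x$n_intersection, x$n_union, x$pct_shared))
  if (x$n_intersection > 0) {
    cat(sprintf("  concordant direction: %d (%.1f%%), up/up=%d down/down=%d\n",
                x$n_concordant, x$pct_concordant, x$n_shared_up,
                x$n_shared_down))
  }
  invisible(x)
}

#' Event-type composition of significant splicing events
#'
#' @param events Filtered `as_table`.
#' @return A list with `counts` and `fractions` over the five event types
#'   (fractions sum to 1 when events exist) and `se_sign`, the counts and
#'   fractions of positive / negative delta-PSI within skipped-exon events.
#' @export
event_type_composition <- function(events) {
  types <- c("SE", "RI", "MXE", "A5SS", "A3SS")
  counts <- vapply(types, function(t) sum(events$event_type == t),
                   integer(1))
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else
    stats::setNames(rep(0, length(types)), types)
  se <- events[events$event_type == "SE", , drop = FALSE]
  n_pos <- sum(se$delta_psi > 0)
  n_neg <- sum(se$delta_psi < 0)
  list(counts = counts, fractions = fractions,
       se_sign = c(n_pos = n_pos, n_neg = n_neg,
                   frac_pos = if (nrow(se) > 0) n_pos / nrow(se) else 0,
                   frac_neg = if (nrow(se) > 0) n_neg / nrow(se) else 0))
}
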