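# Peak-to-region assignment, region composition, and peak-coverage
# metaprofiles across transcript regions and around splice sites.

#' Read CLIP peaks from BED
#'
#' Six-column, strand-aware BED. Coordinates stay 0-based half-open.
#'
#' @param bed_path BED path.
#' @param condition Condition label attached to every peak.
#' @return data.frame with columns `peak_id`, `contig`, `start`, `end`,
#'   `strand`, `condition`, `score`.
#' @export
read_peaks <- function(bed_path, condition = "unlabeled") {
  gr <- rtracklayer::import(bed_path, format = "bed")
  strand_chr <- as.character(GenomicRanges::strand(gr))
  if (any(!strand_chr %in% c("+", "-"))) {
    stop("BED peak without +/- strand")
  }
  nm <- if (!is.null(gr$name) && !anyNA(gr$name)) gr$name
        else sprintf("peak%05d", seq_along(gr))
  data.frame(peak_id = nm,
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = strand_chr,
             condition = condition,
             score = if (is.null(gr$score)) NA_real_ else gr$score,
             stringsAsFactors = FALSE)
}

#' Write peaks to BED
#'
#' @param peaks Peak data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  d <- data.frame(peaks$contig, peaks$start, peaks$end, peaks$peak_id,
                  ifelse(is.na(peaks$score %||% NA), 0, peaks$score %||% 0),
                  peaks$strand)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

peaks_gr <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$contig,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = peaks$strand)
}

#' Assign peaks to transcript regions
#'
#' Each peak is labeled by the same-strand transcript region
#' (5'UTR/CDS/intron/3'UTR) with the maximal nucleotide overlap, summed over
#' the region's intervals within one transcript. Ties are broken by the
#' priority CDS > 5'UTR > 3'UTR > intron, then by the transcript with the
#' longest CDS. Peaks with no same-strand overlap of any coding transcript
#' are omitted (antisense peaks do not enter composition counts).
#'
#' @param peaks Peak data.frame (see [read_peaks()]).
#' @param regions Region table from [region_table()].
#' @return data.frame with columns `peak_id`, `label`, `transcript_id`,
#'   `overlap_nt`.
#' @export
assign_region <- function(peaks, regions) {
  if (nrow(peaks) == 0L || nrow(regions) == 0L) {
    return(data.frame(peak_id = character(), label = character(),
                      transcript_id = character(), overlap_nt = integer(),
                      stringsAsFactors = FALSE))
  }
  pg <- peaks_gr(peaks)
  rg <- GenomicRanges::GRanges(
    seqnames = regions$contig,
    ranges = IRanges::IRanges(start = regions$start + 1L,
                              end = regions$end),
    strand = regions$strand)
  hits <- GenomicRanges::findOverlaps(pg, rg, ignore.strand = FALSE)
  if (length(hits) == 0L) {
    return(data.frame(peak_id = character(), label = character(),
                      transcript_id = character(), overlap_nt = integer(),
                      stringsAsFactors = FALSE))
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(peaks$end[qi], regions$end[si]) -
    pmax(peaks$start[qi], regions$start[si])
  h <- data.frame(peak = qi, tx = regions$transcript_id[si],
                  label = regions$label[si], ov = ov,
                  stringsAsFactors = FALSE)
  agg <- stats::aggregate(ov ~ peak + tx + label, data = h, FUN = sum)
  # CDS length per transcript for the final tie-break
  cds_len <- tapply(
    ifelse(regions$label == "CDS", regions$end - regions$start, 0L),
    regions$transcript_id, sum)
  agg$cds_len <- as.integer(cds_len[agg$tx])
  prio <- c("CDS" = 1L, "5'UTR" = 2L, "3'UTR" = 3L, "intron" = 4L)
  agg$prio <- prio[agg$label]
  o <- order(agg$peak, -agg$ov, agg$prio, -agg$cds_len, agg$tx)
  agg <- agg[o, ]
  best <- agg[!duplicated(agg$peak), ]
  data.frame(peak_id = peaks$peak_id[best$peak], label = best$label,
             transcript_id = best$tx, overlap_nt = best$ov,
             stringsAsFactors = FALSE)
}

#' Region composition of peak assignments
#'
#' Percentages are taken relative to the total number of assigned peaks
#' (all rows of `assignments`), so rows carrying a label outside the four
#' standard regions still count toward the denominator.
#'
#' @param assignments Output of [assign_region()].
#' @return data.frame with columns `label`, `count`, `pct` (unrounded).
#' @export
region_composition <- function(assignments) {
  labels <- c("5'UTR", "CDS", "intron", "3'UTR")
  counts <- vapply(labels, function(l) sum(assignments$label == l),
                   integer(1))
  total <- nrow(assignments)
  data.frame(label = labels, count = counts,
             pct = if (total > 0) 100 * counts / total else rep(0, 4),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Splice-site metaprofile of binary peak coverage
#'
#' For each offset in `[-window_nt, window_nt]` relative to every splice
#' site (transcript orientation; see Details) the profile value is the
#' fraction of sites at which at least one same-strand peak covers the base
#' at that offset. Offsets beyond the end of the flanking exon or intron
#' still count in the denominator, so values are comparable across offsets.
#'
#' @details At a 5' splice site offset 0 is the first intronic base and
#'   negative offsets are exonic; at a 3' splice site offset 0 is the first
#'   base of the downstream exon and negative offsets are intronic.
#'
#' @param peaks Peak data.frame.
#' @param catalog Splice-site catalog from [splice_site_catalog()].
#' @param window_nt Window half-width in nt (default 300).
#' @return data.frame with columns `kind`, `offset`, `value`, `n_sites`.
#' @export
splice_site_metaprofile <- function(peaks, catalog, window_nt = 300L) {
  if (nrow(catalog) == 0L) stop("empty splice-site catalog")
  stopifnot(window_nt >= 1L)
  offsets <- seq(-window_nt, window_nt)
  out <- list()
  for (kind in c("5'SS", "3'SS")) {
    sites <- catalog[catalog$kind == kind, ]
    n_sites <- nrow(sites)
    acc <- numeric(length(offsets))
    if (n_sites > 0L && nrow(peaks) > 0L) {
      for (i in seq_len(n_sites)) {
        s <- sites[i, ]
        p <- peaks[peaks$contig == s$contig & peaks$strand == s$strand, ,
                   drop = FALSE]
        if (nrow(p) == 0L) next
        covered <- logical(length(offsets))
        if (s$strand == "+") {
          lo <- p$start - s$pos      # offset of first covered base
          hi <- p$end - 1L - s$pos   # offset of last covered base
        } else {
          lo <- s$pos - p$end        # pos-1-(end-1)
          hi <- s$pos - 1L - p$start
        }
        for (j in seq_along(lo)) {
          a <- max(lo[j], -window_nt); b <- min(hi[j], window_nt)
          if (a <= b) covered[(a + window_nt + 1L):(b + window_nt + 1L)] <-
              TRUE
        }
        acc <- acc + covered
      }
    }
    out[[kind]] <- data.frame(
      kind = kind, offset = offsets,
      value = if (n_sites > 0L) acc / n_sites else rep(0, length(offsets)),
      n_sites = n_sites, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scaled transcript metaprofile of binary peak coverage
#'
#' Each region class (5'UTR, CDS, intron, 3'UTR) of each coding transcript
#' is rescaled to `bins_per_region` bins in transcript orientation; a bin's
#' value is the fraction of transcripts (among those possessing the region)
#' with at least one peak-covered base mapping to the bin.
#'
#' @param peaks Peak data.frame.
#' @param db A `transcript_db`.
#' @param bins_per_region Bins per region (default 100).
#' @return data.frame with columns `region`, `bin`, `value`,
#'   `n_transcripts`.
#' @export
transcript_metaprofile <- function(peaks, db, bins_per_region = 100L) {
  stopifnot(bins_per_region >= 1L)
  labels <- c("5'UTR", "CDS", "intron", "3'UTR")
  B <- as.integer(bins_per_region)
  acc <- matrix(0, nrow = 4, ncol = B, dimnames = list(labels, NULL))
  n_tx <- stats::setNames(integer(4), labels)
  tx <- db$transcripts[db$transcripts$coding, ]
  for (i in seq_len(nrow(tx))) {
    model <- get_transcript(db, tx$transcript_id[i])
    regions <- derive_regions(model)
    p <- peaks[peaks$contig == model$contig &
                 peaks$strand == model$strand, , drop = FALSE]
    for (lab in labels) {
      r <- regions[regions$label == lab, , drop = FALSE]
      if (nrow(r) == 0L) next
      # intervals in transcript orientation
      if (model$strand == "-") r <- r[rev(seq_len(nrow(r))), , drop = FALSE]
      widths <- r$end - r$start
      L <- sum(widths)
      cum <- cumsum(c(0L, widths))
      n_tx[lab] <- n_tx[lab] + 1L
      covered_bins <- logical(B)
      if (nrow(p) > 0L) {
        for (k in seq_len(nrow(r))) {
          s <- pmax(p$start, r$start[k]); e <- pmin(p$end, r$end[k])
          keep <- e > s
          if (!any(keep)) next
          for (j in which(keep)) {
            if (model$strand == "+") {
              lo <- cum[k] + (s[j] - r$start[k])
              hi <- cum[k] + (e[j] - r$start[k]) - 1L
            } else {
              lo <- cum[k] + (r$end[k] - e[j])
              hi <- cum[k] + (r$end[k] - s[j]) - 1L
            }
            if (L >= B) {
              # base -> bin is onto every bin between the endpoints
              b1 <- (lo * B) %/% L + 1L
              b2 <- (hi * B) %/% L + 1L
              covered_bins[b1:b2] <- TRUE
            } else {
              covered_bins[(seq(lo, hi) * B) %/% L + 1L] <- TRUE
            }
          }
        }
      }
      acc[lab, ] <- acc[lab, ] + covered_bins
    }
  }
  out <- do.call(rbind, lapply(labels, function(lab) {
    data.frame(region = lab, bin = seq_len(B),
               value = if (n_tx[lab] > 0) unname(acc[lab, ]) / n_tx[lab]
                       else rep(0, B),
               n_transcripts = unname(n_tx[lab]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
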