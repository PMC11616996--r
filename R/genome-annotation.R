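# Genome sequence and transcript-structure primitives.
#
# Internal coordinate convention: 0-based, half-open, genomic. GTF input
# (1-based, closed) is converted at the boundary; BED passes through
# unchanged.

#' Read a multi-record FASTA genome
#'
#' Reads a (possibly lowercase) nucleotide FASTA into a `genome_seq` object.
#' Sequences are uppercase-normalized and IUPAC ambiguity codes other than
#' A, C, G, T are mapped to N.
#'
#' @param fasta_path Path to a FASTA file with unique record headers.
#' @return A `genome_seq` object: a list with element `contigs`, a named
#'   character vector of uppercase nucleotide strings.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtacgt"), fa)
#' g <- read_genome(fa)
#' g$contigs[["chr1"]]
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  contigs <- toupper(as.character(seqs))
  contigs <- gsub("[^ACGTN]", "N", contigs)
  if (any(nchar(contigs) == 0L)) stop("FASTA contains an empty contig")
  names(contigs) <- nm
  structure(list(contigs = contigs), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq with", length(x$contigs), "contig(s);",
      "total length", sum(nchar(x$contigs)), "nt\n")
  invisible(x)
}

#' Extract a genomic subsequence
#'
#' @param genome A `genome_seq` object.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`; minus-strand requests are
#'   reverse-complemented so the returned sequence reads in transcript
#'   orientation.
#' @return A single nucleotide string of length `end - start`.
#' @export
get_seq <- function(genome, contig, start, end, strand = "+") {
  stopifnot(inherits(genome, "genome_seq"))
  if (!contig %in% names(genome$contigs)) stop("unknown contig: ", contig)
  len <- nchar(genome$contigs[[contig]])
  if (end <= start) stop("empty or inverted interval [", start, ", ", end, ")")
  if (start < 0 || end > len) {
    stop("interval [", start, ", ", end, ") outside contig ", contig,
         " of length ", len)
  }
  s <- substr(genome$contigs[[contig]], start + 1L, end)
  if (strand == "-") s <- revcomp(s) else if (strand != "+") {
    stop("strand must be '+' or '-'")
  }
  s
}

#' Reverse-complement nucleotide strings
#'
#' @param x Character vector over the alphabet A, C, G, T, N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' GC content of nucleotide sequences
#'
#' Fraction (G + C) / (A + C + G + T); N bases are excluded from both
#' numerator and denominator.
#'
#' @param x Character vector of nonempty nucleotide strings.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
gc_content <- function(x) {
  if (any(nchar(x) == 0L)) stop("gc_content: empty sequence")
  x <- toupper(x)
  n_gc <- nchar(gsub("[^GC]", "", x))
  n_at <- nchar(gsub("[^AT]", "", x))
  denom <- n_gc + n_at
  if (any(denom == 0L)) stop("gc_content: sequence with no A/C/G/T bases")
  n_gc / denom
}

#' Construct a transcript model
#'
#' A transcript model carries the exon structure (0-based half-open genomic
#' intervals, sorted ascending regardless of strand), strand, and optional
#' CDS span of one transcript. It anchors region derivation and splice-site
#' extraction.
#'
#' @param transcript_id,gene_id,contig Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of `start`, `end` intervals.
#' @param cds Optional length-2 numeric `c(start, end)` genomic CDS span.
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, exons,
                             cds = NULL) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1L) stop("transcript needs >= 1 exon")
  if (!strand %in% c("+", "-")) stop("unknown strand: ", strand)
  if (any(exons[, "end"] <= exons[, "start"])) stop("exon with end <= start")
  o <- order(exons[, "start"])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] < exons[-nrow(exons), "end"])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    if (cds[2] <= cds[1]) stop("CDS with end <= start")
    inside <- function(p) any(p >= exons[, "start"] & p < exons[, "end"])
    if (!inside(cds[1]) || !inside(cds[2] - 1L)) {
      stop("CDS span endpoints fall outside the exon union of ",
           transcript_id)
    }
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 contig = contig, strand = strand, exons = exons, cds = cds),
            class = "transcript_model")
}

#' Read transcript models from a GTF annotation
#'
#' Parses exon and CDS features (1-based closed coordinates, converted to
#' 0-based half-open internally), merges and sorts exons per transcript, and
#' records the CDS as a genomic span (min..max of CDS features).
#'
#' @param gtf_path Path to a GTF file whose exon/CDS rows carry
#'   `gene_id` and `transcript_id` attributes.
#' @return A `transcript_db` object: a list with data.frames `transcripts`
#'   (one row per transcript: ids, contig, strand, CDS span, coding flag)
#'   and `exons` (transcript_id, start, end).
#' @export
read_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", gtf_path)
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id)) {
    stop("exon feature without transcript_id attribute")
  }
  strand_chr <- as.character(GenomicRanges::strand(ex))
  if (any(!strand_chr %in% c("+", "-"))) {
    stop("exon with unknown strand character")
  }
  exons <- data.frame(
    transcript_id = ex$transcript_id,
    gene_id = if (is.null(ex$gene_id)) NA_character_ else ex$gene_id,
    contig = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = strand_chr,
    stringsAsFactors = FALSE
  )
  exons <- exons[order(exons$transcript_id, exons$start), ]
  exons <- merge_exons(exons)

  cds_gr <- gr[gr$type == "CDS"]
  cds <- NULL
  if (length(cds_gr) > 0L) {
    cds <- data.frame(transcript_id = cds_gr$transcript_id,
                      start = GenomicRanges::start(cds_gr) - 1L,
                      end = GenomicRanges::end(cds_gr),
                      stringsAsFactors = FALSE)
    cds <- do.call(rbind, lapply(split(cds, cds$transcript_id), function(d) {
      data.frame(transcript_id = d$transcript_id[1],
                 cds_start = min(d$start), cds_end = max(d$end),
                 stringsAsFactors = FALSE)
    }))
  }

  first <- exons[!duplicated(exons$transcript_id),
                 c("transcript_id", "gene_id", "contig", "strand")]
  biotype <- rep(NA_character_, nrow(first))
  bt_col <- intersect(c("transcript_type", "transcript_biotype"),
                      names(S4Vectors::mcols(ex)))
  if (length(bt_col) > 0L) {
    bt <- S4Vectors::mcols(ex)[[bt_col[1]]]
    biotype <- bt[match(first$transcript_id, ex$transcript_id)]
  }
  tx <- first
  tx$biotype <- biotype
  if (!is.null(cds)) {
    m <- match(tx$transcript_id, cds$transcript_id)
    tx$cds_start <- cds$cds_start[m]
    tx$cds_end <- cds$cds_end[m]
  } else {
    tx$cds_start <- NA_integer_
    tx$cds_end <- NA_integer_
  }
  tx$coding <- !is.na(tx$cds_start)
  rownames(tx) <- NULL
  rownames(exons) <- NULL
  structure(list(transcripts = tx,
                 exons = exons[, c("transcript_id", "start", "end")]),
            class = "transcript_db")
}

# Merge overlapping/adjacent duplicate exon rows within each transcript.
merge_exons <- function(exons) {
  do.call(rbind, lapply(split(exons, exons$transcript_id), function(d) {
    d <- d[order(d$start), ]
    keep <- list()
    cs <- d$start[1]; ce <- d$end[1]
    if (nrow(d) > 1L) {
      for (i in 2:nrow(d)) {
        if (d$start[i] <= ce) {
          ce <- max(ce, d$end[i])
        } else {
          keep[[length(keep) + 1L]] <- c(cs, ce)
          cs <- d$start[i]; ce <- d$end[i]
        }
      }
    }
    keep[[length(keep) + 1L]] <- c(cs, ce)
    m <- do.call(rbind, keep)
    data.frame(transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
               contig = d$contig[1], start = m[, 1], end = m[, 2],
               strand = d$strand[1], stringsAsFactors = FALSE)
  }))
}

#' @export
print.transcript_db <- function(x, ...) {
  cat("transcript_db:", nrow(x$transcripts), "transcript(s),",
      nrow(x$exons), "exon(s),", sum(x$transcripts$coding), "coding\n")
  invisible(x)
}

#' Extract one transcript model from a transcript database
#'
#' @param db A `transcript_db` from [read_annotation()].
#' @param transcript_id Transcript to extract.
#' @return A `transcript_model`.
#' @export
get_transcript <- function(db, transcript_id) {
  stopifnot(inherits(db, "transcript_db"))
  i <- match(transcript_id, db$transcripts$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  t <- db$transcripts[i, ]
  ex <- db$exons[db$exons$transcript_id == transcript_id, c("start", "end")]
  cds <- if (t$coding) c(t$cds_start, t$cds_end) else NULL
  transcript_model(t$transcript_id, t$gene_id, t$contig, t$strand,
                   as.matrix(ex), cds)
}

# Intersect a sorted interval matrix with [lo, hi); returns matrix.
intersect_intervals <- function(iv, lo, hi) {
  s <- pmax(iv[, 1], lo)
  e <- pmin(iv[, 2], hi)
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

#' Derive labeled transcript regions (5'UTR / CDS / intron / 3'UTR)
#'
#' Splits a protein-coding transcript's genomic span into disjoint labeled
#' intervals: exonic sequence upstream of the CDS in transcript orientation
#' is 5'UTR, downstream is 3'UTR, exonic sequence inside the CDS span is
#' CDS, and inter-exon gaps are intron. The labeled intervals tile the
#' transcript span exactly.
#'
#' @param model A `transcript_model` with a CDS span.
#' @return A data.frame with columns `label`, `start`, `end` (0-based
#'   half-open genomic intervals) of class `region_set`, carrying the
#'   transcript id as attribute `transcript_id`.
#' @export
derive_regions <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  if (is.null(model$cds)) {
    stop("transcript ", model$transcript_id,
         " has no CDS; non-coding transcripts are excluded from region ",
         "derivation")
  }
  ex <- model$exons
  cs <- model$cds[1]; ce <- model$cds[2]
  span <- c(ex[1, 1], ex[nrow(ex), 2])

  introns <- NULL
  if (nrow(ex) > 1L) {
    introns <- cbind(start = ex[-nrow(ex), 2], end = ex[-1L, 1])
  }
  cds_iv <- intersect_intervals(ex, cs, ce)
  left_iv <- if (cs > span[1]) intersect_intervals(ex, span[1], cs) else NULL
  right_iv <- if (ce < span[2]) intersect_intervals(ex, ce, span[2]) else NULL
  if (model$strand == "+") {
    utr5 <- left_iv; utr3 <- right_iv
  } else {
    utr5 <- right_iv; utr3 <- left_iv
  }
  bind_lab <- function(iv, lab) {
    if (is.null(iv) || nrow(iv) == 0L) return(NULL)
    data.frame(label = lab, start = iv[, 1], end = iv[, 2],
               stringsAsFactors = FALSE)
  }
  out <- rbind(bind_lab(utr5, "5'UTR"), bind_lab(cds_iv, "CDS"),
               bind_lab(introns, "intron"), bind_lab(utr3, "3'UTR"))
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  attr(out, "transcript_id") <- model$transcript_id
  class(out) <- c("region_set", "data.frame")
  out
}

#' Splice-site catalog of one transcript
#'
#' For every intron the exon/intron boundary at the intron's
#' transcript-orientation start is a 5' splice site and the boundary at its
#' end a 3' splice site. Positions are half-open boundary coordinates: a
#' plus-strand intron `[b, c)` yields a 5'SS at `b` and a 3'SS at `c`; on
#' the minus strand the labels swap (5'SS at `c`, 3'SS at `b`).
#'
#' @param model A `transcript_model`.
#' @return A data.frame with columns `kind` (`"5'SS"`/`"3'SS"`), `pos`
#'   (boundary coordinate), `contig`, `strand`, `transcript_id`. Single-exon
#'   transcripts yield zero rows.
#' @export
splice_sites <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  ex <- model$exons
  empty <- data.frame(kind = character(), pos = integer(),
                      contig = character(), strand = character(),
                      transcript_id = character(), stringsAsFactors = FALSE)
  if (nrow(ex) < 2L) return(empty)
  b <- ex[-nrow(ex), 2]  # intron starts (genomic)
  c_ <- ex[-1L, 1]       # intron ends (genomic)
  if (model$strand == "+") {
    d5 <- b; d3 <- c_
  } else {
    d5 <- c_; d3 <- b
  }
  data.frame(
    kind = rep(c("5'SS", "3'SS"), each = length(b)),
    pos = c(d5, d3),
    contig = model$contig,
    strand = model$strand,
    transcript_id = model$transcript_id,
    stringsAsFactors = FALSE
  )
}

#' Splice-site catalog across a transcript database
#'
#' @param db A `transcript_db`.
#' @param coding_only Restrict to transcripts with a CDS (default `TRUE`).
#' @return Row-bound [splice_sites()] output for every transcript.
#' @export
splice_site_catalog <- function(db, coding_only = TRUE) {
  stopifnot(inherits(db, "transcript_db"))
  ids <- db$transcripts$transcript_id
  if (coding_only) ids <- ids[db$transcripts$coding]
  out <- do.call(rbind, lapply(ids, function(id) {
    splice_sites(get_transcript(db, id))
  }))
  if (is.null(out)) {
    out <- data.frame(kind = character(), pos = integer(),
                      contig = character(), strand = character(),
                      transcript_id = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Region tables for all coding transcripts
#'
#' Convenience wrapper around [derive_regions()]: one long data.frame of
#' labeled intervals for every protein-coding transcript in the database.
#'
#' @param db A `transcript_db`.
#' @return data.frame with columns `transcript_id`, `gene_id`, `contig`,
#'   `strand`, `label`, `start`, `end`.
#' @export
region_table <- function(db) {
  stopifnot(inherits(db, "transcript_db"))
  tx <- db$transcripts[db$transcripts$coding, ]
  out <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    m <- get_transcript(db, tx$transcript_id[i])
    r <- derive_regions(m)
    data.frame(transcript_id = tx$transcript_id[i], gene_id = tx$gene_id[i],
               contig = tx$contig[i], strand = tx$strand[i],
               label = r$label, start = r$start, end = r$end,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), gene_id = character(),
                      contig = character(), strand = character(),
                      label = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write transcript models to GTF
#'
#' Emits exon and CDS features (converting the internal 0-based half-open
#' intervals back to GTF's 1-based closed convention) with `gene_id`,
#' `transcript_id`, and `transcript_type` attributes.
#'
#' @param db A `transcript_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(db, path) {
  stopifnot(inherits(db, "transcript_db"))
  lines <- character(0)
  for (i in seq_len(nrow(db$transcripts))) {
    t <- db$transcripts[i, ]
    ex <- db$exons[db$exons$transcript_id == t$transcript_id, ]
    bt <- if (is.na(t$biotype)) {
      if (t$coding) "protein_coding" else "lncRNA"
    } else t$biotype
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_type "%s";',
                     t$gene_id, t$transcript_id, bt)
    lines <- c(lines, sprintf("%s\tclipsplice\texon\t%d\t%d\t.\t%s\t.\t%s",
                              t$contig, ex$start + 1L, ex$end, t$strand,
                              attrs))
    if (t$coding) {
      cds_iv <- intersect_intervals(as.matrix(ex[, c("start", "end")]),
                                    t$cds_start, t$cds_end)
      lines <- c(lines,
                 sprintf("%s\tclipsplice\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                         t$contig, cds_iv[, 1] + 1L, cds_iv[, 2], t$strand,
                         attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome to FASTA
#'
#' @param genome A `genome_seq`.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_seq"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$contigs)) {
    writeLines(paste0(">", nm), con)
    s <- genome$contigs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
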