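# Shared fixture builders: tiny genomes, transcript databases, peak frames
# and splicing-event rows constructed in code.

make_genome <- function(...) {
  contigs <- toupper(unlist(list(...)))
  structure(list(contigs = contigs), class = "genome_seq")
}

make_db <- function(models) {
  tx <- do.call(rbind, lapply(models, function(m) {
    data.frame(transcript_id = m$transcript_id, gene_id = m$gene_id,
               contig = m$contig, strand = m$strand,
               biotype = "protein_coding",
               cds_start = if (is.null(m$cds)) NA_integer_ else m$cds[1],
               cds_end = if (is.null(m$cds)) NA_integer_ else m$cds[2],
               coding = !is.null(m$cds), stringsAsFactors = FALSE)
  }))
  ex <- do.call(rbind, lapply(models, function(m) {
    data.frame(transcript_id = m$transcript_id, start = m$exons[, 1],
               end = m$exons[, 2], stringsAsFactors = FALSE)
  }))
  structure(list(transcripts = tx, exons = ex), class = "transcript_db")
}

make_peaks <- function(start, end, strand = "+", contig = "chr1",
                       condition = "c1", id = NULL) {
  n <- length(start)
  data.frame(peak_id = id %||% sprintf("p%03d", seq_len(n)),
             contig = rep_len(contig, n), start = start, end = end,
             strand = rep_len(strand, n),
             condition = rep_len(condition, n),
             score = rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_as_record <- function(event_id = 1L, gene_id = "g1",
                           event_type = "SE", contig = "chr1",
                           strand = "+", exon = c(1000L, 1100L),
                           upstream = c(500L, 600L),
                           downstream = c(1500L, 1600L),
                           delta_psi = 0.2, fdr = 0.01,
                           ijc1 = c(20L, 20L, 20L), sjc1 = c(5L, 5L, 5L),
                           ijc2 = c(20L, 20L, 20L), sjc2 = c(5L, 5L, 5L),
                           inc1 = NULL, inc2 = NULL) {
  inc1 <- inc1 %||% (ijc1 / (ijc1 + sjc1))
  inc2 <- inc2 %||% (ijc2 / (ijc2 + sjc2))
  d <- data.frame(event_id = event_id, gene_id = gene_id,
                  event_type = event_type, contig = contig,
                  strand = strand, exon_start = exon[1], exon_end = exon[2],
                  upstream_start = upstream[1], upstream_end = upstream[2],
                  downstream_start = downstream[1],
                  downstream_end = downstream[2],
                  delta_psi = delta_psi, fdr = fdr,
                  stringsAsFactors = FALSE)
  d$inc1 <- list(inc1); d$inc2 <- list(inc2)
  d$ijc1 <- list(ijc1); d$sjc1 <- list(sjc1)
  d$ijc2 <- list(ijc2); d$sjc2 <- list(sjc2)
  class(d) <- c("as_table", "data.frame")
  d
}

bind_as_records <- function(...) {
  d <- do.call(rbind, list(...))
  class(d) <- c("as_table", "data.frame")
  d
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random multi-exon transcript on a contig of given length
rand_transcript <- function(contig_len, id = "t1", contig = "chr1",
                            n_exons = sample(2:4, 1),
                            strand = sample(c("+", "-"), 1)) {
  cuts <- sort(sample(seq(2L, contig_len - 2L), 2L * n_exons))
  exons <- cbind(cuts[seq(1, length(cuts), 2)],
                 cuts[seq(2, length(cuts), 2)])
  span <- c(exons[1, 1], exons[n_exons, 2])
  cds <- c(exons[1, 1] + (exons[1, 2] - exons[1, 1]) %/% 2L,
           exons[n_exons, 1] + (exons[n_exons, 2] - exons[n_exons, 1]) %/%
             2L + 1L)
  transcript_model(id, paste0("g_", id), contig, strand, exons, cds)
}
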