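# Seeded synthetic data: toy genome + annotation, CLIP peak sets, splicing
# and expression tables, and a ground-truth manifest.
#
# Every gene has five exons on its own stretch of a single contig; exon 3 is
# the cassette exon and carries a planted class (included / skipped /
# non_differential) that controls its GC target and flanking-intron lengths.
# Planted quantities (region mixtures, significant-event counts, DE
# direction counts) are allocated by exact count; randomness enters only
# through placement and noise, so truth-recovery tests are exact wherever
# possible.
#
# One master seed drives everything. Sub-generators derive their seeds in a
# fixed documented order: genome/annotation = seed, peaks = seed + 1,
# splicing tables = seed + 2, expression tables = seed + 3.

#' Synthetic-dataset configuration
#'
#' Collects every tunable of the synthetic generator with defaults that
#' emulate the statistical structure the downstream analysis assumes: two
#' peak conditions with exonic-binding fractions of about 0.57 and 0.83,
#' CA-rich vs GA-rich planted hexamers, included-vs-skipped cassette-exon GC
#' medians of 53.4% vs 50.0%, and larger intron:exon length ratios for
#' skipped exons.
#'
#' @param seed Master integer seed (mandatory).
#' @param n_genes Number of five-exon protein-coding genes.
#' @param exon_len_range Integer range of exon lengths (nt).
#' @param class_props Named proportions of cassette classes
#'   (`included`, `skipped`, `non_differential`); allocated by exact count.
#' @param gc_targets Named per-class cassette-exon GC targets (fractions).
#' @param gc_sd Per-exon standard deviation of the GC target (fraction).
#' @param flank_exon_gc,intron_gc,background_gc GC of non-cassette exons,
#'   introns, and intergenic background.
#' @param length_ratio_targets Named list of per-class
#'   `c(upstream, downstream)` intron:exon length-ratio medians.
#' @param ratio_sdlog Log-normal spread of the length ratios.
#' @param outer_intron_range Length range of the two outer introns (nt).
#' @param intergenic_gap Gap between genes (nt).
#' @param conditions Two peak condition labels.
#' @param n_peaks Peaks generated per condition.
#' @param exonic_fraction Named per-condition fraction of peaks planted in
#'   CDS (the remainder go to introns); allocated by exact count.
#' @param hexamers Named per-condition planted hexamer.
#' @param motif_prob Per-peak probability that the condition's hexamer is
#'   written into the peak.
#' @param peak_len_range Peak length range (nt).
#' @param n_as_sig,n_as_nonsig Planted significant / non-significant
#'   splicing events per comparison.
#' @param as_type_props Named proportions of the five event types.
#' @param dpsi_range Magnitude range of planted delta-PSI for significant
#'   events.
#' @param as_noise_sd Replicate noise of inclusion levels (PSI units; 0
#'   gives noise-free tables).
#' @param n_reps Replicates per condition.
#' @param read_range Total junction reads per replicate for well-covered
#'   events.
#' @param n_de_up,n_de_down,n_de_null Planted DE direction counts.
#' @param de_lfc_range Magnitude range of significant log2 fold changes.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_genes = 70L,
                             exon_len_range = c(80L, 250L),
                             class_props = c(included = 0.3, skipped = 0.3,
                                             non_differential = 0.4),
                             gc_targets = c(included = 0.534,
                                            skipped = 0.500,
                                            non_differential = 0.512),
                             gc_sd = 0.04,
                             flank_exon_gc = 0.512,
                             intron_gc = 0.46,
                             background_gc = 0.42,
                             length_ratio_targets = list(
                               included = c(12.4, 10.6),
                               skipped = c(19.5, 20.0),
                               non_differential = c(14.2, 13.3)),
                             ratio_sdlog = 0.25,
                             outer_intron_range = c(400L, 2000L),
                             intergenic_gap = 200L,
                             conditions = c("unstim", "stim"),
                             n_peaks = 500L,
                             exonic_fraction = c(unstim = 0.569,
                                                 stim = 0.832),
                             hexamers = c(unstim = "CACACA",
                                          stim = "GAAGAA"),
                             motif_prob = 0.3,
                             peak_len_range = c(30L, 80L),
                             n_as_sig = 60L,
                             n_as_nonsig = 30L,
                             as_type_props = c(SE = 0.7, RI = 0.1,
                                               MXE = 0.1, A5SS = 0.05,
                                               A3SS = 0.05),
                             dpsi_range = c(0.08, 0.4),
                             as_noise_sd = 0.02,
                             n_reps = 3L,
                             read_range = c(15L, 200L),
                             n_de_up = 273L,
                             n_de_down = 241L,
                             n_de_null = 486L,
                             de_lfc_range = c(1, 4)) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exon_len_range = as.integer(exon_len_range),
              class_props = class_props, gc_targets = gc_targets,
              gc_sd = gc_sd, flank_exon_gc = flank_exon_gc,
              intron_gc = intron_gc, background_gc = background_gc,
              length_ratio_targets = length_ratio_targets,
              ratio_sdlog = ratio_sdlog,
              outer_intron_range = as.integer(outer_intron_range),
              intergenic_gap = as.integer(intergenic_gap),
              conditions = conditions, n_peaks = as.integer(n_peaks),
              exonic_fraction = exonic_fraction, hexamers = hexamers,
              motif_prob = motif_prob,
              peak_len_range = as.integer(peak_len_range),
              n_as_sig = as.integer(n_as_sig),
              n_as_nonsig = as.integer(n_as_nonsig),
              as_type_props = as_type_props, dpsi_range = dpsi_range,
              as_noise_sd = as_noise_sd, n_reps = as.integer(n_reps),
              read_range = as.integer(read_range),
              n_de_up = as.integer(n_de_up),
              n_de_down = as.integer(n_de_down),
              n_de_null = as.integer(n_de_null),
              de_lfc_range = de_lfc_range)
  probs <- c(cfg$class_props, cfg$as_type_props, cfg$motif_prob,
             cfg$exonic_fraction, cfg$gc_targets)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(cfg$exon_len_range < 6L) || any(cfg$outer_intron_range < 2L)) {
    stop("infeasible config: lengths too short")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# Largest-remainder allocation of n items into exact counts by proportion.
allocate_counts <- function(n, props) {
  raw <- n * props / sum(props)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

# Vectorized base drawing at a per-base GC probability.
draw_bases <- function(gc_per_base) {
  n <- length(gc_per_base)
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  ifelse(u1 < gc_per_base,
         ifelse(u2 < 0.5, "G", "C"),
         ifelse(u2 < 0.5, "A", "T"))
}

draw_seq <- function(len, gc) paste(draw_bases(rep(gc, len)), collapse = "")

clamp_gc <- function(x) pmin(pmax(x, 0.05), 0.95)

#' Simulate exon sequences for grouped GC classes
#'
#' Draws `n_per_group` exon sequences per group, each with a per-exon GC
#' target from `Normal(gc_means[g], gc_sd)` realized as an i.i.d. base
#' sequence, and reports the observed GC. This is the feature-level slice of
#' the full genome generator, used to benchmark group-comparison statistics.
#'
#' @param n_per_group Exons per group.
#' @param gc_means Named vector of group GC means (percent, e.g. 53).
#' @param gc_sd Standard deviation of per-exon GC (percent).
#' @param len_range Exon length range (nt).
#' @param seed Integer seed.
#' @return data.frame with columns `group` and `gc_pct` (observed percent).
#' @export
simulate_exon_gc_groups <- function(n_per_group, gc_means, gc_sd = 4,
                                    len_range = c(80L, 250L), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  out <- lapply(names(gc_means), function(g) {
    targets <- clamp_gc(stats::rnorm(n_per_group, gc_means[[g]], gc_sd) / 100)
    lens <- sample(seq(len_range[1], len_range[2]), n_per_group,
                   replace = TRUE)
    total <- sum(lens)
    bases <- draw_bases(rep(targets, lens))
    seqs <- vapply(split(bases, rep(seq_len(n_per_group), lens)),
                   paste, character(1), collapse = "")
    data.frame(group = g, gc_pct = 100 * gc_content(seqs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Generate a toy genome and annotation with planted cassette classes
#'
#' Builds `n_genes` five-exon protein-coding genes laid end to end on one
#' contig (alternating strands). Exon 3 of every gene is the cassette exon;
#' its class fixes its GC target and the lengths of its flanking introns.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `genome` (`genome_seq`), `annotation`
#'   (`transcript_db`) and `manifest` (a data.frame of cassette-exon truth:
#'   transcript, gene, class, GC target, coordinates, planted intron:exon
#'   length ratios).
#' @export
generate_genome_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  if (n == 0L) {
    return(list(
      genome = structure(list(contigs = c(chrS = draw_seq(
        1000L, config$background_gc))), class = "genome_seq"),
      annotation = structure(list(
        transcripts = data.frame(transcript_id = character(),
                                 gene_id = character(), contig = character(),
                                 strand = character(), biotype = character(),
                                 cds_start = integer(), cds_end = integer(),
                                 coding = logical()),
        exons = data.frame(transcript_id = character(), start = integer(),
                           end = integer())), class = "transcript_db"),
      manifest = data.frame()))
  }
  classes <- rep(names(config$class_props),
                 allocate_counts(n, config$class_props))
  classes <- sample(classes)

  pieces <- character(0)
  cursor <- 0L
  tx_rows <- vector("list", n)
  exon_rows <- vector("list", n)
  man <- vector("list", n)
  rng_len <- function(r) sample(seq(r[1], r[2]), 1L)

  for (i in seq_len(n)) {
    cls <- classes[i]
    exon_lens <- vapply(1:5, function(j) rng_len(config$exon_len_range),
                        integer(1))
    ratio_med <- config$length_ratio_targets[[cls]]
    up_ratio <- stats::rlnorm(1, log(ratio_med[1]), config$ratio_sdlog)
    down_ratio <- stats::rlnorm(1, log(ratio_med[2]), config$ratio_sdlog)
    intron_lens <- c(rng_len(config$outer_intron_range),
                     max(20L, as.integer(round(exon_lens[3] * up_ratio))),
                     max(20L, as.integer(round(exon_lens[3] * down_ratio))),
                     rng_len(config$outer_intron_range))
    strand <- if (i %% 2L == 1L) "+" else "-"
    # transcript-orientation upstream intron of the cassette is intron 2 on
    # "+" genes and intron 3 on "-" genes
    if (strand == "-") intron_lens[2:3] <- intron_lens[3:2]

    gc_exons <- clamp_gc(stats::rnorm(5, config$flank_exon_gc, config$gc_sd))
    gc_cassette <- clamp_gc(stats::rnorm(1, config$gc_targets[[cls]],
                                         config$gc_sd))
    gc_exons[3] <- gc_cassette
    gc_introns <- clamp_gc(stats::rnorm(4, config$intron_gc, config$gc_sd))

    gene_start <- cursor + config$intergenic_gap
    pieces <- c(pieces, draw_seq(config$intergenic_gap, config$background_gc))
    pos <- gene_start
    ex_iv <- matrix(0L, 5, 2)
    for (j in 1:5) {
      ex_iv[j, ] <- c(pos, pos + exon_lens[j])
      pieces <- c(pieces, draw_seq(exon_lens[j], gc_exons[j]))
      pos <- pos + exon_lens[j]
      if (j < 5) {
        pieces <- c(pieces, draw_seq(intron_lens[j], gc_introns[j]))
        pos <- pos + intron_lens[j]
      }
    }
    cursor <- pos
    gid <- sprintf("gene%04d", i)
    tid <- sprintf("tx%04d", i)
    cds_start <- ex_iv[1, 1] + exon_lens[1] %/% 2L
    cds_end <- ex_iv[5, 1] + (exon_lens[5] + 1L) %/% 2L
    tx_rows[[i]] <- data.frame(transcript_id = tid, gene_id = gid,
                               contig = "chrS", strand = strand,
                               biotype = "protein_coding",
                               cds_start = cds_start, cds_end = cds_end,
                               coding = TRUE, stringsAsFactors = FALSE)
    exon_rows[[i]] <- data.frame(transcript_id = tid, start = ex_iv[, 1],
                                 end = ex_iv[, 2], stringsAsFactors = FALSE)
    up_intron_len <- if (strand == "+") intron_lens[2] else intron_lens[3]
    down_intron_len <- if (strand == "+") intron_lens[3] else intron_lens[2]
    man[[i]] <- data.frame(
      transcript_id = tid, gene_id = gid, class = cls,
      gc_target = gc_cassette, exon_start = ex_iv[3, 1],
      exon_end = ex_iv[3, 2], strand = strand,
      up_intron_len = up_intron_len, down_intron_len = down_intron_len,
      stringsAsFactors = FALSE)
  }
  pieces <- c(pieces, draw_seq(config$intergenic_gap, config$background_gc))
  genome <- structure(list(contigs = c(chrS = paste(pieces, collapse = ""))),
                      class = "genome_seq")
  annotation <- structure(list(transcripts = do.call(rbind, tx_rows),
                               exons = do.call(rbind, exon_rows)),
                          class = "transcript_db")
  list(genome = genome, annotation = annotation,
       manifest = do.call(rbind, man))
}

replace_substr <- function(s, at, repl) {
  # at is 0-based
  paste0(substr(s, 1L, at), repl, substr(s, at + nchar(repl) + 1L, nchar(s)))
}

#' Generate CLIP peak sets with planted region labels and motifs
#'
#' Places `n_peaks` peaks per condition wholly inside CDS or intron
#' intervals of the annotation. The CDS:intron mixture follows the
#' per-condition `exonic_fraction` by exact count; the condition's hexamer
#' is written into the genome at a uniform offset inside each selected peak
#' (in transcript orientation) with probability `motif_prob`.
#'
#' @param config A [synthetic_config()].
#' @param genome A `genome_seq` (will be returned with motifs planted).
#' @param annotation A `transcript_db`.
#' @return A list with `peaks` (data.frame: peak_id, contig, start, end,
#'   strand, condition), `genome` (motif-carrying copy), and `manifest`
#'   (per-peak truth: condition, planted region label, planted motif or NA).
#' @export
generate_peaks <- function(config, genome, annotation) {
  stopifnot(inherits(config, "synthetic_config"))
  if (nrow(annotation$transcripts) == 0L) stop("empty annotation")
  set.seed(config$seed + 1L)
  regions <- region_table(annotation)
  out_peaks <- list()
  out_man <- list()
  k <- 0L
  # registry of already-written motif windows; a new hexamer is only
  # written where it cannot overwrite (or be overwritten by) another
  planted_iv <- matrix(integer(0), ncol = 2)
  for (cond in config$conditions) {
    n <- config$n_peaks
    n_ex <- as.integer(round(config$exonic_fraction[[cond]] * n))
    labels <- sample(c(rep("CDS", n_ex), rep("intron", n - n_ex)))
    motif <- config$hexamers[[cond]]
    planted <- stats::runif(n) < config$motif_prob
    for (i in seq_len(n)) {
      len <- sample(seq(config$peak_len_range[1], config$peak_len_range[2]),
                    1L)
      cand <- regions[regions$label == labels[i] &
                        (regions$end - regions$start) >= len, ]
      if (nrow(cand) == 0L) {
        stop("requested peak longer than any available ", labels[i],
             " region")
      }
      r <- cand[sample.int(nrow(cand), 1L), ]
      start <- r$start + sample.int(r$end - r$start - len + 1L, 1L) - 1L
      k <- k + 1L
      pid <- sprintf("peak%05d", k)
      out_peaks[[k]] <- data.frame(peak_id = pid, contig = r$contig,
                                   start = start, end = start + len,
                                   strand = r$strand, condition = cond,
                                   stringsAsFactors = FALSE)
      pm <- NA_character_
      if (planted[i]) {
        w <- nchar(motif)
        for (try in 1:50) {
          off <- sample.int(len - w + 1L, 1L) - 1L
          a <- start + off; b <- a + w
          clash <- nrow(planted_iv) > 0L &&
            any(planted_iv[, 1] < b & planted_iv[, 2] > a)
          if (!clash) {
            pm <- motif
            ins <- if (r$strand == "+") motif else revcomp(motif)
            genome$contigs[[r$contig]] <- replace_substr(
              genome$contigs[[r$contig]], a, ins)
            planted_iv <- rbind(planted_iv, c(a, b))
            break
          }
        }
      }
      out_man[[k]] <- data.frame(peak_id = pid, condition = cond,
                                 region = labels[i], motif = pm,
                                 transcript_id = r$transcript_id,
                                 stringsAsFactors = FALSE)
    }
  }
  list(peaks = do.call(rbind, out_peaks), genome = genome,
       manifest = do.call(rbind, out_man))
}

#' Generate a splicing event table in the rMATS tab-separated dialect
#'
#' Builds planted-significant and planted-non-significant events across the
#' five event types. Skipped-exon events are anchored on cassette exons of
#' the matching class (`included` hosts positive delta-PSI, `skipped`
#' negative, `non_differential` hosts non-significant events); the other
#' types borrow flanking internal exons as coordinates. Non-significant
#' events fail exactly one filter each, cycling over high FDR, small
#' |delta-PSI|, and a sub-threshold read count.
#'
#' @param config A [synthetic_config()].
#' @param annotation A `transcript_db` from [generate_genome_annotation()].
#' @param exon_manifest Cassette-exon manifest from the same call.
#' @param seed_offset Added to `config$seed + 2` so several comparisons can
#'   be drawn from one config (default 0).
#' @param sig_frac Fraction of each significant-class host pool used
#'   (seeded subset; default 1).
#' @return A list with `events` (the table, one row per event) and
#'   `manifest` (event_id, type, planted_sig, fail_mode, class).
#' @export
generate_as_table <- function(config, annotation, exon_manifest,
                              seed_offset = 0L, sig_frac = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L + as.integer(seed_offset))
  types <- names(config$as_type_props)
  n_sig_type <- allocate_counts(config$n_as_sig, config$as_type_props)
  n_non_type <- allocate_counts(config$n_as_nonsig, config$as_type_props)

  inc_hosts <- exon_manifest[exon_manifest$class == "included", ]
  skp_hosts <- exon_manifest[exon_manifest$class == "skipped", ]
  nd_hosts <- exon_manifest[exon_manifest$class == "non_differential", ]
  if (sig_frac < 1) {
    take <- function(d) d[sample.int(nrow(d), ceiling(sig_frac * nrow(d))), ]
    inc_hosts <- take(inc_hosts); skp_hosts <- take(skp_hosts)
  }
  # cap the significant skipped-exon demand at the available host pool
  # (relevant when sig_frac < 1 shrinks the pools for a second comparison)
  n_se_sig <- min(n_sig_type[["SE"]],
                  nrow(inc_hosts) + nrow(skp_hosts))
  if (sig_frac >= 1 && n_se_sig < n_sig_type[["SE"]]) {
    stop("infeasible config: not enough cassette exons for requested events")
  }
  n_pos <- min(n_se_sig %/% 2L + n_se_sig %% 2L, nrow(inc_hosts))
  n_neg <- n_se_sig - n_pos
  if (n_neg > nrow(skp_hosts)) {
    n_neg <- nrow(skp_hosts)
    n_pos <- n_se_sig - n_neg
  }
  if (n_non_type[["SE"]] > nrow(nd_hosts)) {
    stop("infeasible config: not enough cassette exons for requested events")
  }
  exons_of <- function(tid) {
    annotation$exons[annotation$exons$transcript_id == tid, ]
  }
  tx_of <- function(tid) {
    annotation$transcripts[
      annotation$transcripts$transcript_id == tid, ]
  }

  rows <- list(); man <- list(); eid <- 0L
  mk_event <- function(type, host, exon_idx, sig, sign, fail_mode) {
    eid <<- eid + 1L
    ex <- exons_of(host)
    t <- tx_of(host)
    # transcript-orientation flanks
    if (t$strand == "+") {
      up <- ex[exon_idx - 1L, ]; down <- ex[exon_idx + 1L, ]
    } else {
      up <- ex[exon_idx + 1L, ]; down <- ex[exon_idx - 1L, ]
    }
    dpsi_mag <- stats::runif(1, config$dpsi_range[1], config$dpsi_range[2])
    reads_lo <- FALSE
    if (sig) {
      dpsi <- sign * dpsi_mag
      fdr <- stats::runif(1, 0, 0.049)
    } else {
      if (fail_mode == "fdr") {
        dpsi <- sample(c(-1, 1), 1) * dpsi_mag
        fdr <- stats::runif(1, 0.051, 1)
      } else if (fail_mode == "dpsi") {
        dpsi <- sample(c(-1, 1), 1) * stats::runif(1, 0, 0.049)
        fdr <- stats::runif(1, 0, 0.049)
      } else {
        dpsi <- sample(c(-1, 1), 1) * dpsi_mag
        fdr <- stats::runif(1, 0, 0.049)
        reads_lo <- TRUE
      }
    }
    base <- stats::runif(1, 0.25 + max(0, -dpsi), 0.75 - max(0, dpsi))
    psi1 <- pmin(pmax(base + dpsi +
                        stats::rnorm(config$n_reps, 0, config$as_noise_sd),
                      0), 1)
    psi2 <- pmin(pmax(base +
                        stats::rnorm(config$n_reps, 0, config$as_noise_sd),
                      0), 1)
    tot <- function() {
      if (reads_lo) sample(1:3, config$n_reps, replace = TRUE)
      else sample(seq(config$read_range[1], config$read_range[2]),
                  config$n_reps, replace = TRUE)
    }
    t1 <- tot(); t2 <- tot()
    ijc1 <- as.integer(round(psi1 * t1)); sjc1 <- t1 - ijc1
    ijc2 <- as.integer(round(psi2 * t2)); sjc2 <- t2 - ijc2
    rows[[eid]] <<- data.frame(
      ID = eid, GeneID = t$gene_id, geneSymbol = t$gene_id,
      chr = t$contig, strand = t$strand,
      exonStart_0base = ex[exon_idx, "start"],
      exonEnd = ex[exon_idx, "end"],
      upstreamES = up$start, upstreamEE = up$end,
      downstreamES = down$start, downstreamEE = down$end,
      event_type = type,
      IJC_SAMPLE_1 = paste(ijc1, collapse = ","),
      SJC_SAMPLE_1 = paste(sjc1, collapse = ","),
      IJC_SAMPLE_2 = paste(ijc2, collapse = ","),
      SJC_SAMPLE_2 = paste(sjc2, collapse = ","),
      IncFormLen = ex[exon_idx, "end"] - ex[exon_idx, "start"] + 98L,
      SkipFormLen = 98L,
      PValue = fdr / 2, FDR = fdr,
      IncLevel1 = paste(sprintf("%.6f", psi1), collapse = ","),
      IncLevel2 = paste(sprintf("%.6f", psi2), collapse = ","),
      IncLevelDifference = round(dpsi, 6),
      stringsAsFactors = FALSE)
    man[[eid]] <<- data.frame(
      event_id = eid, event_type = type, planted_sig = sig,
      fail_mode = if (sig) NA_character_ else fail_mode,
      class = if (sig) { if (sign > 0) "included" else "skipped" }
              else "non_differential",
      transcript_id = host, stringsAsFactors = FALSE)
  }

  fail_modes <- c("fdr", "dpsi", "reads")
  fm_i <- 0L
  next_fail <- function() {
    fm_i <<- fm_i + 1L
    fail_modes[(fm_i - 1L) %% 3L + 1L]
  }
  # SE events on cassette exons
  pos_hosts <- inc_hosts$transcript_id[seq_len(n_pos)]
  neg_hosts <- skp_hosts$transcript_id[seq_len(n_neg)]
  for (h in pos_hosts) mk_event("SE", h, 3L, TRUE, 1, NA)
  for (h in neg_hosts) mk_event("SE", h, 3L, TRUE, -1, NA)
  for (h in nd_hosts$transcript_id[seq_len(n_non_type[["SE"]])]) {
    mk_event("SE", h, 3L, FALSE, 0, next_fail())
  }
  # other event types borrow internal exons 2 and 4 as coordinates
  all_tx <- annotation$transcripts$transcript_id
  cyc <- 0L
  next_host <- function() {
    cyc <<- cyc + 1L
    list(tid = all_tx[(cyc - 1L) %% length(all_tx) + 1L],
         idx = if ((cyc %/% length(all_tx)) %% 2L == 0L) 2L else 4L)
  }
  for (type in setdiff(types, "SE")) {
    for (j in seq_len(n_sig_type[[type]])) {
      h <- next_host()
      mk_event(type, h$tid, h$idx, TRUE, sample(c(-1, 1), 1), NA)
    }
    for (j in seq_len(n_non_type[[type]])) {
      h <- next_host()
      mk_event(type, h$tid, h$idx, FALSE, 0, next_fail())
    }
  }
  list(events = do.call(rbind, rows), manifest = do.call(rbind, man))
}

#' Generate a differential-expression table with planted directions
#'
#' @param config A [synthetic_config()].
#' @param gene_ids Optional gene identifiers to use (recycled from the
#'   annotation in pipeline runs); synthesized when absent or too few.
#' @param seed_offset Added to `config$seed + 3`.
#' @return A list with `table` (gene_id, log2FoldChange, padj) and
#'   `manifest` (gene_id, direction in up/down/null).
#' @export
generate_de_table <- function(config, gene_ids = NULL, seed_offset = 0L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 3L + as.integer(seed_offset))
  n <- config$n_de_up + config$n_de_down + config$n_de_null
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("deg%05d", seq_len(n))
  } else if (length(gene_ids) < n) {
    gene_ids <- c(gene_ids, sprintf("deg%05d", seq_len(n - length(gene_ids))))
  } else {
    gene_ids <- gene_ids[seq_len(n)]
  }
  dir <- sample(rep(c("up", "down", "null"),
                    c(config$n_de_up, config$n_de_down, config$n_de_null)))
  lfc_mag <- stats::runif(n, config$de_lfc_range[1], config$de_lfc_range[2])
  lfc <- ifelse(dir == "up", lfc_mag, ifelse(dir == "down", -lfc_mag, 0))
  padj <- stats::runif(n, 0, 0.049)
  # null genes fail exactly one predicate each, alternating
  null_i <- which(dir == "null")
  half <- null_i[seq_along(null_i) %% 2L == 0L]
  other <- setdiff(null_i, half)
  padj[half] <- stats::runif(length(half), 0.05, 1)
  lfc[half] <- sample(c(-1, 1), length(half), TRUE) *
    stats::runif(length(half), 1, 3)
  lfc[other] <- sample(c(-1, 1), length(other), TRUE) *
    stats::runif(length(other), 0, 0.99)
  list(table = data.frame(gene_id = gene_ids, log2FoldChange = lfc,
                          padj = padj, stringsAsFactors = FALSE),
       manifest = data.frame(gene_id = gene_ids, direction = dir,
                             stringsAsFactors = FALSE))
}

#' Generate a complete synthetic dataset
#'
#' Runs all generators in their documented seed order and returns the
#' full bundle: genome (with planted motifs), annotation, both peak
#' conditions, two splicing comparisons, two expression comparisons, and
#' the combined truth manifest.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_dataset`.
#' @export
generate_dataset <- function(config) {
  ga <- generate_genome_annotation(config)
  pk <- generate_peaks(config, ga$genome, ga$annotation)
  as1 <- generate_as_table(config, ga$annotation, ga$manifest,
                           seed_offset = 0L)
  as2 <- generate_as_table(config, ga$annotation, ga$manifest,
                           seed_offset = 10L, sig_frac = 0.6)
  gene_ids <- ga$annotation$transcripts$gene_id
  de1 <- generate_de_table(config, gene_ids, seed_offset = 0L)
  de2 <- generate_de_table(config, gene_ids, seed_offset = 10L)
  structure(list(
    config = config,
    genome = pk$genome,
    annotation = ga$annotation,
    peaks = pk$peaks,
    as_tables = list(comparison1 = as1$events, comparison2 = as2$events),
    de_tables = list(comparison1 = de1$table, comparison2 = de2$table),
    manifest = list(exons = ga$manifest, peaks = pk$manifest,
                    as_events = list(comparison1 = as1$manifest,
                                     comparison2 = as2$manifest),
                    de_genes = list(comparison1 = de1$manifest,
                                    comparison2 = de2$manifest))),
    class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits FASTA, GTF, one BED per peak condition, rMATS-dialect splicing
#' TSVs, expression TSVs, and a JSON truth manifest.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.gtf"),
             truth = file.path(dir, "truth.json"))
  write_fasta(dataset$genome, paths[["genome"]])
  write_gtf(dataset$annotation, paths[["annotation"]])
  for (cond in unique(dataset$peaks$condition)) {
    p <- file.path(dir, paste0("peaks_", cond, ".bed"))
    write_bed(dataset$peaks[dataset$peaks$condition == cond, ], p)
    paths[[paste0("peaks_", cond)]] <- p
  }
  for (nm in names(dataset$as_tables)) {
    p <- file.path(dir, paste0("as_", nm, ".tsv"))
    utils::write.table(dataset$as_tables[[nm]], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[[paste0("as_", nm)]] <- p
  }
  for (nm in names(dataset$de_tables)) {
    p <- file.path(dir, paste0("de_", nm, ".tsv"))
    utils::write.table(dataset$de_tables[[nm]], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[[paste0("de_", nm)]] <- p
  }
  jsonlite::write_json(dataset$manifest, paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
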