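# End-to-end orchestration: filter -> annotate -> metaprofile -> motifs ->
# features -> integrate, from real input files or from the seeded
# synthetic generator, with a machine-readable report.

#' Pipeline configuration
#'
#' Exactly one of `synthetic` (a [synthetic_config()]) or `inputs` must be
#' given. `inputs` is a list of file paths: `genome` (FASTA), `annotation`
#' (GTF), `peaks` (named character vector of BED paths, one per
#' condition), `as_tables` and `de_tables` (named vectors of TSV paths,
#' one per comparison; both optional).
#'
#' @param synthetic A [synthetic_config()], or `NULL`.
#' @param inputs Input-path list, or `NULL`.
#' @param outdir Output directory.
#' @param padj_max,min_abs_fc DE filter thresholds.
#' @param fdr_max,min_abs_dpsi,min_reads Splicing filter thresholds.
#' @param flank_nt High-confidence overlap flank (nt).
#' @param k Motif word length.
#' @param window_nt Splice-site metaprofile half-window (nt).
#' @param bins_per_region Transcript metaprofile bins.
#' @param seed Seed for the motif background shuffle (and, in synthetic
#'   mode, defaulting from the synthetic config).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL,
                            outdir = tempfile("clipsplice_run"),
                            padj_max = 0.05, min_abs_fc = 2,
                            fdr_max = 0.05, min_abs_dpsi = 0.05,
                            min_reads = 10, flank_nt = 250L, k = 6L,
                            window_nt = 300L, bins_per_region = 100L,
                            seed = NULL) {
  if (is.null(synthetic) == is.null(inputs)) {
    stop("exactly one of synthetic / inputs must be given")
  }
  if (is.null(seed)) {
    seed <- if (!is.null(synthetic)) synthetic$seed else 1L
  }
  thresholds <- c(padj_max = padj_max, min_abs_fc = min_abs_fc,
                  fdr_max = fdr_max, min_abs_dpsi = min_abs_dpsi,
                  min_reads = min_reads, flank_nt = flank_nt, k = k,
                  window_nt = window_nt, bins_per_region = bins_per_region)
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  structure(list(synthetic = synthetic, inputs = inputs, outdir = outdir,
                 padj_max = padj_max, min_abs_fc = min_abs_fc,
                 fdr_max = fdr_max, min_abs_dpsi = min_abs_dpsi,
                 min_reads = min_reads, flank_nt = as.integer(flank_nt),
                 k = as.integer(k), window_nt = as.integer(window_nt),
                 bins_per_region = as.integer(bins_per_region),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

as_table_flat <- function(events) {
  d <- events
  for (col in c("inc1", "inc2", "ijc1", "sjc1", "ijc2", "sjc2")) {
    if (col %in% names(d)) {
      d[[col]] <- vapply(d[[col]], paste, character(1), collapse = ",")
    }
  }
  as.data.frame(d)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    ds <- generate_dataset(config$synthetic)
    peaks_by_cond <- split(ds$peaks, ds$peaks$condition)
    peaks_by_cond <- peaks_by_cond[unique(ds$peaks$condition)]
    # round-trip splicing tables through the dialect reader so synthetic
    # and real inputs enter the stages identically
    as_tables <- lapply(ds$as_tables, function(tab) {
      p <- tempfile(fileext = ".tsv")
      utils::write.table(tab, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      on.exit(unlink(p))
      read_as_table(p)
    })
    de_tables <- lapply(ds$de_tables, function(tab) {
      data.frame(gene_id = tab$gene_id, log2fc = tab$log2FoldChange,
                 padj = tab$padj, stringsAsFactors = FALSE)
    })
    list(genome = ds$genome, annotation = ds$annotation,
         peaks = peaks_by_cond, as_tables = as_tables,
         de_tables = de_tables, manifest = ds$manifest)
  } else {
    inp <- config$inputs
    peaks <- lapply(names(inp$peaks), function(cond) {
      read_peaks(inp$peaks[[cond]], condition = cond)
    })
    names(peaks) <- names(inp$peaks)
    list(genome = read_genome(inp$genome),
         annotation = read_annotation(inp$annotation),
         peaks = peaks,
         as_tables = lapply(inp$as_tables %||% character(0), read_as_table),
         de_tables = lapply(inp$de_tables %||% character(0), read_de_table),
         manifest = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (filter, annotate, metaprofile, motifs,
#' features, integrate), writing each stage's tables before the next stage
#' begins. Stages that lack their inputs (e.g. no peak files) are skipped
#' with a logged notice. A run with an identical configuration and seed
#' reproduces a byte-identical report.
#'
#' @param config A [pipeline_config()].
#' @return The analysis report (a nested list), invisibly; also written as
#'   `report.json` in `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[clipsplice] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inp <- stage("load", load_pipeline_inputs(config))
  report <- list(provenance = list(
    seed = config$seed,
    mode = if (is.null(config$synthetic)) "files" else "synthetic",
    thresholds = list(padj_max = config$padj_max,
                      min_abs_fc = config$min_abs_fc,
                      fdr_max = config$fdr_max,
                      min_abs_dpsi = config$min_abs_dpsi,
                      min_reads = config$min_reads,
                      flank_nt = config$flank_nt, k = config$k,
                      window_nt = config$window_nt,
                      bins_per_region = config$bins_per_region)))

  # -- filter ---------------------------------------------------------
  filtered <- stage("filter", {
    de_sig <- lapply(inp$de_tables, filter_de, padj_max = config$padj_max,
                     min_abs_fc = config$min_abs_fc)
    as_sig <- lapply(inp$as_tables, filter_as, fdr_max = config$fdr_max,
                     min_abs_dpsi = config$min_abs_dpsi,
                     min_reads = config$min_reads)
    for (nm in names(de_sig)) {
      utils::write.table(de_sig[[nm]],
                         file.path(config$outdir,
                                   paste0("filtered_de_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (nm in names(as_sig)) {
      utils::write.table(as_table_flat(as_sig[[nm]]),
                         file.path(config$outdir,
                                   paste0("filtered_as_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(de = de_sig, as_ = as_sig)
  })
  report$filter <- list(
    n_de_significant = lapply(filtered$de, nrow),
    n_as_significant = lapply(filtered$as_, nrow),
    event_composition = lapply(filtered$as_, function(e) {
      comp <- event_type_composition(e)
      list(counts = as.list(comp$counts),
           se_sign = as.list(comp$se_sign))
    }))
  if (length(filtered$de) >= 2L) {
    s <- overlap_summary(filtered$de[[1]], filtered$de[[2]])
    report$filter$de_overlap <- unclass(s)
  }
  if (length(filtered$as_) >= 2L) {
    s <- overlap_summary(filtered$as_[[1]], filtered$as_[[2]],
                         key = "event_key", direction = "delta_psi")
    report$filter$as_overlap <- unclass(s)
  }

  have_peaks <- length(inp$peaks) > 0L
  if (!have_peaks) {
    message("[clipsplice] no peak inputs; peak stages skipped")
    report$peaks <- "skipped (no peak inputs)"
  }

  # -- annotate -------------------------------------------------------
  if (have_peaks) {
    regions <- stage("annotate", region_table(inp$annotation))
    assignments <- stage("annotate", {
      a <- lapply(inp$peaks, assign_region, regions = regions)
      all_a <- do.call(rbind, Map(function(d, cond) {
        if (nrow(d) > 0L) d$condition <- cond
        d
      }, a, names(a)))
      utils::write.table(all_a,
                         file.path(config$outdir, "region_assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      a
    })
    report$region_composition <- lapply(assignments, function(a) {
      comp <- region_composition(a)
      stats::setNames(as.list(comp$pct), comp$label)
    })

    # -- metaprofile --------------------------------------------------
    catalog <- splice_site_catalog(inp$annotation)
    profiles <- stage("metaprofile", {
      pr <- lapply(inp$peaks, splice_site_metaprofile, catalog = catalog,
                   window_nt = config$window_nt)
      tp <- lapply(inp$peaks, transcript_metaprofile, db = inp$annotation,
                   bins_per_region = config$bins_per_region)
      for (nm in names(pr)) {
        utils::write.table(pr[[nm]],
                           file.path(config$outdir,
                                     paste0("splice_site_profile_", nm,
                                            ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(tp[[nm]],
                           file.path(config$outdir,
                                     paste0("transcript_profile_", nm,
                                            ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      list(splice_site = pr, transcript = tp)
    })
    report$metaprofile <- lapply(names(profiles$splice_site), function(nm) {
      pr <- profiles$splice_site[[nm]]
      list(condition = nm,
           mean_coverage_5ss = mean(pr$value[pr$kind == "5'SS"]),
           mean_coverage_3ss = mean(pr$value[pr$kind == "3'SS"]))
    })

    # -- motifs -------------------------------------------------------
    motifs <- stage("motifs", {
      m <- lapply(names(inp$peaks), function(cond) {
        peak_motif_enrichment(inp$peaks[[cond]], inp$genome, k = config$k,
                              seed = config$seed)
      })
      names(m) <- names(inp$peaks)
      for (nm in names(m)) {
        utils::write.table(m[[nm]],
                           file.path(config$outdir,
                                     paste0("motifs_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      m
    })
    report$motifs <- lapply(motifs, function(m) {
      top <- utils::head(m, 3L)
      lapply(seq_len(nrow(top)), function(i) {
        list(kmer = top$kmer[i], t = top$t[i], p = top$p[i])
      })
    })
  }

  # -- features -------------------------------------------------------
  if (length(inp$as_tables) > 0L) {
    features <- stage("features", {
      tab <- inp$as_tables[[1]]
      sig <- filtered$as_[[1]]
      se <- tab[tab$event_type == "SE", , drop = FALSE]
      grp <- ifelse(se$event_id %in% sig$event_id,
                    ifelse(se$delta_psi > 0, "included", "skipped"),
                    "non_differential")
      f <- compute_features(se, inp$genome, group = grp)
      utils::write.table(f, file.path(config$outdir, "exon_features.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      f
    })
    feats <- c("exon_gc", "down_intron_to_exon_gc_ratio",
               "up_intron_to_exon_length_ratio",
               "down_intron_to_exon_length_ratio")
    report$features <- lapply(feats, function(ft) {
      cmp <- compare_feature_groups(features, ft, "included", "skipped")
      cmp
    })
  }

  # -- integrate ------------------------------------------------------
  if (have_peaks && length(inp$as_tables) > 0L) {
    integ <- stage("integrate", {
      conds <- names(inp$peaks)
      uniq <- if (length(conds) >= 2L) {
        condition_unique_peaks(inp$peaks[[1]], inp$peaks[[2]])
      } else {
        list(unique_a = inp$peaks[[1]],
             unique_b = inp$peaks[[1]][0, , drop = FALSE])
      }
      uniq_all <- rbind(uniq$unique_a, uniq$unique_b)
      sig <- filtered$as_[[1]]
      hits <- highconf_overlap(uniq_all,
                               sig[sig$event_type == "SE", , drop = FALSE],
                               flank_nt = config$flank_nt)
      utils::write.table(hits,
                         file.path(config$outdir, "highconf_hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      de_genes <- if (length(filtered$de) > 0L)
        filtered$de[[1]]$gene_id else character(0)
      as_genes <- sig$gene_id
      peak_tx <- assign_region(uniq_all, region_table(inp$annotation))
      tx2gene <- inp$annotation$transcripts
      peak_genes <- tx2gene$gene_id[match(peak_tx$transcript_id,
                                          tx2gene$transcript_id)]
      crossref <- three_way_crossref(de_genes, as_genes, peak_genes)
      list(n_unique_a = nrow(uniq$unique_a),
           n_unique_b = nrow(uniq$unique_b), n_hits = nrow(hits),
           n_hit_events = length(unique(hits$event_id)),
           crossref = list(n_de = crossref$n_de, n_as = crossref$n_as,
                           n_peak = crossref$n_peak,
                           cells = as.list(crossref$cells),
                           pct_de_with_peak = crossref$pct_de_with_peak,
                           pct_as_with_peak = crossref$pct_as_with_peak))
    })
    report$integration <- integ
  }

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
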