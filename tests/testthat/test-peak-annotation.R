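# one plus-strand transcript: exons [0,100)+[200,300), CDS 50..250
toy_regions <- function(strand = "+") {
  m <- transcript_model("t1", "g1", "chr1", strand,
                        rbind(c(0L, 100L), c(200L, 300L)), c(50L, 250L))
  r <- derive_regions(m)
  data.frame(transcript_id = "t1", gene_id = "g1", contig = "chr1",
             strand = strand, label = r$label, start = r$start,
             end = r$end, stringsAsFactors = FALSE)
}

test_that("peaks take the label of their maximal-overlap region", {
  regions <- toy_regions()
  inside_cds <- make_peaks(60L, 90L)
  expect_equal(assign_region(inside_cds, regions)$label, "CDS")

  straddle <- make_peaks(70L, 170L)  # 30 nt CDS, 70 nt intron
  a <- assign_region(straddle, regions)
  expect_equal(a$label, "intron")
  expect_equal(a$overlap_nt, 70L)

  tie <- make_peaks(50L, 150L)       # 50 nt CDS, 50 nt intron
  expect_equal(assign_region(tie, regions)$label, "CDS")

  antisense <- make_peaks(60L, 90L, strand = "-")
  expect_equal(nrow(assign_region(antisense, regions)), 0L)
})

test_that("region assignment matches the per-base oracle on random cases", {
  set.seed(61)
  for (i in 1:40) {
    models <- lapply(1:2, function(k) {
      rand_transcript(600L, id = paste0("t", k))
    })
    db <- make_db(models)
    regions <- region_table(db)
    s <- sample(0:560, 1)
    peak <- make_peaks(s, s + sample(10:40, 1),
                       strand = sample(c("+", "-"), 1))
    got <- assign_region(peak, regions)
    want <- oracle_assign_region(peak[1, ], regions)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$label, want$label)
      expect_equal(got$overlap_nt, want$ov)
      expect_equal(got$transcript_id, want$transcript_id)
    }
  }
})

test_that("region composition reproduces printed-count percentages", {
  counts <- c("CDS" = 3727L, "intron" = 1690L, "5'UTR" = 768L,
              "3'UTR" = 367L)
  a <- data.frame(peak_id = sprintf("p%d", seq_len(sum(counts))),
                  label = rep(names(counts), counts))
  comp <- region_composition(a)
  pct <- setNames(comp$pct, comp$label)
  expect_equal(round(pct[["CDS"]], 1), 56.9)
  expect_equal(round(pct[["intron"]], 1), 25.8)
  expect_equal(round(pct[["5'UTR"]], 1), 11.7)
  expect_equal(round(pct[["3'UTR"]], 2), 5.60)
  expect_equal(sum(comp$pct), 100)

  single <- data.frame(peak_id = "p1", label = "CDS")
  expect_equal(region_composition(single)$pct[2], 100)
})

test_that("splice-site profiles place coverage at the documented offsets", {
  m <- transcript_model("t1", "g1", "chr1", "+",
                        rbind(c(0L, 100L), c(200L, 300L)), c(50L, 250L))
  catalog <- splice_sites(m)
  none <- splice_site_metaprofile(make_peaks(integer(0), integer(0)),
                                  catalog, window_nt = 20L)
  expect_true(all(none$value == 0))

  # peak covering bases 90..99 = offsets -10..-1 of the 5'SS at 100
  p <- make_peaks(90L, 100L)
  prof <- splice_site_metaprofile(p, catalog, window_nt = 20L)
  p5 <- prof[prof$kind == "5'SS", ]
  expect_equal(p5$value[p5$offset %in% -10:-1], rep(1, 10))
  expect_equal(sum(p5$value), 10)
  # same bases sit at offsets -110..-101 of the 3'SS at 200: outside window
  p3 <- prof[prof$kind == "3'SS", ]
  expect_equal(sum(p3$value), 0)

  expect_error(splice_site_metaprofile(p, catalog[0, ], 20L), "empty")
})

test_that("minus-strand profiles mirror plus-strand geometry", {
  mp <- transcript_model("t1", "g1", "chr1", "-",
                         rbind(c(0L, 100L), c(200L, 300L)), c(50L, 250L))
  catalog <- splice_sites(mp)
  # 5'SS at boundary 200; first intronic base (transcript orientation) is
  # 199, i.e. offset 0; exonic offsets -1.. are bases 200, 201, ...
  p <- make_peaks(200L, 210L, strand = "-")
  prof <- splice_site_metaprofile(p, catalog, window_nt = 20L)
  p5 <- prof[prof$kind == "5'SS", ]
  expect_equal(p5$value[p5$offset %in% -10:-1], rep(1, 10))
  expect_equal(sum(p5$value), 10)
})

test_that("splice-site profiles match the per-base oracle on random cases", {
  set.seed(62)
  for (i in 1:15) {
    models <- lapply(1:2, function(k) {
      rand_transcript(500L, id = paste0("t", k), n_exons = sample(2:3, 1))
    })
    db <- make_db(models)
    catalog <- splice_site_catalog(db)
    n <- 4
    s <- sample(0:470, n, replace = TRUE)
    peaks <- make_peaks(s, s + sample(5:30, n, replace = TRUE),
                        strand = sample(c("+", "-"), n, replace = TRUE))
    w <- 25L
    got <- splice_site_metaprofile(peaks, catalog, w)
    want <- oracle_metaprofile(peaks, catalog, w)
    for (kind in c("5'SS", "3'SS")) {
      expect_equal(got$value[got$kind == kind], want[[kind]])
    }
  }
})

test_that("profiles are invariant under exact peak duplication", {
  set.seed(63)
  db <- make_db(list(rand_transcript(500L, n_exons = 3)))
  catalog <- splice_site_catalog(db)
  s <- sample(0:450, 5)
  peaks <- make_peaks(s, s + 20L, strand = db$transcripts$strand)
  p1 <- splice_site_metaprofile(peaks, catalog, 30L)
  p2 <- splice_site_metaprofile(rbind(peaks, peaks), catalog, 30L)
  expect_equal(p1$value, p2$value)
  t1 <- transcript_metaprofile(peaks, db, 10L)
  t2 <- transcript_metaprofile(rbind(peaks, peaks), db, 10L)
  expect_equal(t1$value, t2$value)
})

test_that("transcript metaprofile handles full and zero coverage", {
  m <- transcript_model("t1", "g1", "chr1", "+",
                        rbind(c(0L, 100L), c(200L, 300L)), c(50L, 250L))
  db <- make_db(list(m))
  full <- make_peaks(0L, 300L)
  prof <- transcript_metaprofile(full, db, 10L)
  expect_true(all(prof$value == 1))
  none <- transcript_metaprofile(make_peaks(integer(0), integer(0)), db,
                                 10L)
  expect_true(all(none$value == 0))
})

test_that("transcript metaprofile matches a per-base binning oracle", {
  set.seed(64)
  B <- 8L
  for (rep in 1:10) {
    models <- lapply(1:3, function(k) {
      rand_transcript(400L, id = paste0("t", k))
    })
    db <- make_db(models)
    s <- sample(0:360, 6, replace = TRUE)
    peaks <- make_peaks(s, s + sample(10:40, 6, replace = TRUE),
                        strand = sample(c("+", "-"), 6, replace = TRUE))
    got <- transcript_metaprofile(peaks, db, B)
    # oracle: per transcript, walk region bases in transcript order
    labels <- c("5'UTR", "CDS", "intron", "3'UTR")
    acc <- matrix(0, 4, B, dimnames = list(labels, NULL))
    n_tx <- setNames(numeric(4), labels)
    for (m in models) {
      r <- derive_regions(m)
      covered_base <- function(b) {
        any(peaks$strand == m$strand & peaks$start <= b & peaks$end > b)
      }
      for (lab in labels) {
        rl <- r[r$label == lab, , drop = FALSE]
        if (nrow(rl) == 0) next
        if (m$strand == "-") rl <- rl[rev(seq_len(nrow(rl))), ,
                                      drop = FALSE]
        bases <- unlist(lapply(seq_len(nrow(rl)), function(k) {
          bs <- seq(rl$start[k], rl$end[k] - 1L)
          if (m$strand == "-") rev(bs) else bs
        }))
        n_tx[lab] <- n_tx[lab] + 1
        L <- length(bases)
        covered_bins <- rep(FALSE, B)
        for (idx in seq_along(bases)) {
          if (covered_base(bases[idx])) {
            covered_bins[((idx - 1L) * B) %/% L + 1L] <- TRUE
          }
        }
        acc[lab, ] <- acc[lab, ] + covered_bins
      }
    }
    for (lab in labels) {
      want <- if (n_tx[lab] > 0) acc[lab, ] / n_tx[lab] else rep(0, B)
      expect_equal(got$value[got$region == lab], unname(want))
    }
  }
})

test_that("BED round-trip preserves peak coordinates and strand", {
  peaks <- make_peaks(c(10L, 50L), c(30L, 90L), strand = c("+", "-"))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(peaks, bed)
  back <- read_peaks(bed, condition = "c1")
  expect_equal(back$start, peaks$start)
  expect_equal(back$end, peaks$end)
  expect_equal(back$strand, peaks$strand)
  expect_equal(back$peak_id, peaks$peak_id)
})
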