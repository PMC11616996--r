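test_that("expression filter applies strict padj and inclusive fold change", {
  d <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                  log2fc = c(1.0, 3, 0.9, -1.0, 2),
                  padj = c(0.049, 0.05, 0.01, 0.01, NA))
  out <- filter_de(d)
  expect_setequal(out$gene_id, c("a", "d"))
  expect_equal(nrow(filter_de(d[0, ])), 0L)
})

test_that("splicing filter thresholds are inclusive and read-aware", {
  keep <- make_as_record(1, fdr = 0.05, delta_psi = 0.05,
                         ijc1 = c(4L, 4L, 4L), sjc1 = c(0L, 0L, 0L),
                         ijc2 = c(1L, 1L, 1L), sjc2 = c(0L, 0L, 0L))
  expect_equal(nrow(filter_as(keep)), 1L)
  drop_reads <- make_as_record(2, fdr = 0.01, delta_psi = 0.3,
                               ijc1 = c(3L, 3L, 3L), sjc1 = c(0L, 0L, 0L),
                               ijc2 = c(2L, 2L, 2L), sjc2 = c(0L, 1L, 1L))
  expect_equal(nrow(filter_as(drop_reads)), 0L)
  # per-replicate reading of the read rule is stricter here
  expect_equal(nrow(filter_as(keep, per_replicate = TRUE)), 0L)
})

test_that("filters agree with brute-force predicate oracles", {
  set.seed(52)
  de <- data.frame(gene_id = sprintf("g%02d", 1:40),
                   log2fc = round(rnorm(40, 0, 1.5), 2),
                   padj = round(runif(40), 3))
  expect_equal(filter_de(de)$gene_id, oracle_filter_de(de)$gene_id)

  recs <- lapply(1:30, function(i) {
    make_as_record(i, fdr = round(runif(1), 3),
                   delta_psi = round(runif(1, -0.3, 0.3), 3),
                   ijc1 = sample(0:6, 3, TRUE), sjc1 = sample(0:6, 3, TRUE),
                   ijc2 = sample(0:6, 3, TRUE), sjc2 = sample(0:6, 3, TRUE))
  })
  tab <- do.call(bind_as_records, recs)
  expect_equal(filter_as(tab)$event_id, oracle_filter_as(tab)$event_id)
})

test_that("filter tightening never increases the retained count", {
  set.seed(53)
  de <- data.frame(gene_id = sprintf("g%03d", 1:200),
                   log2fc = rnorm(200, 0, 1.5), padj = runif(200))
  n_default <- nrow(filter_de(de))
  expect_lte(nrow(filter_de(de, padj_max = 0.01)), n_default)
  expect_lte(nrow(filter_de(de, min_abs_fc = 4)), n_default)
})

test_that("overlap summary reproduces set arithmetic and percentages", {
  # sizes mirroring the knockdown comparison: 827 and 802 with 521 shared
  a_ids <- sprintf("g%04d", 1:827)
  b_ids <- sprintf("g%04d", c(1:521, 828:1108))
  dir_a <- c(rep(1, 273), rep(-1, 241), rep(1, 7), rep(1, 306))
  dir_b <- c(rep(1, 273), rep(-1, 241), rep(-1, 7), rep(1, 281))
  a <- data.frame(gene_id = a_ids, log2fc = dir_a * runif(827, 1, 3))
  b <- data.frame(gene_id = b_ids, log2fc = dir_b * runif(802, 1, 3))
  s <- overlap_summary(a, b)
  expect_equal(s$n_intersection, 521L)
  expect_equal(s$n_union, 1108L)
  expect_equal(round(s$pct_shared, 1), 47.0)
  expect_equal(s$n_concordant, 514L)
  expect_equal(round(s$pct_concordant, 1), 98.7)
  expect_equal(s$n_shared_up, 273L)
  expect_equal(s$n_shared_down, 241L)
  # symmetric in the sets
  s2 <- overlap_summary(b, a)
  expect_equal(s2$pct_shared, s$pct_shared)
  expect_equal(s2$n_union, s$n_union)
})

test_that("overlap summary handles disjoint sets and rejects duplicates", {
  a <- data.frame(gene_id = c("a", "b"), log2fc = c(1, 2))
  b <- data.frame(gene_id = c("c", "d"), log2fc = c(1, 2))
  s <- overlap_summary(a, b)
  expect_equal(s$n_intersection, 0L)
  expect_equal(s$n_union, 4L)
  expect_equal(s$pct_shared, 0)
  expect_error(overlap_summary(rbind(a, a), b), "duplicate")
})

test_that("overlap summary equals brute-force set arithmetic", {
  set.seed(54)
  for (i in 1:20) {
    ids <- sprintf("x%03d", 1:80)
    a <- data.frame(gene_id = sample(ids, 50), log2fc = rnorm(50))
    b <- data.frame(gene_id = sample(ids, 50), log2fc = rnorm(50))
    s <- overlap_summary(a, b)
    inter <- sum(a$gene_id %in% b$gene_id)
    expect_equal(s$n_intersection, inter)
    expect_equal(s$n_union, 100L - inter)
    expect_equal(s$n_a + s$n_b - s$n_intersection, s$n_union)
  }
})

test_that("event-type composition recovers planted mixtures", {
  one_type <- do.call(bind_as_records, lapply(1:10, function(i) {
    make_as_record(i, event_type = "SE", delta_psi = 0.2)
  }))
  comp <- event_type_composition(one_type)
  expect_equal(unname(comp$fractions[["SE"]]), 1.0)
  expect_equal(sum(comp$fractions), 1.0)

  empty <- one_type[0, ]
  comp0 <- event_type_composition(empty)
  expect_equal(sum(comp0$counts), 0L)

  ds <- generate_dataset(synthetic_config(seed = 9, n_genes = 30L,
                                          n_as_sig = 20L,
                                          n_as_nonsig = 10L,
                                          n_peaks = 10L))
  tab <- ds$as_tables$comparison1
  man <- ds$manifest$as_events$comparison1
  sig <- man$event_id[man$planted_sig]
  comp2 <- event_type_composition(
    data.frame(event_type = tab$event_type[tab$ID %in% sig],
               delta_psi = tab$IncLevelDifference[tab$ID %in% sig]))
  planted <- table(man$event_type[man$planted_sig])
  expect_equal(comp2$counts[names(planted)],
               as.integer(planted), ignore_attr = TRUE)
})

test_that("table readers round-trip the generated dialects", {
  ds <- generate_dataset(synthetic_config(seed = 13, n_genes = 16L,
                                          n_peaks = 20L, n_as_sig = 8L,
                                          n_as_nonsig = 6L,
                                          as_noise_sd = 0))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(ds, dir)
  as_tab <- read_as_table(paths[["as_comparison1"]])
  expect_s3_class(as_tab, "as_table")
  expect_equal(nrow(as_tab), nrow(ds$as_tables$comparison1))
  expect_equal(as_tab$delta_psi, ds$as_tables$comparison1$IncLevelDifference)
  expect_length(as_tab$inc1[[1]], 3L)
  de_tab <- read_de_table(paths[["de_comparison1"]])
  expect_equal(de_tab$log2fc, ds$de_tables$comparison1$log2FoldChange)
})

test_that("noise-free tables yield exact planted-set recovery", {
  cfg <- synthetic_config(seed = 17, n_genes = 60L, n_as_sig = 40L,
                          n_as_nonsig = 20L, n_peaks = 10L,
                          as_noise_sd = 0)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(ds, dir)

  as_tab <- read_as_table(paths[["as_comparison1"]])
  sig <- filter_as(as_tab)
  man <- ds$manifest$as_events$comparison1
  expect_setequal(sig$event_id, man$event_id[man$planted_sig])

  de_tab <- read_de_table(paths[["de_comparison1"]])
  de_sig <- filter_de(de_tab)
  de_man <- ds$manifest$de_genes$comparison1
  expect_setequal(de_sig$gene_id,
                  de_man$gene_id[de_man$direction != "null"])
  expect_equal(sum(de_sig$log2fc > 0), cfg$n_de_up)
  expect_equal(sum(de_sig$log2fc < 0), cfg$n_de_down)
})
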