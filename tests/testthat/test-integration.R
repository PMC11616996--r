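test_that("condition-unique peaks honor 1-nt overlap on the same strand", {
  a <- make_peaks(c(100L, 300L), c(150L, 350L), id = c("a1", "a2"))
  expect_equal(nrow(condition_unique_peaks(a, a)$unique_a), 0L)
  empty <- a[0, ]
  u <- condition_unique_peaks(a, empty)
  expect_equal(u$unique_a$peak_id, c("a1", "a2"))

  b <- make_peaks(149L, 200L, id = "b1")
  u2 <- condition_unique_peaks(a, b)
  expect_equal(u2$unique_a$peak_id, "a2")  # a1 overlaps by exactly 1 nt
  b_anti <- make_peaks(149L, 200L, strand = "-", id = "b1")
  expect_equal(nrow(condition_unique_peaks(a, b_anti)$unique_a), 2L)
})

test_that("condition-unique peaks equal the all-pairs oracle", {
  set.seed(91)
  for (rep in 1:10) {
    s1 <- sample(0:400, 30, replace = TRUE)
    s2 <- sample(0:400, 30, replace = TRUE)
    a <- make_peaks(s1, s1 + sample(5:40, 30, replace = TRUE),
                    strand = sample(c("+", "-"), 30, replace = TRUE),
                    id = sprintf("a%02d", 1:30))
    b <- make_peaks(s2, s2 + sample(5:40, 30, replace = TRUE),
                    strand = sample(c("+", "-"), 30, replace = TRUE),
                    id = sprintf("b%02d", 1:30))
    u <- condition_unique_peaks(a, b)
    expect_equal(u$unique_a$peak_id, oracle_unique(a, b)$peak_id)
    expect_equal(u$unique_b$peak_id, oracle_unique(b, a)$peak_id)
  }
})

test_that("high-confidence window boundaries are bit-exact", {
  # cassette exon [1000,1100); long flanking introns
  ev <- make_as_record(1, exon = c(1000L, 1100L), upstream = c(300L, 400L),
                       downstream = c(1700L, 1800L))
  hit_in <- highconf_overlap(make_peaks(1020L, 1060L), ev)
  expect_equal(hit_in$relation, "within_exon")
  expect_equal(hit_in$distance_nt, 0L)

  # peak ending exactly at exon_end + 250 covers offset 249: a hit
  edge <- highconf_overlap(make_peaks(1330L, 1350L), ev)
  expect_equal(edge$relation, "downstream_flank")
  expect_equal(edge$distance_nt, 230L)
  just_in <- highconf_overlap(make_peaks(1349L, 1360L), ev)
  expect_equal(just_in$distance_nt, 249L)
  # peak starting at exon_end + 250 misses the half-open window
  expect_equal(nrow(highconf_overlap(make_peaks(1350L, 1380L), ev)), 0L)

  up <- highconf_overlap(make_peaks(700L, 760L), ev)
  expect_equal(up$relation, "upstream_flank")
  expect_equal(up$distance_nt, 240L)
  expect_equal(nrow(highconf_overlap(make_peaks(650L, 700L), ev)), 0L)
})

test_that("flanks truncate at the neighboring exon", {
  # downstream intron is only 100 nt: [1100, 1200)
  ev <- make_as_record(1, exon = c(1000L, 1100L), upstream = c(300L, 400L),
                       downstream = c(1200L, 1300L))
  # peak inside the neighboring exon but within 250 nt of the cassette
  expect_equal(nrow(highconf_overlap(make_peaks(1210L, 1240L), ev)), 0L)
  expect_equal(highconf_overlap(make_peaks(1150L, 1180L), ev)$relation,
               "downstream_flank")
})

test_that("flank zero equals plain exon overlap and hits grow with flank", {
  set.seed(92)
  ev <- make_as_record(1, exon = c(1000L, 1100L), upstream = c(300L, 400L),
                       downstream = c(1700L, 1800L))
  s <- sample(300:1800, 60, replace = TRUE)
  peaks <- make_peaks(s, s + sample(5:60, 60, replace = TRUE),
                      id = sprintf("p%02d", 1:60))
  h0 <- highconf_overlap(peaks, ev, flank_nt = 0L)
  plain <- peaks[peaks$start < 1100L & peaks$end > 1000L, ]
  expect_setequal(h0$peak_id, plain$peak_id)
  n_prev <- -1L
  for (f in c(0L, 50L, 150L, 250L, 400L)) {
    n <- nrow(highconf_overlap(peaks, ev, flank_nt = f))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("high-confidence calls match the per-base oracle", {
  set.seed(93)
  for (rep in 1:10) {
    strand <- sample(c("+", "-"), 1)
    if (strand == "+") {
      ev <- make_as_record(1, exon = c(1000L, 1100L),
                           upstream = c(300L, 400L),
                           downstream = c(1700L, 1800L), strand = "+")
    } else {
      ev <- make_as_record(1, exon = c(1000L, 1100L),
                           upstream = c(1700L, 1800L),
                           downstream = c(300L, 400L), strand = "-")
    }
    s <- sample(200:1900, 20, replace = TRUE)
    peaks <- make_peaks(s, s + sample(5:60, 20, replace = TRUE),
                        strand = sample(c("+", "-"), 20, replace = TRUE),
                        id = sprintf("p%02d", 1:20))
    got <- highconf_overlap(peaks, ev, flank_nt = 250L)
    for (i in seq_len(nrow(peaks))) {
      want <- oracle_highconf_hit(peaks[i, ], ev, 250L)
      expect_equal(peaks$peak_id[i] %in% got$peak_id, want)
    }
  }
})

test_that("three-way cross-reference satisfies inclusion-exclusion", {
  s <- three_way_crossref(sprintf("g%03d", 1:596)[1:596],
                          character(0), sprintf("g%03d", 1:32))
  expect_equal(round(s$pct_de_with_peak, 1), 5.4)

  set.seed(94)
  for (rep in 1:10) {
    ids <- sprintf("x%02d", 1:50)
    de <- sample(ids, sample(5:30, 1))
    as_ <- sample(ids, sample(5:30, 1))
    pk <- sample(ids, sample(5:30, 1))
    s <- three_way_crossref(de, as_, pk)
    expect_equal(sum(s$cells[c("de_only", "de_as", "de_peak",
                               "de_as_peak")]), length(de))
    expect_equal(sum(s$cells[c("as_only", "de_as", "as_peak",
                               "de_as_peak")]), length(as_))
    expect_equal(sum(s$cells[c("peak_only", "de_peak", "as_peak",
                               "de_as_peak")]), length(pk))
    inter_dp <- length(intersect(de, pk))
    expect_equal(s$pct_de_with_peak, 100 * inter_dp / length(de))
  }
  disjoint <- three_way_crossref(c("a"), c("b"), c("c"))
  expect_true(all(disjoint$cells[c("de_as", "de_peak", "as_peak",
                                   "de_as_peak")] == 0))
})

test_that("printed bound percentages are recomputed from set sizes", {
  de <- sprintf("d%04d", 1:596)
  pk_de <- de[1:32]
  as_ <- sprintf("a%04d", 1:985)
  pk_as <- as_[1:233]
  s <- three_way_crossref(de, as_, union(pk_de, pk_as))
  expect_equal(round(s$pct_de_with_peak, 1), 5.4)
  expect_equal(round(s$pct_as_with_peak, 1), 23.7)
})

test_that("PSI and isoform-ratio arithmetic match hand values", {
  expect_equal(psi_from_abundances(c(60, 40)), 60.0)
  expect_equal(psi_from_abundances(c(50, 50)), 50.0)
  expect_equal(psi_from_abundances(c(30, 20, 10)), 50.0)
  expect_error(psi_from_abundances(c(0, 0)), "all abundances are zero")
  expect_error(psi_from_abundances(5), ">= 2")
  set.seed(95)
  for (i in 1:20) {
    x <- runif(sample(2:4, 1), 0, 10)
    p <- psi_from_abundances(x)
    expect_gte(p, 0); expect_lte(p, 100)
  }

  expect_equal(isoform_ratio(0.6, 0.4), 1.5)
  expect_equal(isoform_ratio(0.5, 0.5), 1.0)
  expect_equal(isoform_ratio(0.6, 0.4, larger_control = 2,
                             smaller_control = 2), 1.5)
  expect_error(isoform_ratio(0.6, 0), "> 0")
})
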