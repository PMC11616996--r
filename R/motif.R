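# Strand-aware peak sequence extraction and k-mer enrichment testing.

#' Extract oriented peak sequences
#'
#' Minus-strand peaks are reverse-complemented so that motifs read in
#' transcript orientation.
#'
#' @param peaks Peak data.frame.
#' @param genome A `genome_seq`.
#' @return Character vector of sequences, named by peak id.
#' @export
extract_peak_sequences <- function(peaks, genome) {
  stopifnot(inherits(genome, "genome_seq"))
  out <- vapply(seq_len(nrow(peaks)), function(i) {
    get_seq(genome, peaks$contig[i], peaks$start[i], peaks$end[i],
            peaks$strand[i])
  }, character(1))
  names(out) <- peaks$peak_id
  out
}

#' Per-sequence k-mer frequencies
#'
#' Counts overlapping k-mer windows; windows containing N are skipped from
#' both numerator and denominator, so frequencies sum to 1 whenever at
#' least one valid window exists.
#'
#' @param sequence One nucleotide string.
#' @param k Word length (default 6).
#' @return Named numeric vector of frequencies (empty, with a warning, when
#'   the sequence is shorter than `k`).
#' @export
kmer_frequencies <- function(sequence, k = 6L) {
  n <- nchar(sequence)
  if (n < k) {
    warning("sequence shorter than k; returning empty frequency map")
    return(stats::setNames(numeric(0), character(0)))
  }
  starts <- seq_len(n - k + 1L)
  words <- substring(sequence, starts, starts + k - 1L)
  words <- words[!grepl("N", words, fixed = TRUE)]
  if (length(words) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(words)
  stats::setNames(as.numeric(tab) / length(words), names(tab))
}

# Dinucleotide-preserving shuffle of one sequence (Altschul-Erikson).
# Treats the sequence as an Eulerian path on the digraph whose edges are
# its dinucleotides; samples a uniform random last-edge tree oriented
# toward the final symbol, permutes the remaining out-edges, and walks.
shuffle_dinucleotide <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n <= 3L) return(s)
  syms <- unique(ch)
  from <- ch[-n]; to <- ch[-1L]
  adj <- split(to, factor(from, levels = syms))
  last_sym <- ch[n]
  verts <- names(adj)[lengths(adj) > 0L]
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last_sym) NA_character_
      else adj[[v]][sample.int(length(adj[[v]]), 1L)]
    }, character(1))
    # accept iff every vertex reaches last_sym via chosen last edges
    ok <- TRUE
    for (v in verts) {
      if (v == last_sym) next
      seen <- character(0)
      cur <- v
      while (!is.na(cur) && cur != last_sym && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- if (cur %in% names(last_edge)) last_edge[[cur]]
               else NA_character_
      }
      if (is.na(cur) || cur != last_sym) { ok <- FALSE; break }
    }
    if (ok) break
  }
  # permute out-edges, moving the chosen last edge to the end
  for (v in verts) {
    e <- adj[[v]]
    if (v != last_sym) {
      le <- last_edge[[v]]
      i <- match(le, e)
      e <- e[-i]
      e <- c(if (length(e) > 0L) sample(e) else character(0), le)
    } else {
      e <- if (length(e) > 1L) sample(e) else e
    }
    adj[[v]] <- e
  }
  # walk
  res <- character(n)
  res[1] <- ch[1]
  ptr <- stats::setNames(rep(1L, length(adj)), names(adj))
  cur <- ch[1]
  for (i in 2:n) {
    nxt <- adj[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Build a background sequence set
#'
#' One background sequence per foreground sequence, of identical length.
#' `dinucleotide_shuffle` (the default elsewhere) preserves the exact
#' dinucleotide multiset of each sequence; `mononucleotide_shuffle`
#' permutes bases; `user_supplied` returns `user_background` unchanged.
#'
#' @param foreground Character vector of sequences.
#' @param method One of `"dinucleotide_shuffle"`,
#'   `"mononucleotide_shuffle"`, `"user_supplied"`.
#' @param seed Integer seed.
#' @param user_background Required for `method = "user_supplied"`.
#' @return Character vector of background sequences.
#' @export
make_background <- function(foreground,
                            method = c("dinucleotide_shuffle",
                                       "mononucleotide_shuffle",
                                       "user_supplied"),
                            seed = 1L, user_background = NULL) {
  method <- match.arg(method)
  if (method == "user_supplied") {
    if (is.null(user_background)) stop("user_background required")
    return(user_background)
  }
  set.seed(as.integer(seed))
  if (method == "dinucleotide_shuffle") {
    vapply(foreground, shuffle_dinucleotide, character(1),
           USE.NAMES = FALSE)
  } else {
    vapply(foreground, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
}

# kmers x sequences frequency matrix over a fixed kmer universe.
kmer_freq_matrix <- function(seqs, k, universe) {
  m <- matrix(0, nrow = length(universe), ncol = length(seqs),
              dimnames = list(universe, NULL))
  for (j in seq_along(seqs)) {
    f <- suppressWarnings(kmer_frequencies(seqs[j], k))
    if (length(f) > 0L) m[match(names(f), universe), j] <- f
  }
  m
}

#' k-mer enrichment between foreground and background sequence sets
#'
#' For every k-mer observed in either set, compares the per-sequence
#' frequency distributions with a two-sample unequal-variance (Welch)
#' t-test. Results are ranked by ascending p, then descending foreground
#' mean. When both group variances are zero the statistic degenerates: p is
#' 1 (t = 0) for equal means and 0 otherwise.
#'
#' @param foreground,background Character vectors (each of length >= 2).
#' @param k Word length (default 6).
#' @return data.frame of class `kmer_stats`, ranked: `kmer`, `fg_mean`,
#'   `bg_mean`, `t`, `p`, `rank`.
#' @export
enrichment_test <- function(foreground, background, k = 6L) {
  if (length(foreground) < 2L || length(background) < 2L) {
    stop("need >= 2 sequences per group")
  }
  fg_words <- unique(unlist(lapply(foreground, function(s) {
    names(suppressWarnings(kmer_frequencies(s, k)))
  })))
  bg_words <- unique(unlist(lapply(background, function(s) {
    names(suppressWarnings(kmer_frequencies(s, k)))
  })))
  universe <- sort(union(fg_words, bg_words))
  if (length(universe) == 0L) stop("no valid k-mer windows in either group")
  mf <- kmer_freq_matrix(foreground, k, universe)
  mb <- kmer_freq_matrix(background, k, universe)
  n1 <- ncol(mf); n2 <- ncol(mb)
  m1 <- rowMeans(mf); m2 <- rowMeans(mb)
  v1 <- rowSums((mf - m1)^2) / (n1 - 1L)
  v2 <- rowSums((mb - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  d <- m1 - m2
  t_stat <- ifelse(se2 > 0, d / sqrt(se2),
                   ifelse(d == 0, 0, sign(d) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L)),
               1)
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df),
              0)
  p[se2 == 0 & d == 0] <- 1
  out <- data.frame(kmer = universe, fg_mean = m1, bg_mean = m2,
                    t = t_stat, p = p, stringsAsFactors = FALSE)
  o <- order(out$p, -out$fg_mean, out$kmer)
  out <- out[o, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("kmer_stats", "data.frame")
  out
}

#' Motif enrichment of a peak set against a shuffled background
#'
#' Convenience wrapper: extracts oriented peak sequences, builds a
#' dinucleotide-preserving shuffled background, and runs
#' [enrichment_test()].
#'
#' @param peaks Peak data.frame.
#' @param genome A `genome_seq`.
#' @param k Word length.
#' @param background_method Passed to [make_background()].
#' @param seed Seed for the shuffle.
#' @return A `kmer_stats` data.frame.
#' @export
peak_motif_enrichment <- function(peaks, genome, k = 6L,
                                  background_method = "dinucleotide_shuffle",
                                  seed = 1L) {
  fg <- extract_peak_sequences(peaks, genome)
  bg <- make_background(fg, method = background_method, seed = seed)
  enrichment_test(fg, bg, k = k)
}
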