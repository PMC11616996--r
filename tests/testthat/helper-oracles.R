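# Independent brute-force oracles: per-base membership counting and exact
# enumeration, deliberately implemented with naive loops and kept free of
# any code path they are used to check.

# per-base overlap (nt) between a peak and a labeled interval set
oracle_overlap_nt <- function(p_start, p_end, iv_start, iv_end) {
  n <- 0L
  for (b in seq_len(p_end - p_start) - 1L + p_start) {
    for (k in seq_along(iv_start)) {
      if (b >= iv_start[k] && b < iv_end[k]) { n <- n + 1L; break }
    }
  }
  n
}

# region assignment by per-base counting + documented decision rule
oracle_assign_region <- function(peak, regions) {
  r <- regions[regions$contig == peak$contig &
                 regions$strand == peak$strand, , drop = FALSE]
  if (nrow(r) == 0L) return(NULL)
  combos <- unique(r[, c("transcript_id", "label")])
  combos$ov <- NA_integer_
  for (i in seq_len(nrow(combos))) {
    sub <- r[r$transcript_id == combos$transcript_id[i] &
               r$label == combos$label[i], ]
    combos$ov[i] <- oracle_overlap_nt(peak$start, peak$end, sub$start,
                                      sub$end)
  }
  combos <- combos[combos$ov > 0, , drop = FALSE]
  if (nrow(combos) == 0L) return(NULL)
  cds_len <- sapply(combos$transcript_id, function(tid) {
    sub <- r[r$transcript_id == tid & r$label == "CDS", ]
    sum(sub$end - sub$start)
  })
  prio <- c("CDS" = 1, "5'UTR" = 2, "3'UTR" = 3, "intron" = 4)
  o <- order(-combos$ov, prio[combos$label], -cds_len,
             combos$transcript_id)
  combos[o[1], ]
}

# metaprofile by per-site per-offset per-base membership
oracle_metaprofile <- function(peaks, sites, w) {
  offsets <- seq(-w, w)
  out <- list()
  for (kind in c("5'SS", "3'SS")) {
    s <- sites[sites$kind == kind, , drop = FALSE]
    vals <- numeric(length(offsets))
    for (oi in seq_along(offsets)) {
      o <- offsets[oi]
      n_cov <- 0L
      for (i in seq_len(nrow(s))) {
        base <- if (s$strand[i] == "+") s$pos[i] + o else s$pos[i] - 1L - o
        hit <- FALSE
        for (j in seq_len(nrow(peaks))) {
          if (peaks$contig[j] == s$contig[i] &&
              peaks$strand[j] == s$strand[i] &&
              base >= peaks$start[j] && base < peaks$end[j]) {
            hit <- TRUE; break
          }
        }
        if (hit) n_cov <- n_cov + 1L
      }
      vals[oi] <- if (nrow(s) > 0) n_cov / nrow(s) else 0
    }
    out[[kind]] <- vals
  }
  out
}

# exact Mann-Whitney two-sided p by enumeration of all group assignments
oracle_mw <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_obs <- 0
  for (xi in x) for (yi in y) {
    u_obs <- u_obs + (xi > yi) + 0.5 * (xi == yi)
  }
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(ii) {
    a <- pooled[ii]; b <- pooled[-ii]
    u <- 0
    for (ai in a) for (bi in b) u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  })
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_low, p_high)))
}

# all-pairs overlap test for condition-unique peaks
oracle_unique <- function(a, b) {
  keep <- rep(TRUE, nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$contig[i] == b$contig[j] && a$strand[i] == b$strand[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        keep[i] <- FALSE; break
      }
    }
  }
  a[keep, , drop = FALSE]
}

# per-base membership for the exon +/- truncated-flank window
oracle_highconf_hit <- function(peak, ev, flank) {
  if (peak$contig != ev$contig || peak$strand != ev$strand) return(FALSE)
  if (ev$strand == "+") {
    up <- c(ev$upstream_end, ev$exon_start)
    down <- c(ev$exon_end, ev$downstream_start)
    win <- c(max(ev$exon_start - flank, up[1]),
             min(ev$exon_end + flank, down[2]))
  } else {
    up <- c(ev$exon_end, ev$upstream_start)
    down <- c(ev$downstream_end, ev$exon_start)
    win <- c(max(ev$exon_start - flank, down[1]),
             min(ev$exon_end + flank, up[2]))
  }
  for (b in seq(win[1], win[2] - 1L)) {
    if (b >= peak$start && b < peak$end) return(TRUE)
  }
  FALSE
}

# brute-force filter predicates
oracle_filter_de <- function(d, padj_max = 0.05, min_fc = 2) {
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    keep[i] <- !is.na(d$padj[i]) && d$padj[i] < padj_max &&
      !is.na(d$log2fc[i]) && 2^abs(d$log2fc[i]) >= min_fc
  }
  d[keep, , drop = FALSE]
}

oracle_filter_as <- function(d, fdr_max = 0.05, min_dpsi = 0.05,
                             min_reads = 10) {
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    r1 <- sum(d$ijc1[[i]]) + sum(d$sjc1[[i]])
    r2 <- sum(d$ijc2[[i]]) + sum(d$sjc2[[i]])
    keep[i] <- d$fdr[i] <= fdr_max && abs(d$delta_psi[i]) >= min_dpsi &&
      (r1 >= min_reads || r2 >= min_reads)
  }
  d[keep, , drop = FALSE]
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}
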