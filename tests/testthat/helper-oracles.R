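# Independent brute-force oracles, deliberately naive and self-contained:
# they re-derive expected values from first principles without touching the
# package's internals.

# degeneracy sets written out by hand
oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

oracle_iupac_match <- function(pattern, window) {
  p <- strsplit(pattern, "")[[1]]
  w <- strsplit(window, "")[[1]]
  if (length(p) != length(w)) return(FALSE)
  all(vapply(
    seq_along(p),
    function(i) w[[i]] %in% oracle_iupac_sets[[p[[i]]]],
    logical(1)
  ))
}

oracle_revcomp <- function(motif) {
  comp <- c(
    A = "T", C = "G", G = "C", T = "A",
    R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
    B = "V", D = "H", H = "D", V = "B", N = "N"
  )
  paste(rev(comp[strsplit(motif, "")[[1]]]), collapse = "")
}

# tests every start position with the naive matcher; both strands unless
# the motif is its own reverse complement
oracle_scan <- function(seq, motif, cut_offset) {
  seq <- toupper(seq)
  motif <- toupper(motif)
  m <- nchar(motif)
  n <- nchar(seq)
  cuts <- integer(0)
  rc <- oracle_revcomp(motif)
  for (start0 in seq_len(max(n - m + 1, 0)) - 1L) {
    window <- substr(seq, start0 + 1L, start0 + m)
    if (oracle_iupac_match(motif, window)) {
      cuts <- c(cuts, start0 + cut_offset)
    }
    if (!identical(motif, rc) && oracle_iupac_match(rc, window)) {
      cuts <- c(cuts, start0 + m - cut_offset)
    }
  }
  sort(unique(cuts))
}

# same all-positions check as oracle_scan, but testing every start
# position with vectorised set membership so large sweeps stay affordable
oracle_scan_vec <- function(seq, motif, cut_offset) {
  ch <- strsplit(toupper(seq), "")[[1]]
  scan1 <- function(pat, off) {
    sets <- oracle_iupac_sets[strsplit(pat, "")[[1]]]
    m <- length(sets)
    n <- length(ch)
    if (n < m) return(integer(0))
    ok <- rep(TRUE, n - m + 1)
    for (j in seq_len(m)) {
      ok <- ok & ch[j:(n - m + j)] %in% sets[[j]]
    }
    which(ok) - 1L + off
  }
  motif <- toupper(motif)
  rc <- oracle_revcomp(motif)
  cuts <- scan1(motif, cut_offset)
  if (!identical(motif, rc)) {
    cuts <- c(cuts, scan1(rc, nchar(motif) - cut_offset))
  }
  sort(unique(as.integer(cuts)))
}

# naive per-range protocol evaluation straight from the definitions:
# filter fragments by length, mark each site by containment and
# end-proximity, sum weights
oracle_evaluate_range <- function(fragments, sites, lower, breadth,
                                  read_length) {
  upper <- lower + breadth
  keep <- fragments$length >= lower & fragments$length <= upper
  sel <- fragments[keep, , drop = FALSE]
  nf <- nrow(sel)
  gamma <- vapply(seq_len(nrow(sites)), function(i) {
    p <- sites$coord[[i]]
    ch <- sites$chrom[[i]]
    for (j in seq_len(nrow(sel))) {
      if (sel$chrom[[j]] == ch && sel$start[[j]] <= p && p < sel$end[[j]]) {
        near <- (p - sel$start[[j]] < read_length) ||
          (sel$end[[j]] - p <= read_length)
        return(as.integer(near))
      }
    }
    0L
  }, integer(1))
  score <- sum(sites$weight * gamma)
  max_score <- sum(sites$weight)
  n <- nrow(sites)
  ev <- if (nf > 0 && score > 0) {
    -log10((score / nf) * (n / max_score))
  } else {
    NA_real_
  }
  list(nf = nf, score = score, ev = ev, gamma = gamma)
}

# full brute force over combinations x grid, mirroring the thresholds and
# tie-breaks from the definitions; returns the winning row per combination
oracle_search <- function(indices_by_family, sites, config) {
  fam_ids <- sort(names(indices_by_family))
  combos <- c(
    as.list(fam_ids),
    combn(fam_ids, 2, simplify = FALSE)
  )
  grid <- expand.grid(
    breadth = seq(config$experimental_error, config$max_breadth,
      by = config$experimental_error
    ),
    lower = seq(config$min_lower, config$max_lower,
      by = config$experimental_error
    )
  )[, c("lower", "breadth")]
  grid <- grid[order(grid$lower, grid$breadth), ]
  nf_max <- config$nf_constant * config$genome_size / 1000
  max_score <- sum(sites$weight)
  best_rows <- list()
  for (fids in combos) {
    index <- if (length(fids) == 2) {
      merge_cut_indices(indices_by_family[[fids[1]]],
        indices_by_family[[fids[2]]])
    } else {
      indices_by_family[[fids]]
    }
    fragments <- build_fragments(index)
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      r <- oracle_evaluate_range(
        fragments, sites, grid$lower[[g]], grid$breadth[[g]],
        config$read_length
      )
      if (is.na(r$ev)) next
      if (r$score < config$score_threshold * max_score - 1e-12) next
      if (r$nf > nf_max) next
      if (is.null(best) || r$ev < best$ev - 1e-12) {
        best <- c(r, list(lower = grid$lower[[g]], breadth = grid$breadth[[g]]))
      }
    }
    if (!is.null(best)) {
      best_rows[[paste(fids, collapse = "+")]] <- data.frame(
        enzymes = paste(fids, collapse = "+"),
        lower = best$lower, breadth = best$breadth,
        nf = best$nf, score = best$score, ev = best$ev
      )
    }
  }
  if (length(best_rows) == 0) return(NULL)
  do.call(rbind, unname(best_rows))
}
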