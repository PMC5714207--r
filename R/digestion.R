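#' Test a genomic window against an IUPAC pattern
#'
#' A window matches when every base falls inside the degeneracy set of the
#' corresponding pattern letter. A genome `N` (assembly gap or unknown base)
#' matches only the pattern letter `N`: a motif cannot be asserted inside a
#' gap run, so specific pattern letters never match genomic `N`.
#'
#' @param pattern IUPAC nucleotide string (15-letter alphabet).
#' @param window Nucleotide string over `A,C,G,T,N` of the same length.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' iupac_match("WCCGGW", "TCCGGA") # W = A or T
#' iupac_match("CCGG", "CCGN")
iupac_match <- function(pattern, window) {
  if (nchar(pattern) != nchar(window)) {
    stop("pattern and window lengths differ", call. = FALSE)
  }
  pm <- iupac_masks(toupper(pattern))
  wm <- base_masks(toupper(window))
  all(bitwAnd(pm, wm) != 0L)
}

# bitmask per IUPAC letter: A=1 C=2 G=4 T=8, plus a private bit 16 for the
# genomic-N letter so that pattern N (and only pattern N) matches genome N
iupac_bits <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 31L
)

iupac_masks <- function(x) {
  ch <- strsplit(x, "")[[1]]
  m <- iupac_bits[ch]
  if (anyNA(m)) {
    stop("non-IUPAC letter in pattern: ", x, call. = FALSE)
  }
  unname(m)
}

# genome letters: ACGT literal; N and any other ambiguity code are treated
# as unknown (mask 16), matchable only by pattern N
base_masks <- function(x) {
  ch <- strsplit(x, "")[[1]]
  m <- c(A = 1L, C = 2L, G = 4L, T = 8L)[ch]
  m[is.na(m)] <- 16L
  unname(m)
}

#' Reverse complement of an IUPAC motif
#'
#' @param motif IUPAC nucleotide string.
#' @return The IUPAC reverse complement.
#' @keywords internal
iupac_revcomp <- function(motif) {
  as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif))
  )
}

# set-wise palindromy: the motif's degeneracy sets equal those of its
# reverse complement (string identity suffices because IUPAC letters map
# one-to-one onto base sets)
is_palindromic <- function(motif) {
  identical(toupper(motif), iupac_revcomp(motif))
}

#' Scan one sequence for the cut sites of an enzyme
#'
#' Finds every occurrence of the recognition motif (IUPAC-aware, overlapping
#' matches included) and reports the top-strand cut coordinate of each
#' double-strand cut. Coordinates are 0-based: a cut at coordinate `c`
#' severs the bond between positions `c - 1` and `c`, i.e. `c` is the first
#' base after the cut. For a top-strand match starting at 0-based position
#' `m` the cut falls at `m + cut_offset`; when the motif is not its own
#' IUPAC reverse complement the opposite strand is scanned too, a match at
#' `m` cutting at `m + (motif_length - cut_offset)`. Palindromic motifs are
#' scanned once to avoid double counting. Matching is case-insensitive;
#' genomic `N` matches only pattern `N`.
#'
#' @param seq A character string or [Biostrings::DNAString].
#' @param motif IUPAC recognition motif.
#' @param cut_offset Bases 5' of the top-strand cut within the motif,
#'   in `[1, nchar(motif)]`.
#' @return Sorted, deduplicated integer vector of 0-based cut coordinates.
#' @export
#' @examples
#' scan_cut_sites("ATCCGGAT", "CCGG", 1) # MspI: C^CGG
#' scan_cut_sites("CCGGAACCGG", "CCGG", 1)
scan_cut_sites <- function(seq, motif, cut_offset) {
  motif <- toupper(motif)
  cut_offset <- as.integer(cut_offset)
  stopifnot(cut_offset >= 1L, cut_offset <= nchar(motif))
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  if (length(seq) < nchar(motif)) return(integer(0))
  # fixed = "subject": degeneracy interpreted in the pattern only, so a
  # genomic N stays literal and never satisfies a specific pattern letter
  fwd <- Biostrings::start(
    Biostrings::matchPattern(motif, seq, fixed = "subject")
  )
  cuts <- (fwd - 1L) + cut_offset
  if (!is_palindromic(motif)) {
    rev <- Biostrings::start(
      Biostrings::matchPattern(iupac_revcomp(motif), seq, fixed = "subject")
    )
    cuts <- c(cuts, (rev - 1L) + (nchar(motif) - cut_offset))
  }
  sort(unique(as.integer(cuts)))
}

#' Digest a genome with an isoschizomer family
#'
#' Scans every chromosome with the family's representative enzyme (all
#' members share the motif and offset, so one member suffices) and returns
#' a cut-site table.
#'
#' @param genome A named [Biostrings::DNAStringSet] (one entry per
#'   chromosome) or a named character vector of sequences. The genome
#'   identifier is taken from `attr(genome, "genome_id")` unless overridden.
#' @param family One row of a family tibble from [enzyme_families()], or any
#'   list with `family_id`, `motif`, `cut_offset`.
#' @param genome_id Optional genome identifier recorded in the index.
#' @return A `cut_sites` tibble with columns `chrom` and `cut` (0-based,
#'   strictly increasing within each chromosome) and attributes `genome_id`,
#'   `family_id`, `motif`, `cut_offset`.
#' @export
digest_genome <- function(genome, family, genome_id = NULL) {
  genome_id <- genome_id %||% attr(genome, "genome_id") %||% "unknown"
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (is.null(names(genome)) || anyDuplicated(names(genome))) {
    stop("genome chromosomes must have unique names", call. = FALSE)
  }
  fam <- as.list(family)
  cuts <- purrr::map(seq_along(genome), function(i) {
    s <- genome[[i]]
    if (is.null(s)) {
      stop("sequence unavailable for chromosome ", names(genome)[[i]],
        call. = FALSE
      )
    }
    scan_cut_sites(s, fam$motif, fam$cut_offset)
  })
  out <- tibble::tibble(
    chrom = rep(names(genome), lengths(cuts)),
    cut = as.integer(unlist(cuts))
  )
  new_cut_sites(
    out,
    genome_id = genome_id,
    family_id = fam$family_id,
    motif = fam$motif,
    cut_offset = as.integer(fam$cut_offset)
  )
}

new_cut_sites <- function(tbl, genome_id, family_id, motif, cut_offset) {
  structure(
    tbl,
    genome_id = genome_id,
    family_id = family_id,
    motif = motif,
    cut_offset = cut_offset,
    class = c("cut_sites", class(tibble::as_tibble(tbl)))
  )
}

#' @export
print.cut_sites <- function(x, ...) {
  cat(
    "<cut_sites> genome:", attr(x, "genome_id"),
    " family:", attr(x, "family_id"),
    " motif:", paste(attr(x, "motif"), collapse = "+"), "\n"
  )
  NextMethod()
}

#' Merge two cut-site indices (double digestion)
#'
#' The union of cut coordinates of two enzymes models a double digestion:
#' every fragment end produced by either enzyme is an end of the combined
#' digestion. Indices must come from the same genome.
#'
#' @param a,b `cut_sites` tibbles from [digest_genome()] or
#'   [read_precomputed()].
#' @return A `cut_sites` tibble with the per-chromosome sorted union;
#'   `family_id` becomes `"<a>+<b>"`.
#' @export
merge_cut_indices <- function(a, b) {
  ga <- attr(a, "genome_id")
  gb <- attr(b, "genome_id")
  if (!identical(ga, gb)) {
    stop(
      "cannot merge cut indices from different genomes: ",
      ga, " vs ", gb,
      call. = FALSE
    )
  }
  out <- dplyr::bind_rows(
    tibble::as_tibble(a)[c("chrom", "cut")],
    tibble::as_tibble(b)[c("chrom", "cut")]
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$chrom, .data$cut)
  new_cut_sites(
    out,
    genome_id = ga,
    family_id = paste(attr(a, "family_id"), attr(b, "family_id"), sep = "+"),
    motif = c(attr(a, "motif"), attr(b, "motif")),
    cut_offset = c(attr(a, "cut_offset"), attr(b, "cut_offset"))
  )
}

#' Write / read a pre-computed cut-site file
#'
#' Digesting a large genome dominates run time, so digestions are stored
#' once and re-read whenever an enzyme is assessed. The format is
#' gzip-compressed text: `#`-prefixed header lines (`genome_id`,
#' `family_id`, `motif`, `cut_offset`), then `chrom<TAB>coordinate` records
#' sorted by chromosome then coordinate.
#'
#' @param index A `cut_sites` tibble.
#' @param path Output path (written gzip-compressed).
#' @return `write_precomputed()` returns `path` invisibly;
#'   `read_precomputed()` returns a validated `cut_sites` tibble.
#' @export
write_precomputed <- function(index, path) {
  con <- gzfile(path, "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("#genome_id=", attr(index, "genome_id")),
    paste0("#family_id=", attr(index, "family_id")),
    paste0("#motif=", paste(attr(index, "motif"), collapse = "+")),
    paste0("#cut_offset=", paste(attr(index, "cut_offset"), collapse = "+"))
  ), con)
  if (nrow(index) > 0L) {
    writeLines(paste(index$chrom, index$cut, sep = "\t"), con)
  }
  invisible(path)
}

#' @param expect_genome_id If given, `read_precomputed()` refuses to load a
#'   file whose header records a different genome, preventing cross-genome
#'   contamination of a run.
#' @rdname write_precomputed
#' @export
read_precomputed <- function(path, expect_genome_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(gzfile(path), warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    hit <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(hit) != 1L) {
      stop("pre-computed file lacks header field ", key, ": ", path,
        call. = FALSE
      )
    }
    sub(paste0("^#", key, "="), "", hit)
  }
  genome_id <- get_hdr("genome_id")
  if (!is.null(expect_genome_id) && !identical(genome_id, expect_genome_id)) {
    stop(
      "pre-computed file is for genome ", genome_id,
      ", refusing to load into a run for ", expect_genome_id,
      call. = FALSE
    )
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) > 0L) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("malformed record in pre-computed file: ", path, call. = FALSE)
    }
    tbl <- tibble::tibble(
      chrom = vapply(parts, `[[`, "", 1L),
      cut = as.integer(vapply(parts, `[[`, "", 2L))
    )
    if (anyNA(tbl$cut)) {
      stop("non-integer coordinate in pre-computed file: ", path,
        call. = FALSE
      )
    }
    unsorted <- tbl |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(ok = !is.unsorted(.data$cut, strictly = TRUE))
    if (!all(unsorted$ok)) {
      stop(
        "pre-computed file is not strictly sorted within chromosome: ", path,
        call. = FALSE
      )
    }
  } else {
    tbl <- tibble::tibble(chrom = character(0), cut = integer(0))
  }
  new_cut_sites(
    tbl,
    genome_id = genome_id,
    family_id = get_hdr("family_id"),
    motif = strsplit(get_hdr("motif"), "+", fixed = TRUE)[[1]],
    cut_offset = as.integer(
      strsplit(get_hdr("cut_offset"), "+", fixed = TRUE)[[1]]
    )
  )
}

#' Export cut sites as BED intervals
#'
#' Writes each cut coordinate as a 1 bp BED interval (0-based half-open)
#' for inspection in a genome browser.
#'
#' @param index A `cut_sites` tibble.
#' @param path Output path.
#' @export
write_cut_bed <- function(index, path) {
  df <- tibble::as_tibble(index)
  utils::write.table(
    data.frame(
      chrom = df$chrom,
      start = df$cut,
      end = df$cut + 1L,
      name = attr(index, "family_id")
    ),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
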