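#' Generate a seeded synthetic genome with planted restriction sites
#'
#' Builds random chromosomes whose background is guaranteed free of a set
#' of recognition motifs (on both strands), then plants concrete motif
#' instances at recorded positions. Because the background cannot match the
#' avoided motifs, the planted instances are provably the only cut sites,
#' giving tests an exact ground truth. Generation is deterministic for a
#' given seed.
#'
#' @param seed Integer seed.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param planted Optional tibble with columns `chrom`, `pos` (0-based
#'   insertion start) and `seq` (concrete `ACGT` string); instances of one
#'   motif must not overlap.
#' @param avoid_motifs Character vector of IUPAC motifs the background must
#'   not contain (typically the recognition motifs of the catalog under
#'   test).
#' @param max_iter Repair iterations before giving up (a dense motif set on
#'   a short sequence can make a clean background impossible).
#' @return A named [Biostrings::DNAStringSet] with attributes `genome_id`
#'   (`"synthetic-seed<seed>-v1"`) and `planted` (the planted tibble).
#' @export
generate_genome <- function(seed, chrom_lengths, planted = NULL,
                            avoid_motifs = character(0), max_iter = 100L) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  if (is.null(planted)) {
    planted <- tibble::tibble(
      chrom = character(0), pos = integer(0), seq = character(0)
    )
  }
  bad <- planted$pos < 0 |
    planted$pos + nchar(planted$seq) > chrom_lengths[planted$chrom]
  if (any(bad)) stop("planted instance outside chromosome", call. = FALSE)
  chroms <- withr::with_seed(seed, {
    lapply(names(chrom_lengths), function(ch) {
      len <- chrom_lengths[[ch]]
      x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      pl <- planted[planted$chrom == ch, , drop = FALSE]
      plant_ranges <- if (nrow(pl)) {
        cbind(pl$pos + 1L, pl$pos + nchar(pl$seq)) # 1-based inclusive
      } else {
        matrix(integer(0), ncol = 2L)
      }
      x <- scrub_motifs(
        x, avoid_motifs,
        protect = matrix(integer(0), ncol = 2L),
        expected_starts = integer(0), max_iter = max_iter
      )
      for (i in seq_len(nrow(pl))) {
        s <- strsplit(pl$seq[[i]], "")[[1L]]
        x[(pl$pos[[i]] + 1L):(pl$pos[[i]] + length(s))] <- s
      }
      x <- scrub_motifs(
        x, avoid_motifs,
        protect = plant_ranges,
        expected_starts = pl$pos + 1L, max_iter = max_iter
      )
      paste(x, collapse = "")
    })
  })
  genome <- Biostrings::DNAStringSet(unlist(chroms))
  names(genome) <- names(chrom_lengths)
  attr(genome, "genome_id") <- paste0("synthetic-seed", seed, "-v1")
  attr(genome, "planted") <- planted
  genome
}

# redraw background bases until no avoided motif matches outside the
# expected planted starts; bases inside `protect` ranges are never touched
scrub_motifs <- function(x, motifs, protect, expected_starts, max_iter) {
  if (length(motifs) == 0L) return(x)
  protected <- rep(FALSE, length(x))
  for (i in seq_len(nrow(protect))) {
    protected[protect[i, 1L]:protect[i, 2L]] <- TRUE
  }
  pats <- unique(unlist(lapply(motifs, function(m) {
    c(toupper(m), iupac_revcomp(m))
  })))
  for (iter in seq_len(max_iter)) {
    s <- Biostrings::DNAString(paste(x, collapse = ""))
    bad <- rep(FALSE, length(x))
    any_bad <- FALSE
    for (p in pats) {
      st <- Biostrings::start(
        Biostrings::matchPattern(p, s, fixed = "subject")
      )
      st <- setdiff(st, expected_starts)
      for (m in st) {
        w <- m:(m + nchar(p) - 1L)
        if (all(protected[w])) {
          stop(
            "planted sequence creates an unexpected motif match that ",
            "cannot be repaired; adjust the fixture spec",
            call. = FALSE
          )
        }
        bad[w[!protected[w]]] <- TRUE
        any_bad <- TRUE
      }
    }
    if (!any_bad) return(x)
    x[bad] <- sample(c("A", "C", "G", "T"), sum(bad), replace = TRUE)
  }
  stop(
    "could not build a motif-free background in ", max_iter,
    " iterations; motif density too high for the sequence length",
    call. = FALSE
  )
}

#' Expected cut sites implied by planted motif instances
#'
#' For a planted tibble (as stored on a [generate_genome()] genome) and one
#' enzyme, returns the ground-truth cut coordinates: a planted instance
#' matching the motif on the top strand cuts at `pos + cut_offset`; one
#' matching the reverse complement (for non-palindromic motifs) cuts at
#' `pos + motif_length - cut_offset`.
#'
#' @param planted Tibble with `chrom`, `pos`, `seq`.
#' @param motif,cut_offset The enzyme's recognition motif and offset.
#' @return Tibble with `chrom`, `cut`, sorted and deduplicated.
#' @export
planted_cuts <- function(planted, motif, cut_offset) {
  motif <- toupper(motif)
  len <- nchar(motif)
  rows <- purrr::pmap(planted, function(chrom, pos, seq) {
    cuts <- integer(0)
    if (nchar(seq) == len) {
      if (iupac_match(motif, seq)) cuts <- c(cuts, pos + cut_offset)
      if (!is_palindromic(motif) && iupac_match(iupac_revcomp(motif), seq)) {
        cuts <- c(cuts, pos + len - cut_offset)
      }
    }
    tibble::tibble(chrom = rep(chrom, length(cuts)), cut = as.integer(cuts))
  })
  dplyr::bind_rows(rows) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$chrom, .data$cut)
}

#' Generate sites of interest with analytically known recovery
#'
#' Places sites relative to a ground-truth fragment set so that the
#' recovery indicator for a declared size window and read length is known
#' by construction, without running the recovery code:
#'
#' * `in-fragment-near-end` — inside an in-window fragment, under
#'   `read_length` bases from its start: recovered (`gamma = 1`).
#' * `in-fragment-center` — at the midpoint of an in-window fragment
#'   longer than twice the read length: not recovered (`gamma = 0`).
#' * `terminal-fragment` — before the first cut of a chromosome: never
#'   recovered (terminal pieces lack a second ligatable end).
#' * `outside` — inside a fragment whose length falls outside the window:
#'   not recovered.
#'
#' @param fragments Ground-truth fragment tibble (e.g.
#'   [build_fragments()] on a planted-cut index).
#' @param chrom_lengths Named lengths of the genome the fragments belong
#'   to (needed for terminal placements).
#' @param lower,breadth The declared size window.
#' @param read_length The declared read length.
#' @param n_per_class Named integer vector; names from the four placement
#'   classes above. Classes with no suitable fragment raise an error.
#' @param weights `"equal"` (all 1) or `"random"` (uniform on (0, 2),
#'   seeded).
#' @param seed Seed for placement choices.
#' @return A site tibble (`site_id`, `chrom`, `coord` 0-based, `weight`)
#'   with extra columns `placement` and `expected_gamma`.
#' @export
generate_sites <- function(fragments, chrom_lengths, lower, breadth,
                           read_length,
                           n_per_class = c(
                             `in-fragment-near-end` = 5L,
                             `in-fragment-center` = 5L,
                             `terminal-fragment` = 5L,
                             `outside` = 5L
                           ),
                           weights = c("equal", "random"),
                           seed = 1L) {
  weights <- match.arg(weights)
  upper <- lower + breadth
  in_win <- fragments[
    fragments$length >= lower & fragments$length <= upper, ,
    drop = FALSE
  ]
  out_win <- fragments[
    fragments$length < lower | fragments$length > upper, ,
    drop = FALSE
  ]
  centerable <- in_win[in_win$length > 2L * read_length, , drop = FALSE]
  withr::with_seed(seed, {
    place <- function(class, n) {
      if (n == 0L) return(NULL)
      coords <- switch(class,
        "in-fragment-near-end" = {
          if (nrow(in_win) == 0L) stop(
            "no in-window fragment for near-end placement", call. = FALSE
          )
          f <- in_win[sample.int(nrow(in_win), n, replace = TRUE), ]
          off <- sample.int(min(read_length, min(f$length)), n,
            replace = TRUE) - 1L
          tibble::tibble(chrom = f$chrom, coord = f$start + off, gamma = 1L)
        },
        "in-fragment-center" = {
          if (nrow(centerable) == 0L) stop(
            "no in-window fragment longer than 2*read_length for ",
            "center placement", call. = FALSE
          )
          f <- centerable[sample.int(nrow(centerable), n, replace = TRUE), ]
          tibble::tibble(
            chrom = f$chrom,
            coord = f$start + f$length %/% 2L,
            gamma = 0L
          )
        },
        "terminal-fragment" = {
          first_cut <- fragments |>
            dplyr::group_by(.data$chrom) |>
            dplyr::summarise(first = min(.data$start))
          ok <- first_cut[first_cut$first > 0L, , drop = FALSE]
          if (nrow(ok) == 0L) stop(
            "no chromosome with a terminal stretch", call. = FALSE
          )
          f <- ok[sample.int(nrow(ok), n, replace = TRUE), ]
          tibble::tibble(
            chrom = f$chrom,
            coord = vapply(f$first, function(fc) {
              sample.int(fc, 1L) - 1L
            }, integer(1)),
            gamma = 0L
          )
        },
        "outside" = {
          big <- out_win[out_win$length >= 1L, , drop = FALSE]
          if (nrow(big) == 0L) stop(
            "no out-of-window fragment for outside placement", call. = FALSE
          )
          f <- big[sample.int(nrow(big), n, replace = TRUE), ]
          tibble::tibble(
            chrom = f$chrom,
            coord = f$start + vapply(f$length, function(l) {
              sample.int(l, 1L) - 1L
            }, integer(1)),
            gamma = 0L
          )
        },
        stop("unknown placement class: ", class, call. = FALSE)
      )
      dplyr::mutate(coords, placement = class)
    }
    sites <- dplyr::bind_rows(
      purrr::imap(as.list(n_per_class), function(n, cls) place(cls, n))
    )
    sites <- sites |>
      dplyr::distinct(.data$chrom, .data$coord, .keep_all = TRUE) |>
      dplyr::mutate(
        site_id = paste0(.data$chrom, ":", .data$coord + 1L),
        weight = if (weights == "equal") {
          1
        } else {
          stats::runif(dplyr::n(), 0, 2)
        }
      )
  })
  dplyr::select(
    sites,
    "site_id", "chrom", "coord", "weight",
    "placement", expected_gamma = "gamma"
  )
}

#' Write a site tibble as a site annotation file
#'
#' Inverse of [read_sites()]: coordinates are written 1-based with a
#' header line.
#'
#' @param sites Site tibble (`site_id`, `chrom`, `coord` 0-based,
#'   `weight`).
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  lines <- c(
    "site_id\tchrom\tcoordinate\tweight",
    paste(sites$site_id, sites$chrom, sites$coord + 1L, sites$weight,
      sep = "\t"
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path (uncompressed FASTA).
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA, dropping unplaced scaffolds on request
#'
#' @param path FASTA path (multi-record, wrapped lines, optionally
#'   gzipped).
#' @param keep_chroms Optional character vector: keep only these records
#'   (unassembled scaffolds are conventionally excluded from digestion).
#' @param genome_id Identifier recorded on the object; defaults to the
#'   file name without extension.
#' @return A named [Biostrings::DNAStringSet] with a `genome_id`
#'   attribute.
#' @export
read_genome_fasta <- function(path, keep_chroms = NULL, genome_id = NULL) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!is.null(keep_chroms)) {
    missing <- setdiff(keep_chroms, names(genome))
    if (length(missing) > 0L) {
      stop("chromosome(s) absent from FASTA: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    genome <- genome[keep_chroms]
  }
  attr(genome, "genome_id") <- genome_id %||%
    sub("\\.(fa|fasta)(\\.gz)?$", "", basename(path))
  genome
}
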