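#' Build restriction fragments from a cut-site index
#'
#' Consecutive cut coordinates on a chromosome delimit the fragments a
#' complete digestion produces. Chromosome-terminal stretches (before the
#' first cut or after the last) are excluded: a sequencing library fragment
#' needs two enzyme-generated ends for adapter ligation, so terminal pieces
#' are never recovered. Chromosomes with fewer than two cuts therefore
#' yield no fragments.
#'
#' @param index A `cut_sites` tibble from [digest_genome()],
#'   [merge_cut_indices()] or [read_precomputed()].
#' @return A tibble with columns `chrom`, `start` (0-based inclusive),
#'   `end` (exclusive) and `length` (bp), ordered by chromosome then start.
#' @export
build_fragments <- function(index) {
  tibble::as_tibble(index) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(
      start = .data$cut[-dplyr::n()],
      end = .data$cut[-1L]
    ) |>
    dplyr::mutate(length = .data$end - .data$start)
}

#' Apply a size-selection window to fragments
#'
#' Models gel excision of fragments whose length lies in the inclusive
#' window `[lower, lower + breadth]`. The count of retained fragments (NF)
#' is the proxy for sequencing cost.
#'
#' @param fragments Fragment tibble from [build_fragments()].
#' @param lower Lower length limit `a` (bp).
#' @param breadth Window breadth `b` (bp); the upper limit is `a + b`,
#'   inclusive.
#' @return The retained fragments, with the fragment count in
#'   `attr(, "nf")`.
#' @export
select_by_size <- function(fragments, lower, breadth) {
  stopifnot(lower >= 0, breadth >= 0)
  sel <- fragments |>
    dplyr::filter(.data$length >= lower, .data$length <= lower + breadth)
  attr(sel, "nf") <- nrow(sel)
  sel
}

#' Read a site-of-interest annotation file
#'
#' Tab-separated columns `site_id`, `chrom`, `coordinate` (1-based, common
#' annotation convention), `weight`; `#` comment lines allowed; a header
#' line is detected and skipped. Coordinates are converted to 0-based
#' internally. For a CpG the coordinate is that of the C on the plus
#' strand. Equal weighting (`w = 1`) is the usual default; weights let the
#' user prioritise sites, e.g. by regression-model coefficients.
#'
#' @param path Path to the site annotation file.
#' @return A tibble with columns `site_id`, `chrom`, `coord` (0-based
#'   integer), `weight`.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("site file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) > 0L && any(lengths(parts) != 4L)) {
    stop("site annotation rows must have 4 tab-separated fields",
      call. = FALSE
    )
  }
  col <- function(i) vapply(parts, `[[`, "", i)
  if (length(parts) > 0L && is.na(suppressWarnings(as.numeric(col(3)[[1]])))) {
    parts <- parts[-1L] # header line
  }
  out <- tibble::tibble(
    site_id = col(1),
    chrom = col(2),
    coord = as.integer(col(3)) - 1L,
    weight = as.numeric(col(4))
  )
  if (anyNA(out$coord) || anyNA(out$weight)) {
    stop("non-numeric coordinate or weight in site file", call. = FALSE)
  }
  if (any(out$weight < 0)) stop("negative site weight", call. = FALSE)
  if (anyDuplicated(out$site_id)) {
    stop("duplicated site_id in site file", call. = FALSE)
  }
  out
}

#' Which sites of interest would be sequenced?
#'
#' A site is theoretically sequenced (indicator `gamma = 1`) when it falls
#' inside a size-selected fragment and within `read_length` bases of one of
#' the fragment's ends, so that a read started from either end covers it.
#' For a fragment `[s, e)` and 0-based site coordinate `p` the condition is
#' `s <= p < e` and (`p - s < read_length` or `e - p <= read_length`): each
#' read covers exactly `read_length` bases from its end in half-open
#' coordinates.
#'
#' @param selected Size-selected fragment tibble (non-overlapping per
#'   chromosome), e.g. from [select_by_size()].
#' @param sites Site tibble from [read_sites()] (0-based `coord`).
#' @param read_length Read length `r` in bp (`>= 1`).
#' @return The `sites` tibble with an added integer column `gamma`.
#'   Sites on chromosomes absent from the fragments get `gamma = 0`
#'   (with a warning for unknown chromosomes).
#' @export
recovered_sites <- function(selected, sites, read_length) {
  stopifnot(read_length >= 1)
  unknown <- setdiff(unique(sites$chrom), unique(selected$chrom))
  if (length(unknown) > 0L && nrow(selected) > 0L) {
    warning(
      "site(s) on chromosome(s) without selected fragments: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  gamma <- integer(nrow(sites))
  for (ch in intersect(unique(sites$chrom), unique(selected$chrom))) {
    fr <- selected[selected$chrom == ch, , drop = FALSE]
    fr <- fr[order(fr$start), , drop = FALSE]
    idx <- which(sites$chrom == ch)
    p <- sites$coord[idx]
    k <- findInterval(p, fr$start)
    inside <- k >= 1L & p < fr$end[pmax(k, 1L)]
    s <- fr$start[pmax(k, 1L)]
    e <- fr$end[pmax(k, 1L)]
    near <- (p - s < read_length) | (e - p <= read_length)
    gamma[idx] <- as.integer(inside & near)
  }
  dplyr::mutate(sites, gamma = gamma)
}

#' Export fragments as BED intervals
#'
#' @param fragments Fragment tibble.
#' @param path Output path (0-based half-open BED).
#' @export
write_fragment_bed <- function(fragments, path) {
  utils::write.table(
    fragments[c("chrom", "start", "end")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
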