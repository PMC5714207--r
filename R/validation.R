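#' Read an observed-sites file
#'
#' Tab-separated `site_id`, `depth` (reads covering the site, e.g. from a
#' Bismark cytosine report aggregated per site). `#` comments allowed; a
#' non-numeric second field on the first row is treated as a header.
#'
#' @param path Path to the file.
#' @return A tibble with columns `site_id`, `depth` (integer `>= 1`).
#' @export
read_observed_sites <- function(path) {
  if (!file.exists(path)) stop("observed-sites file not found: ", path,
    call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("observed-sites rows must have 2 tab-separated fields",
      call. = FALSE)
  }
  if (length(parts) > 0L &&
      is.na(suppressWarnings(as.integer(parts[[1L]][[2L]])))) {
    parts <- parts[-1L]
  }
  out <- tibble::tibble(
    site_id = vapply(parts, `[[`, "", 1L),
    depth = as.integer(vapply(parts, `[[`, "", 2L))
  )
  if (anyNA(out$depth) || any(out$depth < 1L)) {
    stop("observed depths must be integers >= 1", call. = FALSE)
  }
  out
}

#' Confusion counts of predicted versus observed site recovery
#'
#' Compares the sites a protocol is predicted to sequence against the
#' sites actually observed in an experiment at a minimum depth of
#' coverage. Over the site universe: true positives are predicted and
#' observed, false positives predicted but not observed, false negatives
#' observed but not predicted, true negatives neither.
#'
#' @param universe Character vector of all site IDs under consideration.
#' @param predicted Character vector of site IDs predicted to be
#'   sequenced (must be a subset of `universe`).
#' @param observed Tibble from [read_observed_sites()]; IDs outside the
#'   universe are dropped with a warning.
#' @param min_depth Minimum read depth for a site to count as observed.
#' @return A tibble row with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(universe, predicted, observed, min_depth = 1L) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty site universe", call. = FALSE)
  predicted <- unique(predicted)
  if (!all(predicted %in% universe)) {
    stop("predicted sites must be a subset of the universe", call. = FALSE)
  }
  stray <- setdiff(observed$site_id, universe)
  if (length(stray) > 0L) {
    warning(
      length(stray), " observed site(s) outside the universe dropped",
      call. = FALSE
    )
    observed <- observed[observed$site_id %in% universe, , drop = FALSE]
  }
  obs <- unique(observed$site_id[observed$depth >= min_depth])
  tibble::tibble(
    tp = length(intersect(predicted, obs)),
    fp = length(setdiff(predicted, obs)),
    fn = length(setdiff(obs, predicted)),
    tn = length(setdiff(universe, union(predicted, obs)))
  )
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP / (TP + FN) * 100`;
#' `specificity = TN / (FP + TN) * 100`. A zero denominator yields
#' `NA_real_` (undefined, reported as missing).
#'
#' @param counts A tibble row with `tp`, `tn`, `fp`, `fn`.
#' @return A percentage in `[0, 100]`, or `NA_real_`.
#' @export
sensitivity <- function(counts) {
  d <- counts$tp + counts$fn
  ifelse(d > 0, counts$tp / d * 100, NA_real_)
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  d <- counts$fp + counts$tn
  ifelse(d > 0, counts$tn / d * 100, NA_real_)
}

#' Prediction performance as a function of coverage threshold
#'
#' Recomputes the confusion counts, sensitivity and specificity at each
#' depth-of-coverage threshold. As the threshold rises the observed set
#' shrinks, so `tp + fn` is non-increasing.
#'
#' @inheritParams confusion
#' @param depth_thresholds Integer vector of thresholds, sorted ascending.
#' @return A tibble with one row per threshold: `min_depth`, `tp`, `fp`,
#'   `fn`, `tn`, `sensitivity`, `specificity`.
#' @export
metric_curve <- function(universe, predicted, observed, depth_thresholds) {
  stopifnot(!is.unsorted(depth_thresholds))
  purrr::map_dfr(depth_thresholds, function(d) {
    cc <- suppressWarnings(confusion(universe, predicted, observed, d))
    dplyr::mutate(
      cc,
      min_depth = d,
      sensitivity = sensitivity(cc),
      specificity = specificity(cc),
      .before = 1L
    )
  })
}
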