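#' Candidate size-selection windows at the experimental-error resolution
#'
#' Because gel excision is imperfect to within the experimental error
#' `delta`, size ranges are sampled on a grid whose resolution equals
#' `delta`: lower limits `min_lower, min_lower + delta, ...` up to
#' `max_lower`, crossed with breadths `delta, 2 delta, ...` up to
#' `max_breadth`. Finer sampling would distinguish windows the experiment
#' cannot realise.
#'
#' @param delta Grid resolution / experimental error (bp, `>= 1`).
#' @param max_breadth Largest breadth sampled (bp).
#' @param min_lower,max_lower Bounds on the window lower limit (bp).
#' @return A tibble with columns `lower` and `breadth`, in deterministic
#'   order (lower ascending, then breadth ascending).
#' @export
candidate_ranges <- function(delta, max_breadth, min_lower, max_lower) {
  stopifnot(delta >= 1)
  if (max_lower < min_lower || max_breadth < delta) {
    stop("empty size-range grid", call. = FALSE)
  }
  lowers <- seq(min_lower, max_lower, by = delta)
  breadths <- seq(delta, max_breadth, by = delta)
  tidyr::expand_grid(lower = as.integer(lowers), breadth = as.integer(breadths))
}

# Per-site fragment context: length of the containing fragment (NA when the
# site is not inside any fragment) and whether the site lies within
# read_length of a fragment end. Both are independent of the size window,
# so a site's recovery under window [a, a+b] reduces to
# eligible && a <= frag_length <= a + b.
site_fragment_context <- function(fragments, sites, read_length) {
  frag_length <- rep(NA_integer_, nrow(sites))
  eligible <- rep(FALSE, nrow(sites))
  for (ch in intersect(unique(sites$chrom), unique(fragments$chrom))) {
    fr <- fragments[fragments$chrom == ch, , drop = FALSE]
    fr <- fr[order(fr$start), , drop = FALSE]
    idx <- which(sites$chrom == ch)
    p <- sites$coord[idx]
    k <- findInterval(p, fr$start)
    kk <- pmax(k, 1L)
    inside <- k >= 1L & p < fr$end[kk]
    near <- (p - fr$start[kk] < read_length) | (fr$end[kk] - p <= read_length)
    frag_length[idx[inside]] <- fr$length[kk][inside]
    eligible[idx] <- inside & near
  }
  dplyr::mutate(sites, frag_length = frag_length, eligible = eligible)
}

#' Evaluate NF, Score and EV over a set of size windows
#'
#' Computes, for every candidate window, the number of selected fragments
#' (NF), the weighted recovery score, the enrichment value, and whether the
#' window passes the Score and NF thresholds. The sweep uses sorted
#' fragment lengths and cumulative site weights, so each window costs two
#' binary searches rather than a fresh pass over the fragments.
#'
#' @param fragments Fragment tibble from [build_fragments()].
#' @param sites Site tibble (0-based `coord`, `weight`).
#' @param ranges Window tibble (`lower`, `breadth`), e.g. from
#'   [candidate_ranges()].
#' @param config An [run_config()] object (uses `read_length`,
#'   `score_threshold`, `nf_constant`, `genome_size`).
#' @return `ranges` with added columns `nf`, `score`, `ev`, `pass_score`,
#'   `pass_nf`, `pass`.
#' @export
range_metrics <- function(fragments, sites, ranges, config) {
  ctx <- site_fragment_context(fragments, sites, config$read_length)
  n <- nrow(sites)
  max_score <- sum(sites$weight)
  frag_sorted <- sort(fragments$length)
  elig <- ctx[ctx$eligible, , drop = FALSE]
  ord <- order(elig$frag_length)
  elig_len <- elig$frag_length[ord]
  elig_cumw <- cumsum(elig$weight[ord])
  count_le <- function(x, v) findInterval(x, v)
  wsum_le <- function(x) {
    i <- findInterval(x, elig_len)
    ifelse(i == 0L, 0, elig_cumw[pmax(i, 1L)])
  }
  upper <- ranges$lower + ranges$breadth
  nf <- count_le(upper, frag_sorted) - count_le(ranges$lower - 1L, frag_sorted)
  score <- wsum_le(upper) - wsum_le(ranges$lower - 1L)
  ev <- ifelse(
    nf > 0 & score > 0,
    -log10((score / nf) * (n / max_score)),
    NA_real_
  )
  nf_max <- config$nf_constant * genome_size_of(config, fragments) / 1000
  dplyr::mutate(
    ranges,
    nf = as.integer(nf),
    score = score,
    ev = ev,
    pass_score = score >= config$score_threshold * max_score - 1e-12,
    pass_nf = nf <= nf_max,
    pass = .data$pass_score & .data$pass_nf
  )
}

genome_size_of <- function(config, fragments = NULL) {
  g <- config$genome_size
  if (is.null(g)) {
    stop(
      "genome_size is not set in the run configuration; ",
      "pass it to run_config() or let run_search() derive it from the genome",
      call. = FALSE
    )
  }
  g
}

#' Evaluate one enzyme (or enzyme pair) across all candidate windows
#'
#' Merges the cut indices of a pair into a double digestion, builds the
#' fragments once, sweeps every candidate window, discards windows failing
#' the Score threshold (`Score >= c * max_Score`) or the NF ceiling
#' (`NF <= k * g / 1000`), and returns the surviving window with the lowest
#' EV, annotated with CRF and robustness. Ties in EV (within 1e-12) are
#' broken by smaller lower limit, then smaller breadth.
#'
#' @param indices List of one or two `cut_sites` tibbles.
#' @param sites Site tibble.
#' @param config An [run_config()] object with `genome_size` set.
#' @return A one-row tibble (`enzymes`, `lower`, `breadth`, `nf`, `score`,
#'   `max_score`, `n_sites`, `ev`, `crf`, `robustness`), or `NULL` when no
#'   window survives the thresholds.
#' @export
evaluate_combination <- function(indices, sites, config) {
  index <- if (length(indices) == 2L) {
    merge_cut_indices(indices[[1L]], indices[[2L]])
  } else {
    indices[[1L]]
  }
  fragments <- build_fragments(index)
  ranges <- if (!is.null(config$fixed_range)) {
    tibble::tibble(
      lower = as.integer(config$fixed_range[[1L]]),
      breadth = as.integer(config$fixed_range[[2L]])
    )
  } else {
    candidate_ranges(
      config$experimental_error, config$max_breadth,
      config$min_lower, config$max_lower
    )
  }
  metrics <- range_metrics(fragments, sites, ranges, config)
  surv <- metrics[metrics$pass & !is.na(metrics$ev), , drop = FALSE]
  if (nrow(surv) == 0L) return(NULL)
  best_ev <- min(surv$ev)
  best <- surv[surv$ev <= best_ev + 1e-12, , drop = FALSE][1L, , drop = FALSE]
  ev_at <- function(lower, breadth) {
    m <- range_metrics(
      fragments, sites,
      tibble::tibble(lower = lower, breadth = breadth), config
    )
    m$ev
  }
  tibble::tibble(
    enzymes = attr(index, "family_id"),
    lower = best$lower,
    breadth = best$breadth,
    nf = best$nf,
    score = best$score,
    max_score = sum(sites$weight),
    n_sites = nrow(sites),
    ev = best$ev,
    crf = cost_reduction_factor(
      best$nf, genome_size_of(config), config$read_length
    ),
    robustness = robustness(
      ev_at, best$lower, best$breadth, config$experimental_error
    )
  )
}

#' Search all single enzymes and enzyme pairs for the best protocols
#'
#' Digests the genome once per isoschizomer family, then evaluates every
#' single family and every unordered pair of families (a double digestion)
#' across the full size-window grid, ranks the surviving protocols by EV
#' (ascending; ties broken by robustness descending, NF ascending, then
#' enzyme names), and keeps the top `output_size`.
#'
#' @param families Family tibble from [enzyme_families()] or
#'   [filter_families()].
#' @param sites Site tibble from [read_sites()].
#' @param genome Named [Biostrings::DNAStringSet] or named character
#'   vector; used to digest and, when `config$genome_size` is `NULL`, to
#'   set the genome size.
#' @param config An [run_config()] object.
#' @param indices Optional pre-computed list of `cut_sites` tibbles named
#'   by `family_id` (e.g. loaded with [read_precomputed()]); families
#'   missing from the list are digested from `genome`.
#' @return An object of class `rrbs_search`: a list with `protocols` (the
#'   ranked tibble, one row per reported protocol, including the
#'   experimental size range with adapters added), `config`,
#'   `n_combinations`, `n_passing`. Supports [generics::tidy()],
#'   [generics::glance()], `print()` and [ggplot2::autoplot()].
#' @export
run_search <- function(families, sites, genome, config, indices = NULL) {
  stopifnot(nrow(families) > 0L, nrow(sites) > 0L)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (is.null(config$genome_size)) {
    config$genome_size <- sum(Biostrings::width(genome))
  }
  fam_ids <- families$family_id
  idx <- purrr::map(seq_len(nrow(families)), function(i) {
    fid <- fam_ids[[i]]
    if (!is.null(indices) && fid %in% names(indices)) {
      return(indices[[fid]])
    }
    digest_genome(genome, families[i, , drop = FALSE])
  })
  names(idx) <- fam_ids
  combos <- as.list(fam_ids)
  if (length(fam_ids) >= 2L) {
    combos <- c(combos, utils::combn(sort(fam_ids), 2L, simplify = FALSE))
  }
  rows <- purrr::map(combos, function(fids) {
    evaluate_combination(idx[fids], sites, config)
  })
  protocols <- dplyr::bind_rows(rows)
  n_passing <- nrow(protocols)
  if (n_passing == 0L) {
    message(
      "no enzyme combination passes the Score and NF thresholds; ",
      "consider lowering score_threshold or raising nf_constant"
    )
    protocols <- empty_protocols()
  } else {
    protocols <- rank_protocols(protocols) |>
      utils::head(config$output_size) |>
      dplyr::mutate(
        exp_lower = .data$lower + config$adapters_size,
        exp_upper = .data$lower + .data$breadth + config$adapters_size
      )
    if (config$emit_site_ids) {
      protocols$site_ids <- purrr::pmap(
        protocols[c("enzymes", "lower", "breadth")],
        function(enzymes, lower, breadth) {
          fids <- strsplit(enzymes, "+", fixed = TRUE)[[1]]
          index <- if (length(fids) == 2L) {
            merge_cut_indices(idx[[fids[[1]]]], idx[[fids[[2]]]])
          } else {
            idx[[fids]]
          }
          sel <- select_by_size(build_fragments(index), lower, breadth)
          rec <- recovered_sites(sel, sites, config$read_length)
          rec$site_id[rec$gamma == 1L]
        }
      )
    }
  }
  structure(
    list(
      protocols = protocols,
      config = config,
      n_combinations = length(combos),
      n_passing = n_passing
    ),
    class = "rrbs_search"
  )
}

empty_protocols <- function() {
  tibble::tibble(
    rank = integer(0), enzymes = character(0),
    lower = integer(0), breadth = integer(0),
    nf = integer(0), score = double(0), max_score = double(0),
    n_sites = integer(0), ev = double(0), crf = double(0),
    robustness = double(0), exp_lower = integer(0), exp_upper = integer(0)
  )
}

# EV ascending with a 1e-12 absolute tolerance grouping, then robustness
# descending, NF ascending, enzyme names lexicographic — deterministic
# across platforms
rank_protocols <- function(protocols) {
  p <- dplyr::arrange(protocols, .data$ev)
  grp <- cumsum(c(1, diff(p$ev) > 1e-12))
  p |>
    dplyr::mutate(.ev_grp = grp) |>
    dplyr::arrange(
      .data$.ev_grp, dplyr::desc(.data$robustness),
      .data$nf, .data$enzymes
    ) |>
    dplyr::select(-".ev_grp") |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1L)
}

#' @export
print.rrbs_search <- function(x, ...) {
  cat(
    "<rrbs_search> ", x$n_combinations, " combinations evaluated, ",
    x$n_passing, " passed thresholds; reporting ",
    nrow(x$protocols), " protocol(s)\n",
    sep = ""
  )
  print(x$protocols, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the ranked protocol table of a search
#'
#' @param x An `rrbs_search` object.
#' @param ... Unused.
#' @return The ranked protocol tibble.
#' @method tidy rrbs_search
#' @export
tidy.rrbs_search <- function(x, ...) x$protocols

#' One-row summary of a protocol search
#'
#' @param x An `rrbs_search` object.
#' @param ... Unused.
#' @return A one-row tibble: combinations evaluated, combinations passing
#'   the thresholds, and the best protocol's EV, NF and CRF (`NA` when
#'   nothing passed).
#' @method glance rrbs_search
#' @export
glance.rrbs_search <- function(x, ...) {
  p <- x$protocols
  tibble::tibble(
    n_combinations = x$n_combinations,
    n_passing = x$n_passing,
    best_ev = if (nrow(p)) p$ev[[1L]] else NA_real_,
    best_nf = if (nrow(p)) p$nf[[1L]] else NA_integer_,
    best_crf = if (nrow(p)) p$crf[[1L]] else NA_real_
  )
}

#' Write / read a protocol report file
#'
#' Tab-separated table of the ranked protocols with a `#` header recording
#' every configuration parameter, so a report is self-describing and
#' reproducible. Size ranges are printed as `lower-upper` (bp, inclusive),
#' both theoretical and experimental (adapters added). CRF is printed to 1
#' decimal place; EV and robustness to 6.
#'
#' @param result An `rrbs_search` object.
#' @param path Output path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns a tibble of the data rows with numeric columns restored.
#' @export
write_report <- function(result, path) {
  cfg <- result$config
  hdr <- vapply(
    names(unclass(cfg)),
    function(nm) {
      v <- cfg[[nm]]
      paste0("#", nm, "=", if (is.null(v)) "NA" else paste(v, collapse = ","))
    },
    ""
  )
  p <- result$protocols
  cols <- c(
    "rank", "enzymes", "theoretical_range", "experimental_range",
    "nf", "score", "max_score", "ev", "crf", "robustness"
  )
  has_ids <- "site_ids" %in% names(p)
  if (has_ids) cols <- c(cols, "site_ids")
  lines <- c(hdr, paste(cols, collapse = "\t"))
  if (nrow(p) > 0L) {
    body <- tibble::tibble(
      rank = p$rank,
      enzymes = p$enzymes,
      theoretical_range = paste0(p$lower, "-", p$lower + p$breadth),
      experimental_range = paste0(p$exp_lower, "-", p$exp_upper),
      nf = p$nf,
      score = format(p$score, digits = 15, trim = TRUE, scientific = FALSE),
      max_score = format(
        p$max_score, digits = 15, trim = TRUE, scientific = FALSE
      ),
      ev = formatC(p$ev, digits = 6, format = "f"),
      crf = formatC(p$crf, digits = 1, format = "f"),
      robustness = ifelse(
        is.na(p$robustness), "NA",
        formatC(p$robustness, digits = 6, format = "f")
      )
    )
    if (has_ids) {
      body$site_ids <- vapply(
        p$site_ids, function(ids) paste(ids, collapse = ","), ""
      )
    }
    lines <- c(
      lines,
      do.call(paste, c(as.list(body), sep = "\t"))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data <- lines[!grepl("^#", lines)]
  header <- strsplit(data[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(data) == 1L) {
    out <- tibble::as_tibble(
      stats::setNames(rep(list(character(0)), length(header)), header)
    )
    return(out)
  }
  parts <- strsplit(data[-1L], "\t", fixed = TRUE)
  out <- tibble::as_tibble(
    stats::setNames(
      lapply(seq_along(header), function(i) vapply(parts, `[[`, "", i)),
      header
    )
  )
  num_cols <- intersect(
    c("rank", "nf", "score", "max_score", "ev", "crf", "robustness"),
    names(out)
  )
  out[num_cols] <- lapply(out[num_cols], function(x) {
    suppressWarnings(as.numeric(x))
  })
  out
}
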