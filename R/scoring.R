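#' Weighted recovery score
#'
#' `Score = sum(w_i * gamma_i)` over the sites of interest; `max_Score`
#' (`sum(w_i)`) is the score attained if every site were sequenced.
#'
#' @param gamma 0/1 recovery indicator per site.
#' @param weights Non-negative weight per site (same length).
#' @return A list with `score` and `max_score`.
#' @export
compute_score <- function(gamma, weights) {
  if (length(gamma) != length(weights)) {
    stop("gamma and weights lengths differ", call. = FALSE)
  }
  if (any(weights < 0)) stop("negative site weight", call. = FALSE)
  list(score = sum(weights * gamma), max_score = sum(weights))
}

#' Enrichment value of a candidate protocol
#'
#' `EV = -log10((Score / NF) * (n / max_Score))` balances recovering a
#' large fraction of the sites of interest (high `Score / max_Score`)
#' against sequencing few fragments (low `NF / n`). Lower is better; the
#' optimal protocol minimises EV. When `NF = 0` or `Score = 0` the EV is
#' undefined and returned as `NA`; such protocols compare as worse than any
#' defined EV.
#'
#' @param score Weighted recovery score.
#' @param nf Number of size-selected fragments.
#' @param n Total number of sites of interest.
#' @param max_score Sum of all site weights.
#' @return EV as a double, or `NA_real_` when undefined.
#' @export
#' @examples
#' enrichment_value(score = 2, nf = 100, n = 4, max_score = 4) # -log10(0.02)
enrichment_value <- function(score, nf, n, max_score) {
  stopifnot(n > 0, max_score > 0)
  if (nf <= 0 || score <= 0) return(NA_real_)
  -log10((score / nf) * (n / max_score))
}

#' Cost reduction factor versus whole-genome bisulfite sequencing
#'
#' `CRF = NF_ref / NF = (g / r) / NF`, where `g / r` approximates the
#' number of fragments a WGBS experiment would sequence for genome size `g`
#' and read length `r`. Assuming sequencing cost proportional to the number
#' of fragments, CRF is the fold reduction in cost.
#'
#' @param nf Number of size-selected fragments.
#' @param g Genome size (bp).
#' @param r Read length (bp).
#' @return CRF as a double (full precision), `NA_real_` when `nf = 0`.
#' @export
#' @examples
#' cost_reduction_factor(nf = 1e5, g = 3e9, r = 75) # 400
cost_reduction_factor <- function(nf, g, r) {
  stopifnot(g > 0, r > 0)
  if (nf <= 0) return(NA_real_)
  (g / r) / nf
}

#' Robustness of a protocol to size-selection error
#'
#' Gel excision is imperfect: the realised window may be displaced from the
#' chosen one by up to the experimental error `delta`. Robustness samples
#' the EV landscape on the 3x3 stencil
#' `{a - delta, a, a + delta} x {b - delta, b, b + delta}` around the
#' optimum `(a, b)` and summarises the relative deviation
#' `theta = sum(|EV_xy - EV_ab|) / EV_ab`; `R = exp(-theta)` lies in
#' `(0, 1]`, with 1 meaning the enrichment is unaffected by excision error.
#'
#' A neighbour whose EV is undefined (empty window) contributes a full
#' relative deviation of 1, penalising fragile optima near empty ranges
#' while keeping `theta` finite. Neighbour lower limits below 1 bp are
#' clamped to 1 bp so the stencil always has nine points. If `EV_ab` is
#' undefined or non-positive, robustness is undefined (`NA`).
#'
#' @param ev_at Function `(lower, breadth) -> EV` evaluating the landscape.
#' @param lower,breadth The optimal window `(a, b)`.
#' @param delta Experimental size-selection error (bp).
#' @return Robustness in `(0, 1]`, or `NA_real_` when undefined.
#' @export
robustness <- function(ev_at, lower, breadth, delta) {
  ev0 <- ev_at(lower, breadth)
  if (is.na(ev0) || ev0 <= 0) return(NA_real_)
  xs <- pmax(c(lower - delta, lower, lower + delta), 1)
  ys <- pmax(c(breadth - delta, breadth, breadth + delta), 0)
  theta <- 0
  for (x in xs) {
    for (y in ys) {
      ev <- ev_at(x, y)
      dev <- if (is.na(ev)) 1 else abs(ev - ev0) / ev0
      theta <- theta + dev
    }
  }
  exp(-theta)
}

#' Run configuration for a protocol search
#'
#' Bundles the user-tunable parameters of a search with their defaults.
#'
#' @param read_length Read length `r` in bp (typical range 30-300). Sets
#'   which positions in a fragment a read can see.
#' @param adapters_size Adapter length `s` in bp added to each reported
#'   experimental size range, so that gel excision selects the right
#'   molecules after ligation.
#' @param score_threshold Fraction `c` in `[0, 1]`: candidate windows must
#'   recover at least `c * max_Score`.
#' @param genome_size Genome size `g` in bp; needed for CRF and the NF
#'   ceiling. Defaults to the total length of the supplied genome.
#' @param nf_constant Constant `k` in `[0, 1]` (default 0.2): candidate
#'   windows must keep `NF <= k * g / 1000`, equivalently a minimum CRF of
#'   `1000 / (k * r)`.
#' @param experimental_error Assumed gel-excision error `delta` in bp
#'   (default 20, typical range 5-500); also the grid resolution of the
#'   size-range search.
#' @param max_breadth Maximum window breadth in bp (default 980).
#' @param output_size Number of protocols reported (default 30).
#' @param emit_site_ids If `TRUE`, attach recovered site IDs to each
#'   reported protocol.
#' @param min_lower,max_lower Grid bounds for the window lower limit (bp);
#'   defaults 20 and 1000 (mappable-fragment heuristic).
#' @param fixed_range Optional `c(lower, breadth)`: bypass the grid and
#'   evaluate exactly this window (validation mode).
#' @return A list of class `rrbs_config`.
#' @export
run_config <- function(read_length,
                       adapters_size = 0L,
                       score_threshold = 0.25,
                       genome_size = NULL,
                       nf_constant = 0.2,
                       experimental_error = 20L,
                       max_breadth = 980L,
                       output_size = 30L,
                       emit_site_ids = FALSE,
                       min_lower = 20L,
                       max_lower = 1000L,
                       fixed_range = NULL) {
  stopifnot(
    read_length >= 1,
    adapters_size >= 0,
    score_threshold >= 0, score_threshold <= 1,
    nf_constant >= 0, nf_constant <= 1,
    experimental_error >= 1,
    max_breadth >= experimental_error,
    output_size >= 1,
    min_lower >= 1, max_lower >= min_lower
  )
  if (!is.null(fixed_range)) {
    stopifnot(length(fixed_range) == 2L, fixed_range[[1]] >= 1,
      fixed_range[[2]] >= 0)
  }
  structure(
    list(
      read_length = as.integer(read_length),
      adapters_size = as.integer(adapters_size),
      score_threshold = score_threshold,
      genome_size = genome_size,
      nf_constant = nf_constant,
      experimental_error = as.integer(experimental_error),
      max_breadth = as.integer(max_breadth),
      output_size = as.integer(output_size),
      emit_site_ids = isTRUE(emit_site_ids),
      min_lower = as.integer(min_lower),
      max_lower = as.integer(max_lower),
      fixed_range = fixed_range
    ),
    class = "rrbs_config"
  )
}

#' @export
print.rrbs_config <- function(x, ...) {
  cat("<rrbs_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(
      " ", format(nm, width = 18),
      if (is.null(v)) "<genome total>" else paste(v, collapse = ","), "\n"
    )
  }
  invisible(x)
}
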