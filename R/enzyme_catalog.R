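#' Read a restriction-enzyme annotation file
#'
#' Parses a comma- or tab-separated enzyme annotation with a header line and
#' columns `enzyme_name`, `motif`, `cut_offset`, `cpg_sensitive`,
#' `chg_sensitive`, `chh_sensitive`, `family_id`. Enzymes sharing a
#' `family_id` form an isoschizomer family: they must share an identical
#' recognition motif and cut offset, since isoschizomers generate identical
#' fragment length distributions and only one member per family is ever
#' digested.
#'
#' Only Type IIP-style enzymes cutting once inside (or immediately adjacent
#' to) their recognition motif are supported: `cut_offset` counts the bases
#' 5' of the top-strand cut within the motif and must lie in
#' `[1, nchar(motif)]`. Sensitivity flags accept `yes/no`, `true/false`,
#' `1/0` (case-insensitive).
#'
#' @param path Path to the annotation file. Lines starting with `#` are
#'   ignored.
#' @return A tibble with one row per enzyme and columns `enzyme_name`,
#'   `motif`, `cut_offset` (integer), `cpg_sensitive`, `chg_sensitive`,
#'   `chh_sensitive` (logical), `family_id`.
#' @seealso [enzyme_families()], [filter_families()]
#' @export
#' @examples
#' cat_file <- system.file("extdata", "mini_enzyme_catalog.tsv",
#'   package = "rrbsdesign")
#' read_enzyme_catalog(cat_file)
read_enzyme_catalog <- function(path) {
  if (!file.exists(path)) {
    stop("enzyme annotation file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) {
    stop("enzyme annotation file has no data rows: ", path, call. = FALSE)
  }
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  split_row <- function(x) trimws(strsplit(x, sep, fixed = TRUE)[[1]])
  header <- tolower(split_row(lines[[1]]))
  required <- c(
    "enzyme_name", "motif", "cut_offset",
    "cpg_sensitive", "chg_sensitive", "chh_sensitive", "family_id"
  )
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0L) {
    stop(
      "enzyme annotation header lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    fields <- split_row(lines[[i]])
    if (length(fields) != length(header)) {
      stop(
        "malformed enzyme annotation line ", lineno[[i]],
        ": expected ", length(header), " fields, found ", length(fields),
        call. = FALSE
      )
    }
    stats::setNames(as.list(fields), header)
  })
  tbl <- dplyr::bind_rows(rows)
  out <- tibble::tibble(
    enzyme_name = tbl$enzyme_name,
    motif = toupper(tbl$motif),
    cut_offset = suppressWarnings(as.integer(tbl$cut_offset)),
    cpg_sensitive = parse_flag(tbl$cpg_sensitive, "cpg_sensitive"),
    chg_sensitive = parse_flag(tbl$chg_sensitive, "chg_sensitive"),
    chh_sensitive = parse_flag(tbl$chh_sensitive, "chh_sensitive"),
    family_id = tbl$family_id
  )
  validate_enzyme_table(out)
  out
}

# {yes,no,true,false,0,1}, case-insensitive -> logical
parse_flag <- function(x, what) {
  x <- tolower(trimws(x))
  out <- dplyr::case_match(
    x,
    c("yes", "true", "1") ~ TRUE,
    c("no", "false", "0") ~ FALSE,
    .default = NA
  )
  if (anyNA(out)) {
    stop(
      "unparseable ", what, " flag value(s): ",
      paste(unique(x[is.na(out)]), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

iupac_alphabet <- c(
  "A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N"
)

validate_enzyme_table <- function(x) {
  bad_motif <- !vapply(
    strsplit(x$motif, ""),
    function(ch) all(ch %in% iupac_alphabet),
    logical(1)
  )
  if (any(bad_motif)) {
    stop(
      "non-IUPAC recognition motif for enzyme(s): ",
      paste(x$enzyme_name[bad_motif], collapse = ", "),
      call. = FALSE
    )
  }
  bad_off <- is.na(x$cut_offset) |
    x$cut_offset < 1L | x$cut_offset > nchar(x$motif)
  if (any(bad_off)) {
    stop(
      "cut_offset out of bounds (must be in [1, motif length]) for: ",
      paste(x$enzyme_name[bad_off], collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(x$enzyme_name)) {
    stop("duplicated enzyme names in annotation", call. = FALSE)
  }
  invisible(x)
}

#' Group an enzyme table into isoschizomer families
#'
#' Isoschizomers recognise the same sequence and cut at the same offset, so
#' every member of a family produces the same in silico digestion. Each
#' family is represented by its lexicographically first member; digestion
#' output is identical whichever member is chosen.
#'
#' @param enzymes A tibble as returned by [read_enzyme_catalog()].
#' @return A tibble with one row per family, ordered by `family_id`, and
#'   columns `family_id`, `motif`, `cut_offset`, `representative`,
#'   `members` (list-column of member name vectors), `n_members`, and the
#'   three `any_*_insensitive` flags used by [filter_families()].
#' @export
enzyme_families <- function(enzymes) {
  stopifnot(is.data.frame(enzymes))
  if (nrow(enzymes) == 0L) {
    return(tibble::tibble(
      family_id = character(0), motif = character(0),
      cut_offset = integer(0), representative = character(0),
      members = list(), n_members = integer(0),
      any_cpg_insensitive = logical(0), any_chg_insensitive = logical(0),
      any_chh_insensitive = logical(0)
    ))
  }
  fam <- enzymes |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      motif = unique_or_fail(.data$motif, .data$family_id[[1]], "motif"),
      cut_offset = unique_or_fail(
        .data$cut_offset, .data$family_id[[1]], "cut_offset"
      ),
      representative = sort(.data$enzyme_name)[[1]],
      members = list(sort(.data$enzyme_name)),
      n_members = dplyr::n(),
      any_cpg_insensitive = any(!.data$cpg_sensitive),
      any_chg_insensitive = any(!.data$chg_sensitive),
      any_chh_insensitive = any(!.data$chh_sensitive),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$family_id)
  fam
}

unique_or_fail <- function(x, family, what) {
  u <- unique(x)
  if (length(u) != 1L) {
    stop(
      "family ", family, " members disagree on ", what, ": ",
      paste(u, collapse = " vs "),
      call. = FALSE
    )
  }
  u
}

#' Filter isoschizomer families by methylation insensitivity
#'
#' Digestion-based enrichment of methylated sites must not depend on the
#' methylation state being measured, so only families containing at least
#' one enzyme insensitive to cytosine methylation in every requested context
#' are retained. The family representative is recomputed among the
#' qualifying (insensitive-in-all-requested-contexts) members.
#'
#' @param enzymes Enzyme tibble from [read_enzyme_catalog()].
#' @param contexts Character subset of `c("CpG", "CHG", "CHH")`.
#' @return A family tibble (as [enzyme_families()]) restricted to qualifying
#'   families, with `representative`/`members` recomputed over qualifying
#'   enzymes.
#' @export
filter_families <- function(enzymes, contexts = "CpG") {
  contexts <- match.arg(contexts, c("CpG", "CHG", "CHH"), several.ok = TRUE)
  if (length(contexts) == 0L) stop("contexts must be non-empty", call. = FALSE)
  ok <- rep(TRUE, nrow(enzymes))
  if ("CpG" %in% contexts) ok <- ok & !enzymes$cpg_sensitive
  if ("CHG" %in% contexts) ok <- ok & !enzymes$chg_sensitive
  if ("CHH" %in% contexts) ok <- ok & !enzymes$chh_sensitive
  out <- enzyme_families(enzymes[ok, , drop = FALSE])
  if (nrow(out) == 0L) {
    warning(
      "no isoschizomer family is insensitive in context(s): ",
      paste(contexts, collapse = ", "),
      call. = FALSE
    )
  }
  out
}
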