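# shared in-code fixtures

mini_catalog_path <- function() {
  system.file("extdata", "mini_enzyme_catalog.tsv", package = "rrbsdesign")
}

toy_enzymes <- function() {
  read_enzyme_catalog(mini_catalog_path())
}

# write an enzyme annotation from a data.frame and return its path
write_catalog <- function(df, sep = "\t") {
  path <- withr::local_tempfile(
    fileext = ".tsv",
    .local_envir = parent.frame()
  )
  header <- c(
    "enzyme_name", "motif", "cut_offset",
    "cpg_sensitive", "chg_sensitive", "chh_sensitive", "family_id"
  )
  lines <- c(
    paste(header, collapse = sep),
    apply(df[header], 1, paste, collapse = sep)
  )
  writeLines(lines, path)
  path
}

catalog_row <- function(name, motif, offset = 1, family = paste0("fam_", motif),
                        cpg = "no", chg = "no", chh = "no") {
  data.frame(
    enzyme_name = name, motif = motif, cut_offset = offset,
    cpg_sensitive = cpg, chg_sensitive = chg, chh_sensitive = chh,
    family_id = family
  )
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a deterministic ~150 kb 2-chromosome genome plus 50 equally weighted
# CpG sites placed near CCGG occurrences, emulating the clustering of
# target CpGs around MspI sites in CpG islands; used by the search-oracle
# checks (gregexpr keeps the placement independent of the package scanner)
search_fixture <- function(seed = 20260925) {
  withr::with_seed(seed, {
    s1 <- random_seq(100000L)
    genome <- Biostrings::DNAStringSet(c(
      chr1 = s1,
      chr2 = random_seq(50000L)
    ))
    attr(genome, "genome_id") <- "fixture-150kb"
    cc <- as.integer(gregexpr("CCGG", s1, fixed = TRUE)[[1]])
    cg <- as.integer(gregexpr("CG", s1, fixed = TRUE)[[1]])
    near <- cg[vapply(cg, function(p) any(abs(p - cc) <= 40), logical(1))]
    picks <- sort(sample(near, 50L))
    sites <- tibble::tibble(
      site_id = paste0("chr1:", picks),
      chrom = "chr1",
      coord = picks - 1L, # 0-based position of the C
      weight = 1
    )
    list(genome = genome, sites = sites)
  })
}

# fixture-appropriate configuration: on a 150 kb genome the fragment
# ceiling k*g/1000 scales down to 150 fragments at k = 1, matching the
# spirit of the genome-proportional NF threshold at desk scale
fixture_config <- function(...) {
  args <- list(...)
  defaults <- list(
    read_length = 75, score_threshold = 0.25, genome_size = 150000,
    nf_constant = 1
  )
  do.call(run_config, utils::modifyList(defaults, args))
}

search_families <- function() {
  enz <- toy_enzymes()
  fams <- enzyme_families(enz)
  fams[fams$family_id %in% c("fam_CCGG", "fam_TCGA", "fam_WCCGGW"), ]
}
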