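---
title: "Designing customised RRBS protocols in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing customised RRBS protocols in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbsdesign)
library(Biostrings)
library(tibble)
```

## The problem

Reduced representation bisulfite sequencing (RRBS) assays DNA methylation
on a small, reproducible subset of the genome: a restriction digestion
(classically MspI, cutting C^CGG) followed by size selection of the
resulting fragments. Only cytosines that end up inside a selected fragment,
close enough to a fragment end to be covered by a read, are measured. The
classical protocol enriches CpG islands and promoters — but for any other
set of target sites (clock CpGs, imprinted regions, transcription-factor
binding sites, non-CpG contexts in plants), MspI is rarely the best choice
among the hundreds of commercially available enzymes.

`rrbsdesign` turns protocol choice into an explicit optimisation. Given

* a genome (FASTA),
* a catalog of restriction enzymes grouped into isoschizomer families,
* a weighted list of genomic sites of interest,

it digests the genome in silico with every single family and every
unordered pair of families, sweeps candidate size-selection windows on a
grid, and ranks the resulting protocols.

## The model

For a candidate protocol (enzyme set + size window `[a, a + b]`):

* **NF** — the number of fragments whose length falls inside the window,
  both bounds inclusive. Sequencing cost is assumed proportional to NF.
* **Score** — `sum(w_i * gamma_i)` over the `n` sites of interest, where
  `w_i` is the site's weight and `gamma_i` is 1 when the site sits inside a
  selected fragment within `read_length` bases of one of its ends.
  `max_Score = sum(w_i)` is the score if everything were recovered.
* **Enrichment value** —
  `EV = -log10((Score / NF) * (n / max_Score))`. EV falls when more site
  weight is recovered in fewer fragments; the search minimises it.
* **Cost reduction factor** — `CRF = (g / r) / NF`, the fold reduction in
  sequenced fragments relative to whole-genome bisulfite sequencing of a
  genome of size `g` at read length `r`.
* **Robustness** — gel excision is imperfect; the realised window may be
  displaced by up to the experimental error `delta`. Robustness evaluates
  EV on the 3x3 stencil `{a - delta, a, a + delta} x {b - delta, b,
  b + delta}`, sums the relative deviations from the central EV into
  `theta`, and reports `R = exp(-theta)` in `(0, 1]`. A flat EV landscape
  around the optimum gives `R = 1`.

Candidate windows must pass two user thresholds before ranking: a minimum
score, `Score >= c * max_Score`, and a fragment ceiling,
`NF <= k * g / 1000` (equivalently, a minimum CRF of `1000 / (k * r)`).

## A worked example

A small synthetic study: a 60 kb genome, 30 equally weighted CpG sites
placed near CCGG occurrences (mimicking how RRBS targets cluster around
MspI sites in CpG islands), and three enzyme families from the shipped
miniature catalog.

```{r example}
set.seed(42)
rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
s1 <- rand_seq(60000)
genome <- DNAStringSet(c(chr1 = s1))
attr(genome, "genome_id") <- "vignette-60kb"

cc <- as.integer(gregexpr("CCGG", s1, fixed = TRUE)[[1]])
cg <- as.integer(gregexpr("CG", s1, fixed = TRUE)[[1]])
near <- cg[vapply(cg, function(p) any(abs(p - cc) <= 40), logical(1))]
picks <- sort(sample(near, 30))
sites <- tibble(
  site_id = paste0("chr1:", picks), chrom = "chr1",
  coord = picks - 1L, weight = 1
)

catalog <- read_enzyme_catalog(
  system.file("extdata", "mini_enzyme_catalog.tsv", package = "rrbsdesign")
)
families <- filter_families(catalog, "CpG")
families <- families[
  families$family_id %in% c("fam_CCGG", "fam_TCGA", "fam_WCCGGW"),
]

config <- run_config(
  read_length = 75, score_threshold = 0.25,
  nf_constant = 1, max_lower = 300, max_breadth = 300
)
res <- run_search(families, sites, genome, config)
tidy(res)[, c("rank", "enzymes", "lower", "breadth", "nf", "score",
  "ev", "crf", "robustness")]
glance(res)
```

The ranked table reads like the output file of the command-line tool
(`exec/rrbsdesign`): for each enzyme (or pair) the winning window, its
fragment count, recovered score, EV, CRF and robustness. `autoplot(res)`
shows EV by rank; `plot_size_tradeoff()` and `plot_ev_landscape()`
visualise one combination's full grid.

```{r landscape, fig.width = 6, fig.height = 4}
idx <- digest_genome(genome, families[families$family_id == "fam_CCGG", ])
fragments <- build_fragments(idx)
grid <- candidate_ranges(20, 300, 20, 300)
metrics <- range_metrics(fragments, sites, grid,
  run_config(read_length = 75, genome_size = 60000, nf_constant = 1))
plot_ev_landscape(metrics, optimum = tidy(res)[1, ])
```

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `read_length` (bp) | positions visible from a fragment end | — | typical 30–300 |
| `adapters_size` (bp) | added to reported experimental windows | 0 | gel excision happens after ligation |
| `score_threshold` `c` | minimum `Score / max_Score` | 0.25 | in `[0, 1]` |
| `nf_constant` `k` | fragment ceiling `NF <= k g / 1000` | 0.2 | in `[0, 1]` |
| `experimental_error` `delta` (bp) | assumed gel error; grid resolution | 20 | typical 5–500 |
| `max_breadth` (bp) | widest window sampled | 980 | |
| `min_lower`, `max_lower` (bp) | window lower-limit grid bounds | 20, 1000 | mappable-fragment heuristic |
| `output_size` `t` | protocols reported | 30 | |
| `emit_site_ids` | attach recovered site IDs | off | needed for validation runs |

The grid resolution deliberately equals `delta`: windows closer together
than the experimental error cannot be realised distinctly on a gel, so
finer sampling would only add cost. `fixed_range = c(a, b)` bypasses the
grid entirely and scores exactly one window — the mode used to validate
predictions against a published protocol's reported size range.

## Conventions and numerical choices

* **Coordinates** are 0-based internally; a cut at coordinate `c` severs
  the bond before position `c`. Site annotation files are read and written
  1-based, the common convention for site lists. One cut coordinate is
  recorded per double-strand cut (the top-strand position); sticky-end
  overhangs shift true fragment ends by at most 4 bp, which is absorbed
  into the experimental error `delta`.
* **IUPAC matching**: degeneracy codes in motifs are honoured; a genomic
  `N` matches only the pattern letter `N`, so motifs are never asserted
  across assembly gaps. Rare ambiguity letters in a genome are treated
  like `N`. Matching is case-insensitive (soft-masked bases count).
* **Strandedness**: a motif that equals its IUPAC reverse complement is
  scanned once; otherwise both orientations are scanned, the reverse
  orientation cutting at `motif_length - cut_offset` from the match start.
* **Terminal fragments** (chromosome ends) are excluded: a library
  fragment needs two enzyme-generated ends for adapter ligation. On real
  genomes this changes NF negligibly; the synthetic tests exploit it for
  exact ground truth.
* **Window bounds** are inclusive at both ends, so a grid with breadths in
  multiples of `delta` tiles lengths without gaps or double counting.
* **Read coverage rule**: with a fragment `[s, e)` and site `p`, recovery
  requires `p - s < r` or `e - p <= r`; the asymmetry makes each read
  cover exactly `r` bases in half-open coordinates. The boundary case — a
  site exactly `r` bases from the fragment start — is the one place where
  an alternative reading ("distance <= r") would differ.
* **Undefined EV** (`NF = 0` or `Score = 0`) is a sentinel that compares
  worse than any defined EV. Inside the robustness stencil an undefined
  neighbour contributes a full relative deviation of 1 — penalising
  optima adjacent to empty windows while keeping `R` in `(0, 1]`. Stencil
  lower limits are clamped at 1 bp and the breadth floor is 0 (a
  single-length window), so the stencil always has nine points.
* **Determinism**: within a combination, EV ties (within 1e-12) go to the
  smaller lower limit, then the smaller breadth; across combinations the
  ranking is EV ascending, robustness descending, NF ascending, enzyme
  names lexicographic. Results are independent of evaluation order.

## What the synthetic generator emulates — and what it does not

`generate_genome()` builds uniform-composition background sequence that is
rejection-repaired to contain no occurrence of the avoided motifs on
either strand, then plants concrete motif instances at recorded positions.
That guarantees the planted cuts are the *only* cuts, so fragment
boundaries, lengths and site recovery are known analytically —
`generate_sites()` places sites in classes (near a fragment end, at the
centre of a long fragment, in a terminal fragment, in an out-of-window
fragment) whose recovery indicator is forced by construction.

Real genomes are not uniform: GC content varies over megabases, CpG
islands concentrate both targets and cut sites, and repeats create
fragment-length structure the generator does not model. Passing tests
therefore demonstrate the *correctness of the computation* — digestion,
selection, scoring, ranking — not that any particular enrichment level
will be achieved on a real genome. The search fixtures used in testing run
on ~150 kb of random sequence with 50 target CpGs placed near CCGG
occurrences; at that scale the fragment ceiling `k * g / 1000` is only 150
fragments at `k = 1`, so the fixtures use `k = 1` where a human-genome run
would use the default `k = 0.2`. Problem sizes (10 kb scan sequences, 150
kb search genomes, 3-family catalogs) were chosen so that exhaustive
brute-force re-evaluation remains affordable as an independent oracle.

## Validation against experimental data

For a protocol that was actually run, `metric_curve()` compares the sites
the search predicted to be sequenced (via `emit_site_ids`) with the sites
observed at a given depth of coverage, producing TP/TN/FP/FN counts over
the site universe, `sensitivity = TP / (TP + FN) * 100` and
`specificity = TN / (FP + TN) * 100` per depth threshold. Site identity is
compared by `site_id` string (conventionally `chrom:coordinate`), which
sidesteps coordinate-convention mismatches at the comparison boundary.
Read trimming, alignment and methylation calling are out of scope; the
observed-sites file is a two-column table that a Bismark coverage report
reduces to.

## Limitations

* Only Type IIP-style enzymes cutting once, inside or adjacent to their
  recognition motif, are supported (`cut_offset <= motif length`); no
  nicking enzymes, no distant Type IIS cutters, no star activity or
  buffer-compatibility modelling.
* Combinations of more than two enzymes are not searched.
* Methylation sensitivity is handled categorically by catalog filtering
  (`filter_families()`), not by simulating methylation-state-dependent
  digestion.
* The isoschizomer family counts of any given commercial catalog depend on
  its curation snapshot; the shipped catalog is a miniature for testing,
  and real runs should supply a curated annotation file.
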