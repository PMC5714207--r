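test_that("the candidate grid tiles lower limits and breadths at delta", {
  g <- candidate_ranges(delta = 20, max_breadth = 40, min_lower = 20,
    max_lower = 60)
  expect_equal(nrow(g), 6L) # 3 lowers x 2 breadths
  expect_equal(unique(g$lower), c(20L, 40L, 60L))
  expect_equal(unique(g$breadth), c(20L, 40L))
  # default breadth cap at delta = 20 gives 49 breadth values
  g2 <- candidate_ranges(20, 980, 20, 20)
  expect_equal(nrow(g2), 49L)
  expect_error(candidate_ranges(20, 10, 20, 60), "empty")
})

test_that("fixed-range mode evaluates exactly one window", {
  fx <- search_fixture()
  fams <- search_families()
  cfg <- fixture_config(score_threshold = 0, fixed_range = c(90, 95),
    output_size = 5)
  res <- run_search(fams, fx$sites, fx$genome, cfg)
  expect_s3_class(res, "rrbs_search")
  expect_true(all(res$protocols$lower == 90L))
  expect_true(all(res$protocols$breadth == 95L))
})

test_that("range metrics agree with the naive per-range oracle", {
  fx <- search_fixture()
  fams <- search_families()
  idx <- digest_genome(fx$genome, fams[1, ])
  fragments <- build_fragments(idx)
  cfg <- fixture_config()
  ranges <- tibble::tibble(
    lower = c(40L, 40L, 100L, 200L),
    breadth = c(20L, 200L, 300L, 500L)
  )
  m <- range_metrics(fragments, fx$sites, ranges, cfg)
  for (i in seq_len(nrow(ranges))) {
    o <- oracle_evaluate_range(
      fragments, fx$sites, ranges$lower[[i]], ranges$breadth[[i]], 75
    )
    expect_equal(m$nf[[i]], o$nf)
    expect_equal(m$score[[i]], o$score)
    expect_equal(m$ev[[i]], o$ev, tolerance = 1e-12)
  }
})

test_that("search enumerates singles plus unordered pairs and ranks by EV", {
  fx <- search_fixture()
  fams <- search_families() # 3 families -> 3 + 3 combinations
  cfg <- fixture_config(max_lower = 400, max_breadth = 400)
  res <- run_search(fams, fx$sites, fx$genome, cfg)
  expect_equal(res$n_combinations, 6L)
  p <- res$protocols
  # EVs never decrease down the table
  expect_true(all(diff(p$ev) >= -1e-12))
  # each enzyme (pair) appears at most once
  expect_equal(anyDuplicated(p$enzymes), 0L)
  # every reported protocol satisfies both thresholds
  expect_true(all(p$score >= 0.25 * p$max_score - 1e-12))
  expect_true(all(p$nf <= 1 * 150000 / 1000))
  # robustness defined and in (0, 1]
  expect_true(all(is.na(p$robustness) | (p$robustness > 0 & p$robustness <= 1)))
  # experimental range is the theoretical one shifted by adapters
  expect_equal(p$exp_lower, p$lower + cfg$adapters_size)
  expect_equal(p$exp_upper, p$lower + p$breadth + cfg$adapters_size)
})

test_that("the top hit equals brute force over combinations x grid", {
  fx <- search_fixture()
  fams <- search_families()
  cfg <- fixture_config(max_lower = 300, max_breadth = 300)
  res <- run_search(fams, fx$sites, fx$genome, cfg)

  idx <- lapply(seq_len(nrow(fams)), function(i) {
    digest_genome(fx$genome, fams[i, ])
  })
  names(idx) <- fams$family_id
  oracle <- oracle_search(idx, fx$sites, cfg)
  oracle <- oracle[order(oracle$ev), ]

  top <- res$protocols[1, ]
  expect_equal(top$ev, oracle$ev[[1]], tolerance = 1e-12)
  expect_equal(top$enzymes, oracle$enzymes[[1]])
  expect_equal(top$lower, oracle$lower[[1]])
  expect_equal(top$breadth, oracle$breadth[[1]])
  expect_equal(top$nf, oracle$nf[[1]])
  expect_equal(top$score, oracle$score[[1]])
  # per-combination winners also agree
  merged <- merge(res$protocols, oracle, by = "enzymes",
    suffixes = c("", ".oracle"))
  expect_equal(nrow(merged), nrow(oracle))
  expect_equal(merged$ev, merged$ev.oracle, tolerance = 1e-12)
  expect_equal(merged$nf, merged$nf.oracle)
})

test_that("adding a family never worsens the best reported EV", {
  fx <- search_fixture()
  fams <- search_families()
  cfg <- fixture_config(max_lower = 300, max_breadth = 300)
  small <- run_search(fams[1:2, ], fx$sites, fx$genome, cfg)
  full <- run_search(fams, fx$sites, fx$genome, cfg)
  expect_lte(glance(full)$best_ev, glance(small)$best_ev)
})

test_that("an infeasible threshold combination yields an empty report", {
  fx <- search_fixture()
  fams <- search_families()[1, ]
  cfg <- fixture_config(score_threshold = 1, nf_constant = 1e-9,
    max_lower = 100, max_breadth = 100)
  expect_message(res <- run_search(fams, fx$sites, fx$genome, cfg),
    "no enzyme combination passes")
  expect_equal(nrow(res$protocols), 0L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(res, path)
  expect_equal(nrow(read_report(path)), 0L) # header-only file
})

test_that("reports round-trip and respect the output size", {
  fx <- search_fixture()
  fams <- search_families()
  cfg <- fixture_config(max_lower = 300, max_breadth = 300,
    output_size = 2, emit_site_ids = TRUE, adapters_size = 120)
  res <- run_search(fams, fx$sites, fx$genome, cfg)
  expect_lte(nrow(res$protocols), 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(res, path)
  back <- read_report(path)
  expect_equal(nrow(back), nrow(res$protocols))
  expect_equal(back$nf, as.numeric(res$protocols$nf))
  expect_equal(back$ev, round(res$protocols$ev, 6), tolerance = 1e-9)
  expect_equal(back$crf, round(res$protocols$crf, 1), tolerance = 1e-9)
  expect_equal(
    back$theoretical_range,
    paste0(res$protocols$lower, "-",
      res$protocols$lower + res$protocols$breadth)
  )
  expect_equal(
    back$experimental_range,
    paste0(res$protocols$lower + 120, "-",
      res$protocols$lower + res$protocols$breadth + 120)
  )
  # recovered site IDs are attached and are real site IDs
  expect_true(all(unlist(res$protocols$site_ids) %in% fx$sites$site_id))

  # tidy/glance accessors
  expect_equal(tidy(res), res$protocols)
  expect_equal(glance(res)$best_ev, res$protocols$ev[[1]])
})

test_that("precomputed indices can stand in for fresh digestion", {
  fx <- search_fixture()
  fams <- search_families()
  cfg <- fixture_config(max_lower = 300, max_breadth = 300)
  dir <- withr::local_tempdir()
  idx <- list()
  for (i in seq_len(nrow(fams))) {
    ix <- digest_genome(fx$genome, fams[i, ])
    path <- file.path(dir, paste0(fams$family_id[[i]], ".txt.gz"))
    write_precomputed(ix, path)
    idx[[fams$family_id[[i]]]] <-
      read_precomputed(path, expect_genome_id = "fixture-150kb")
  }
  from_files <- run_search(fams, fx$sites, fx$genome, cfg, indices = idx)
  fresh <- run_search(fams, fx$sites, fx$genome, cfg)
  expect_equal(from_files$protocols, fresh$protocols)
})
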