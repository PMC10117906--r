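test_that("genome generation rejects bad input, is seed-deterministic, and hits target GC", {
  expect_error(generate_genome(0), "positive")
  expect_error(generate_genome(1000, gc = 1.2), "0, 1")

  a <- generate_genome(1e5, gc = 0.5, seed = 1)
  b <- generate_genome(1e5, gc = 0.5, seed = 1)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$length, nchar(a$sequence))
  expect_false(grepl("[^ACGT]", a$sequence))

  g <- generate_genome(1e6, gc = 0.5, seed = 7)
  se <- sqrt(0.5 * 0.5 / 1e6)
  expect_lt(abs(g$gc_content - 0.5), 3 * se)

  skewed <- generate_genome(2e5, gc = 0.3, seed = 2)
  expect_lt(abs(skewed$gc_content - 0.3), 3 * sqrt(0.3 * 0.7 / 2e5))
})

test_that("site planting respects counts, spacing, and motif rewriting", {
  g <- generate_genome(5e4, seed = 3)
  none <- plant_sites(g, 0)
  expect_identical(nrow(none$sites), 0L)
  expect_identical(none$genome$sequence, g$sequence)

  # fully deterministic motif (probability-1 columns) writes its consensus
  m1 <- build_pfm(tibble::tibble(sequence = "ACGTACGTAC"))  # halfwidth 3
  one <- plant_sites(g, 1, motif = m1, seed = 5)
  c0 <- one$sites$center[1]
  expect_identical(genome_window(one$genome, c0 - 3, 10), "ACGTACGTAC")
  expect_identical(motif_consensus(m1), "ACGTACGTAC")

  planted <- plant_sites(g, 60, seed = 9)
  expect_identical(planted$sites$center, sort(planted$sites$center))
  expect_true(all(diff(planted$sites$center) > 5))

  expect_error(plant_sites(g, 2e4, seed = 1), "too large")
})

test_that("planted determinant columns are recovered at the planted frequencies", {
  g <- generate_genome(2e5, seed = 21)
  m <- determinant_motif(halfwidth = 8, prob = 0.8)
  planted <- plant_sites(g, 200, motif = m, seed = 22)
  win <- extract_windows(planted$genome, planted$sites, halfwidth = 8)
  pfm <- build_pfm(win)
  dets <- c("-4" = "G", "-2" = "A", "-1" = "T",
            "5" = "A", "6" = "T", "8" = "C")
  se <- sqrt(0.8 * 0.2 / 200)
  for (p in names(dets)) {
    expect_lt(abs(pfm$freq[dets[[p]], p] - 0.8), 3 * se)
  }
})

test_that("simulated samples respect condition design and fragment-length bounds", {
  fx <- canonical_fixture(strength = 80, background = 3000L)
  cfg <- fx$cfg

  # -drug: no 3'-end walls near the planted center
  nodrug <- simulate_sample(fx$genome, fx$sites,
                            sample_condition(FALSE, TRUE, 1), cfg)
  tr0 <- compute_tracks(nodrug, fx$genome$length)
  near <- seq(fx$sites$center - 10, fx$sites$center + 10) + 1
  expect_lte(max(tr0$n3e_fwd[near], tr0$n3e_rev[near]), 3)

  # background fragment lengths stay inside the sonication range
  empty_sites <- fx$sites[0, ]
  bg <- simulate_sample(fx$genome, empty_sites,
                        sample_condition(TRUE, TRUE, 1), cfg)
  expect_true(all(bg$end - bg$start >= 200 & bg$end - bg$start <= 800))

  # mock (-IP) samples carry strongly diluted site signal
  mock <- simulate_sample(fx$genome, fx$sites,
                          sample_condition(TRUE, FALSE, 1), cfg)
  trm <- compute_tracks(mock, fx$genome$length)
  expect_lt(trm$n3e_fwd[fx$sites$center],
            fx$trt$n3e_fwd[fx$sites$center] / 4)
})

test_that("exact event counts produce the four-fragment staggered geometry", {
  cfg <- simulation_config(seed = 1, genome_length = 1e4,
                           capture_efficiency_3p = 1,
                           capture_efficiency_5p = 0)
  fr <- withr::with_seed(42, {
    trapped_complex_fragments(1000L, 5L, 100L, cfg, 1e4)
  })
  fwd <- fr[fr$strand == "+", ]
  rev_ <- fr[fr$strand == "-", ]
  expect_identical(nrow(fwd), 100L)
  expect_identical(nrow(rev_), 100L)
  expect_true(all(fwd$end - 1L == 999L))   # forward 3' ends
  expect_true(all(rev_$start == 1004L))    # reverse 3' ends (leftmost coord)

  # with 5' capture on, covalent-side fragments appear at the gap edges
  cfg5 <- simulation_config(seed = 1, genome_length = 1e4,
                            capture_efficiency_3p = 0,
                            capture_efficiency_5p = 1)
  fr5 <- withr::with_seed(43, {
    trapped_complex_fragments(1000L, 5L, 50L, cfg5, 1e4)
  })
  expect_true(all(fr5$start[fr5$strand == "+"] == 1000L))
  expect_true(all(fr5$end[fr5$strand == "-"] == 1004L))
})

test_that("composite loci invert the wall order and overlap instead of gapping", {
  g <- generate_genome(2e4, seed = 5)
  cfg <- simulation_config(seed = 5, genome_length = g$length,
                           background_fragments = 1000L,
                           capture_efficiency_3p = 1)
  cond <- sample_condition(TRUE, TRUE, 1)
  fr <- simulate_composite_site(g, center = 5000L, stagger = 5L,
                                strength = 120, condition = cond,
                                config = cfg)
  tr <- compute_tracks(fr, g$length)
  geo <- wall_geometry(tr, 4900, 5100)
  expect_identical(geo$fwd_wall, 5000)
  expect_identical(geo$rev_wall, 4995)
  expect_identical(geo$wall_order, "inverted")
  expect_identical(geo$inclusive_span, 6)
  expect_identical(geo$both_covered, 6L)

  # zero strength is byte-identical to a background-only sample
  z <- simulate_composite_site(g, 5000L, 5L, 0, cond, cfg)
  bg <- simulate_sample(g, tibble::tibble(center = integer(),
                                          strength = double(),
                                          kind = character(),
                                          parent = integer(),
                                          stagger = integer()),
                        cond, cfg)
  expect_identical(z, bg)
})

test_that("seed determinism gives byte-identical fragment sets", {
  fx <- canonical_fixture()
  cond <- sample_condition(TRUE, TRUE, 2)
  a <- simulate_sample(fx$genome, fx$sites, cond, fx$cfg)
  b <- simulate_sample(fx$genome, fx$sites, cond, fx$cfg)
  expect_identical(a, b)
  # a different replicate gets a different derived seed
  c2 <- simulate_sample(fx$genome, fx$sites, sample_condition(TRUE, TRUE, 3),
                        fx$cfg)
  expect_false(identical(a$start, c2$start))
})

test_that("truth tables round-trip and use the overhang BED convention", {
  sites <- tibble::tibble(center = c(1000L, 5000L), strength = c(25.5, 3.25),
                          kind = c("canonical", "satellite"),
                          parent = c(NA_integer_, 1000L),
                          stagger = c(5L, 5L))
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sites, bed, tsv)
  expect_identical(read_truth(tsv), sites)
  bedtab <- readr::read_tsv(bed, col_names = FALSE, show_col_types = FALSE)
  expect_identical(bedtab$X2[1], 1000)
  expect_identical(bedtab$X3[1], 1004)

  write_truth(sites[0, ], bed, tsv)
  expect_identical(nrow(read_truth(tsv)), 0L)
  expect_identical(length(readLines(bed)), 0L)
})

test_that("fragments respect length bounds except at cleavage walls and wrap correctly", {
  cfg <- simulation_config(seed = 2, genome_length = 5e4,
                           background_fragments = 5000L)
  g <- generate_genome(5e4, seed = 2)
  planted <- plant_sites(g, 20, seed = 3)
  fr <- simulate_sample(g, planted$sites, sample_condition(TRUE, TRUE, 1),
                        cfg)
  expect_true(all(fr$end > fr$start))
  expect_true(all(fr$start >= 0 & fr$start < g$length))
  expect_true(all(fr$end - fr$start <= 800))
})
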