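test_that("count-enrichment p-values match brute-force series summation", {
  grid <- expand.grid(x = c(0L, 1L, 5L, 50L, 200L),
                      y = c(0L, 1L, 10L, 200L),
                      ratio = c(0.5, 1, 2.3))
  for (i in seq_len(nrow(grid))) {
    n2 <- 1e6
    n1 <- grid$ratio[i] * n2
    p_pkg <- audic_claverie_pvalue(grid$x[i], grid$y[i], n1, n2)
    p_ora <- ac_tail_oracle(grid$x[i], grid$y[i], n1, n2)
    expect_lt(abs(p_pkg - p_ora) / max(p_ora, 1e-300), 1e-10)
  }
  # strong enrichment over a single control count is called at alpha = 1e-5
  p <- audic_claverie_pvalue(50, 1, 1e6, 1e6)
  expect_equal(p, ac_tail_oracle(50, 1, 1e6, 1e6), tolerance = 1e-10)
  expect_lt(p, 1e-5)
})

test_that("no spikes are called when treatment equals control", {
  fr <- dplyr::bind_rows(
    random_fragments(500, 3000L, seed = 51),
    tibble::tibble(start = rep(100L, 30), end = rep(400L, 30), strand = "+",
                   count = 1L)
  )
  tr <- compute_tracks(fr, 3000L)
  expect_identical(nrow(call_strand_spikes(tr, tr, "forward")), 0L)
  expect_identical(nrow(call_strand_spikes(tr, tr, "reverse")), 0L)
  expect_error(call_strand_spikes(tr, tr, "forward", alpha = 2), "alpha")
})

test_that("null calibration: per-position false-call rate stays at or below alpha", {
  # mock-vs-mock split of one background-only sample
  L <- 1e5L
  g <- generate_genome(L, seed = 61)
  cfg <- simulation_config(seed = 61, genome_length = L,
                           background_fragments = 200000L)
  empty <- tibble::tibble(center = integer(), strength = double(),
                          kind = character(), parent = integer(),
                          stagger = integer())
  a <- compute_tracks(simulate_sample(g, empty, sample_condition(TRUE, TRUE, 1),
                                      cfg), L)
  b <- compute_tracks(simulate_sample(g, empty, sample_condition(TRUE, TRUE, 2),
                                      cfg), L)
  alpha <- 1e-3
  calls <- nrow(call_strand_spikes(a, b, "forward", alpha = alpha,
                                   min_height = 1)) +
    nrow(call_strand_spikes(a, b, "reverse", alpha = alpha, min_height = 1))
  expected <- alpha * 2 * L
  expect_lte(calls, expected + 3 * sqrt(expected))
})

test_that("spike pairing reproduces the canonical and composite geometries", {
  fwd <- tibble::tibble(position = 999L, strand = "+", height = 50,
                        control = 0, fold = 40, p = 1e-10)
  rev_ <- tibble::tibble(position = 1004L, strand = "-", height = 45,
                         control = 0, fold = 38, p = 1e-10)
  tcs <- pair_spikes(fwd, rev_, stagger = 5, jitter = 0)
  expect_identical(nrow(tcs), 1L)
  expect_identical(tcs$center, 1000L)
  expect_identical(tcs$geometry, "canonical")
  expect_identical(tcs$rev_wall - tcs$fwd_wall, 5L)  # interior gap = 4

  comp <- pair_spikes(
    dplyr::mutate(fwd, position = 5000L),
    dplyr::mutate(rev_, position = 4995L), stagger = 5)
  expect_identical(comp$geometry, "composite")
  expect_identical(comp$center, 4995L)
  expect_identical(comp$fwd_wall - comp$rev_wall, 5L)  # inclusive span = 6

  none <- pair_spikes(fwd[0, ], rev_, stagger = 5)
  expect_identical(nrow(none), 0L)
  expect_identical(nrow(attr(none, "orphans")), 1L)
  expect_error(pair_spikes(fwd, rev_, jitter = -1), "jitter")

  # jitter admits near-miss walls; strict pairing does not
  off <- dplyr::mutate(rev_, position = 1005L)
  expect_identical(nrow(pair_spikes(fwd, off, stagger = 5, jitter = 0)), 0L)
  expect_identical(nrow(pair_spikes(fwd, off, stagger = 5, jitter = 2)), 1L)
})

test_that("repair fill-in transform gives the expected overlap and separation", {
  expect_identical(predict_repair_extension(5),
                   tibble::tibble(overlap = 4L, separation = 2L))
  expect_identical(predict_repair_extension(3),
                   tibble::tibble(overlap = 2L, separation = 0L))
  expect_identical(predict_repair_extension(7),
                   tibble::tibble(overlap = 6L, separation = 4L))
  expect_error(predict_repair_extension(2), "stagger")
})

test_that("primary/satellite classification follows cluster score ranking", {
  one <- tibble::tibble(center = 500L, score = 3)
  expect_identical(classify_primary_satellite(one, 100)$rank, "primary")

  three <- tibble::tibble(center = c(1000L, 1030L, 1050L), score = c(3, 10, 2))
  cl <- classify_primary_satellite(three, 100)
  expect_identical(cl$rank[cl$center == 1030L], "primary")
  expect_identical(sum(cl$rank == "satellite"), 2L)

  # score permutations change the primary but never the cluster partition
  centers <- withr::with_seed(71, sort(sample.int(5000, 40)))
  window <- 60
  oracle <- brute_clusters(centers, window)
  for (s in 1:5) {
    scores <- withr::with_seed(s, stats::runif(40))
    cl <- classify_primary_satellite(
      tibble::tibble(center = centers, score = scores), window)
    cl <- dplyr::arrange(cl, center)
    # each oracle cluster must contain exactly one primary
    got <- tapply(cl$rank == "primary", oracle, sum)
    expect_true(all(got == 1))
  }
})

test_that("replicate reconciliation counts support and is order-invariant", {
  mk <- function(centers) tibble::tibble(center = as.integer(centers),
                                         score = seq_along(centers) + 0.5)
  sets <- list(mk(c(100, 200)), mk(c(100, 300)), mk(c(100, 200)))
  rec <- reconcile_replicates(sets, min_support = 2, tolerance = 0)
  expect_identical(rec$center, c(100L, 200L))
  expect_identical(rec$support, c(3L, 2L))

  all1 <- reconcile_replicates(sets, min_support = 1, tolerance = 0)
  expect_identical(all1$center, c(100L, 200L, 300L))

  perm <- reconcile_replicates(sets[c(3, 1, 2)], min_support = 2)
  expect_identical(perm$center, rec$center)
  expect_identical(perm$support, rec$support)

  expect_error(reconcile_replicates(sets, min_support = 0), "min_support")
})

test_that("set intersection obeys inclusion-exclusion and symmetry", {
  a <- tibble::tibble(center = c(10L, 50L, 90L))
  same <- intersect_sets(a, a, tolerance = 0)
  expect_identical(same$shared, 3L)
  expect_identical(same$union, 3L)

  b <- tibble::tibble(center = c(200L, 300L))
  disj <- intersect_sets(a, b)
  expect_identical(disj$shared, 0L)
  expect_identical(disj$union, 5L)

  c_ <- tibble::tibble(center = c(11L, 49L, 400L))
  ab <- intersect_sets(a, c_, tolerance = 2)
  ba <- intersect_sets(c_, a, tolerance = 2)
  expect_identical(ab$shared, ba$shared)
  expect_identical(ab$union, ba$union)
  expect_identical(ab$shared, 2L)
  expect_identical(ab$union, nrow(a) + nrow(c_) - ab$shared)
})

test_that("end-to-end calling recovers a planted site at single-nucleotide resolution", {
  fx <- canonical_fixture(center = 7000L, strength = 60)
  tcs <- call_tcs(fx$trt, fx$ctl)
  expect_identical(nrow(tcs), 1L)
  expect_identical(tcs$center, 7000L)
  expect_identical(tcs$geometry, "canonical")
  expect_true(all(c(tcs$p_fwd, tcs$p_rev) <= 1e-5))
  expect_gt(tcs$score, 5)
})
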