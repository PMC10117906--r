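test_that("region enrichment matches the brute-force binomial oracle", {
  grid <- expand.grid(obs = c(0L, 3L, 42L, 250L, 950L),
                      n = c(100L, 1000L, 5000L),
                      pr = c(0.01, 0.15, 0.5))
  grid <- grid[grid$obs <= grid$n, ]
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; pr <- grid$pr[i]; obs <- grid$obs[i]
    L <- 1e6
    region <- tibble::tibble(name = "r", start = 0L,
                             end = as.integer(round(pr * L)))
    centers <- c(seq_len(obs) %% region$end,                 # inside
                 region$end + seq_len(n - obs) %% (L - region$end))
    res <- region_enrichment(tibble::tibble(center = as.integer(centers)),
                             region, L)
    p_oracle <- binom_twosided_oracle(res$observed, n, region$end / L)
    expect_lt(abs(res$p - p_oracle) / max(p_oracle, 1e-300), 1e-10)
    expect_equal(res$expected, as.numeric(n) * (region$end / L))
  }
})

test_that("region enrichment handles whole-genome, wrapping, and direction", {
  tcs <- tibble::tibble(center = c(10L, 500L, 900L))
  whole <- region_enrichment(tcs, tibble::tibble(name = "all", start = 0L,
                                                 end = 1000L), 1000)
  expect_identical(whole$observed, 3L)
  expect_equal(whole$expected, 3)
  expect_equal(whole$fold, 1)
  expect_equal(whole$p, 1)

  # wrap-around region [900, 100) on a 1000-bp circle holds centers 10 and 900
  wrap <- region_enrichment(tcs, tibble::tibble(name = "ori", start = 900L,
                                                end = 100L), 1000)
  expect_identical(wrap$observed, 2L)
  expect_identical(wrap$direction, "enriched")

  depl <- region_enrichment(tcs, tibble::tibble(name = "d", start = 0L,
                                                end = 600L), 1000)
  expect_identical(depl$observed, 2L)  # fold 1.11 enriched
  expect_error(region_enrichment(tcs[0, ],
                                 tibble::tibble(name = "r", start = 0L,
                                                end = 10L), 1000), "Empty")
})

test_that("uniform sites are not flagged as enriched (calibration)", {
  hits <- 0L
  for (s in 1:100) {
    centers <- withr::with_seed(s, sample.int(1e6, 100) - 1L)
    res <- region_enrichment(tibble::tibble(center = centers),
                             tibble::tibble(name = "r", start = 0L,
                                            end = 100000L), 1e6)
    expect_equal(res$expected, 10)
    if (res$p < 0.01) hits <- hits + 1L
  }
  expect_lte(hits, 5L)
})

test_that("binned densities keep every site and respect bin boundaries", {
  empty <- bin_density(tibble::tibble(center = integer()), 40000, 4e6)
  expect_true(all(empty$count == 0))

  edge <- bin_density(tibble::tibble(center = c(0L, 39999L, 40000L)),
                      40000, 4e6)
  expect_identical(edge$count[1:2], c(2L, 1L))

  centers <- withr::with_seed(91, sample.int(4e6, 1000) - 1L)
  bins <- bin_density(tibble::tibble(center = centers), 40000, 4e6)
  expect_identical(sum(bins$count), 1000L)
  expect_equal(mean(bins$count), 10)

  # partial last bin is kept
  part <- bin_density(tibble::tibble(center = 95000L), 40000, 1e5)
  expect_identical(nrow(part), 3L)
  expect_identical(part$bin_end[3], 100000L)
  expect_identical(sum(part$count), 1L)
})

test_that("region-mean comparisons use a Welch two-tailed t-test", {
  L <- 1e6
  ra <- tibble::tibble(name = "a", start = 0L, end = 500000L)
  rb <- tibble::tibble(name = "b", start = 500000L, end = 1000000L)
  mk <- function(centers, scores) tibble::tibble(center = centers,
                                                 score = scores)
  # identical value multisets: t = 0, p = 1
  tcs <- mk(c(100L, 200L, 600000L, 600100L), c(1, 2, 2, 1))
  same <- compare_region_means(tcs, ra, rb, L)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # power: N(2,1) vs N(1,1), n = 200 each
  sc <- withr::with_seed(17, c(rnorm(200, 2), rnorm(200, 1)))
  tcs2 <- mk(c(seq_len(200) * 100L, 500000L + seq_len(200) * 100L), sc)
  pw <- compare_region_means(tcs2, ra, rb, L)
  expect_lt(pw$p, 0.01)
  expect_gt(pw$mean_a, pw$mean_b)

  expect_error(compare_region_means(mk(c(100L, 200L), c(1, 2)), ra, rb, L),
               "at least 2")
  expect_error(compare_region_means(mk(c(100L, 200L, 600000L, 600100L),
                                       rep(3, 4)), ra, rb, L), "constant")
})

make_tus <- function(n, L, tu_len = 2000L, seed = 7) {
  withr::with_seed(seed, {
    starts <- (seq_len(n) - 1L) * (L %/% n) + 5000L
    tibble::tibble(
      name = paste0("tu", seq_len(n)),
      start = as.integer(starts),
      end = as.integer(starts + tu_len),
      strand = sample(c("+", "-"), n, replace = TRUE),
      expression = stats::rexp(n)
    )
  })
}

test_that("metagene of a constant track is constant across strata", {
  L <- 200000L
  tus <- make_tus(40, L)
  prof <- metagene(rep(1, L), tus, flank = 500, body_bins = 20,
                   min_stratum = 2)
  expect_true(all(abs(prof$mean_fe - 1) < 1e-12))
  expect_setequal(unique(prof$stratum), c("all", "HETU", "LETU"))
  expect_identical(nrow(prof[prof$stratum == "all", ]), 2L * 500L + 20L)

  # TU order invariance
  perm <- withr::with_seed(3, sample(nrow(tus)))
  prof2 <- metagene(rep(1, L), tus[perm, ], flank = 500, body_bins = 20,
                    min_stratum = 2)
  expect_equal(prof2$mean_fe, prof$mean_fe)
})

test_that("metagene orients reverse-strand TUs so downstream = lower coordinates", {
  L <- 50000L
  tu <- tibble::tibble(name = "tu1", start = 20000L, end = 22000L,
                       strand = "-", expression = 1)
  values <- rep(1, L)
  values[seq(19000, 19999) + 1] <- 5   # left of TU = downstream for "-"
  prof <- metagene(values, tu, flank = 1000, body_bins = 10, min_stratum = 1)
  down <- prof[prof$stratum == "all" & prof$region == "downstream", ]
  up <- prof[prof$stratum == "all" & prof$region == "upstream", ]
  expect_true(all(down$mean_fe == 5))
  expect_true(all(up$mean_fe == 1))
})

test_that("planted downstream enrichment is recovered in the HETU stratum only", {
  L <- 400000L
  tus <- make_tus(60, L, seed = 19)
  qs <- stats::quantile(tus$expression, c(0.1, 0.9))
  values <- rep(1, L)
  for (i in seq_len(nrow(tus))) {
    if (tus$expression[i] >= qs[[2]]) {
      pos <- if (tus$strand[i] == "+") seq(tus$end[i], tus$end[i] + 2000L - 1L)
        else seq(tus$start[i] - 2000L, tus$start[i] - 1L)
      values[(pos %% L) + 1L] <- 3
    }
  }
  prof <- metagene(values, tus, flank = 2000, body_bins = 20,
                   min_stratum = 5)
  dmean <- function(st) mean(prof$mean_fe[prof$stratum == st &
                                            prof$region == "downstream"])
  umean <- function(st) mean(prof$mean_fe[prof$stratum == st &
                                            prof$region == "upstream"])
  expect_gt(dmean("HETU"), 2.5)
  expect_lt(dmean("LETU"), 1.3)
  expect_lt(abs(umean("HETU") - umean("LETU")), 0.3)
})

test_that("metagene skips too-short TUs and validates input", {
  L <- 50000L
  tus <- dplyr::bind_rows(
    make_tus(5, L, tu_len = 2000L),
    tibble::tibble(name = "short", start = 100L, end = 120L, strand = "+",
                   expression = 1)
  )
  expect_message(
    prof <- metagene(rep(1, L), tus, flank = 100, body_bins = 20,
                     min_stratum = 1),
    "Skipping 1 TU")
  expect_error(metagene(rep(1, L), tus[6, ], flank = 100, body_bins = 20),
               "No TUs")
  expect_error(metagene(rep(1, L), tus, flank = -1), "flank")
})

test_that("downstream correlations behave at the identities and under the null", {
  L <- 300000L
  tus <- make_tus(50, L, seed = 23)
  a <- withr::with_seed(24, stats::rnorm(L, mean = 2))
  same <- downstream_correlation(a, a, tus, window = 1000)
  expect_equal(same$r, 1)

  neg <- downstream_correlation(a, -(a - mean(a)), tus, window = 1000)
  expect_equal(neg$r, -1)

  tus500 <- make_tus(500, 500000L, seed = 25)
  x <- withr::with_seed(26, stats::rnorm(500000))
  y <- withr::with_seed(27, stats::rnorm(500000))
  null <- downstream_correlation(x, y, tus500, window = 1000)
  expect_lt(abs(null$r), 0.1)

  expect_error(downstream_correlation(a, a, tus[1:2, ]), "3 TUs")
  expect_error(downstream_correlation(a, rep(1, L), tus), "variance")
})
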