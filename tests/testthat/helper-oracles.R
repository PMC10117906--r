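# Independent brute-force oracles used to pin the package's closed-form
# statistics, plus small shared fixtures.

# Direct log-space summation of the count-enrichment tail series
#   p = sum_{k >= x} (n1/n2)^k (y+k)! / (y! k! (1 + n1/n2)^{y+k+1})
# run to numerical convergence.
ac_tail_oracle <- function(x, y, n1, n2) {
  r <- n1 / n2
  logterm <- function(k) {
    k * log(r) + lgamma(y + k + 1) - lgamma(y + 1) - lgamma(k + 1) -
      (y + k + 1) * log(1 + r)
  }
  s <- 0
  k <- x
  repeat {
    t <- exp(logterm(k))
    s <- s + t
    if ((t < 1e-18 * max(s, 1e-300) && k > x + 20) || k > x + 2e5) break
    k <- k + 1
  }
  s
}

# Two-sided exact binomial p by direct term summation and tail doubling.
binom_twosided_oracle <- function(obs, n, pr) {
  lo <- sum(dbinom(0:obs, n, pr))
  hi <- if (obs == 0) 1 else sum(dbinom(obs:n, n, pr))
  min(1, 2 * min(lo, hi))
}

# Transitive-closure clustering by repeated pairwise merging (quadratic,
# order-free) — oracle for the chain clustering used in site classification.
brute_clusters <- function(centers, window) {
  n <- length(centers)
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(centers[i] - centers[j]) <= window && cl[i] != cl[j]) {
          cl[cl == cl[j]] <- cl[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(cl, unique(cl))
}

# Shared small genome + one strong canonical site, with treatment and
# control tracks.
canonical_fixture <- function(center = 10000L, strength = 100,
                              genome_len = 2e4, seed = 11,
                              eff3 = 1, eff5 = 0.5, background = 2000L) {
  g <- generate_genome(genome_len, gc = 0.5, seed = seed)
  cfg <- simulation_config(seed = seed, genome_length = genome_len,
                           background_fragments = background,
                           capture_efficiency_3p = eff3,
                           capture_efficiency_5p = eff5)
  sites <- tibble::tibble(center = as.integer(center), strength = strength,
                          kind = "canonical", parent = NA_integer_,
                          stagger = 5L)
  trt <- compute_tracks(
    simulate_sample(g, sites, sample_condition(TRUE, TRUE, 1), cfg),
    genome_len)
  ctl <- compute_tracks(
    simulate_sample(g, sites, sample_condition(FALSE, TRUE, 1), cfg),
    genome_len)
  list(genome = g, sites = sites, cfg = cfg, trt = trt, ctl = ctl)
}

random_fragments <- function(n, genome_len, seed, circular = TRUE) {
  withr::with_seed(seed, {
    len <- sample(50:300, n, replace = TRUE)
    start <- if (circular) sample.int(genome_len, n, replace = TRUE) - 1L
      else floor(runif(n) * (genome_len - len + 1))
    tibble::tibble(start = as.integer(start),
                   end = as.integer(start + len),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   count = sample(1:3, n, replace = TRUE))
  })
}
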