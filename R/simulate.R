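#' Sample conditions for a trapped-complex experiment
#'
#' A sample is defined by drug treatment (a fluoroquinolone poison that traps
#' covalent cleavage complexes), immunoprecipitation (affinity enrichment of
#' the tagged topoisomerase), and replicate index. `sample_condition()`
#' builds one condition; `condition_grid()` builds the full +/-drug x +/-IP
#' design in `n_replicates` replicates.
#'
#' @param drug Logical: drug added (+Cfx)?
#' @param ip Logical: affinity-enriched (+IP)?
#' @param replicate Replicate index (>= 1).
#' @return A one-row tibble with columns `drug`, `ip`, `replicate`, `label`;
#'   `condition_grid()` returns one row per sample. Labels are unique per
#'   (drug, ip, replicate).
#' @examples
#' condition_grid(2)
#' @export
sample_condition <- function(drug, ip, replicate = 1L) {
  stopifnot(is.logical(drug), is.logical(ip), replicate >= 1)
  tibble(
    drug = drug, ip = ip, replicate = as.integer(replicate),
    label = paste0(if (drug) "+Cfx" else "-Cfx",
                   if (ip) "+IP" else "-IP",
                   "_R", replicate)
  )
}

#' @rdname sample_condition
#' @param n_replicates Number of replicates per condition.
#' @export
condition_grid <- function(n_replicates = 3L) {
  tidyr::crossing(drug = c(TRUE, FALSE), ip = c(TRUE, FALSE),
                  replicate = seq_len(n_replicates)) |>
    purrr::pmap(sample_condition) |>
    dplyr::bind_rows() |>
    dplyr::arrange(dplyr::desc(.data$drug), dplyr::desc(.data$ip),
                   .data$replicate)
}

#' Simulation configuration
#'
#' Holds the parameters of the trapped-complex simulator. Defaults encode the
#' emulated experiment: sonication fragments of 200-800 bp, triplicate
#' samples, a 5-coordinate stagger between the strand walls (4-nt
#' 5'-overhang), and mock (-IP) samples carrying site fragments at 1/20 of
#' the +IP abundance.
#'
#' @param seed Global integer seed; per-sample seeds are derived from it.
#' @param genome_length Genome length (bp).
#' @param n_sites Number of planted sites.
#' @param strength_meanlog,strength_sdlog Log-normal parameters of per-site
#'   strength (expected trapping events per +drug/+IP sample; the default of
#'   ~100 events emulates the deep spike coverage of strong drug-trapped
#'   sites).
#' @param fragment_length_min,fragment_length_max Sonication fragment length
#'   bounds (bp).
#' @param background_fragments Background fragments per sample.
#' @param capture_efficiency_3p Probability that a free-3'-OH-side fragment
#'   of a trapping event is recovered.
#' @param capture_efficiency_5p Probability that a covalent-5'-side fragment
#'   is recovered (5'-phosphotyrosine adducts may impair library entry; the
#'   caller uses N3E only, so this affects N5E realism).
#' @param n_replicates Replicates per condition.
#' @param stagger Coordinate offset between the reverse and forward strand
#'   walls; `stagger = overhang + 1`, so the default 5 encodes a 4-nt
#'   overhang.
#' @param mock_dilution Fraction of site-derived fragments retained in -IP
#'   (mock) samples.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 1e5,
                              n_sites = 50L,
                              strength_meanlog = log(100),
                              strength_sdlog = 0.5,
                              fragment_length_min = 200L,
                              fragment_length_max = 800L,
                              background_fragments = 20000L,
                              capture_efficiency_3p = 0.8,
                              capture_efficiency_5p = 0.5,
                              n_replicates = 3L,
                              stagger = 5L,
                              mock_dilution = 1 / 20) {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    n_sites = as.integer(n_sites),
    strength_meanlog = strength_meanlog,
    strength_sdlog = strength_sdlog,
    fragment_length_min = as.integer(fragment_length_min),
    fragment_length_max = as.integer(fragment_length_max),
    background_fragments = as.integer(background_fragments),
    capture_efficiency_3p = capture_efficiency_3p,
    capture_efficiency_5p = capture_efficiency_5p,
    n_replicates = as.integer(n_replicates),
    stagger = as.integer(stagger),
    mock_dilution = mock_dilution
  )
  if (cfg$fragment_length_min > cfg$fragment_length_max) {
    abort("`fragment_length_min` must be <= `fragment_length_max`.")
  }
  for (f in c("capture_efficiency_3p", "capture_efficiency_5p",
              "mock_dilution")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0("`", f, "` must lie in [0, 1]."))
  }
  if (cfg$stagger < 1) abort("`stagger` must be >= 1.")
  structure(cfg, class = "simulation_config")
}

#' Derive a per-stage seed from the global seed
#'
#' Deterministic expansion of one global seed into independent per-sample /
#' per-stage seeds: the tag is hashed by a position-weighted character sum
#' and combined with the seed modulo 2^31 - 1.
#'
#' @param seed Global integer seed.
#' @param tag Character tag (e.g. a sample label).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 65521
  as.integer((as.numeric(seed) * 10007 + h * 31 + 1) %% 2147483647)
}

#' Plant cleavage sites in a synthetic genome
#'
#' Chooses non-overlapping site centers, assigns log-normal strengths, and
#' (optionally) rewrites the genome window around each center by sampling a
#' motif column-wise, oriented so that motif position +1 is the base at the
#' center coordinate. Optionally surrounds each primary site with weaker
#' satellite sites. Centers are 0-based coordinates of the first overhang
#' base.
#'
#' @param genome A `synthetic_genome`.
#' @param n_sites Number of primary sites (>= 0).
#' @param strengths Either `c(meanlog=, sdlog=)` log-normal parameters or a
#'   numeric vector of `n_sites` explicit strengths.
#' @param motif Optional `motif_matrix` used to rewrite site sequences.
#' @param kind Site kind for the primary sites: "canonical" or "composite".
#' @param stagger Wall offset (overhang + 1).
#' @param satellites Number of satellite sites planted around each primary.
#' @param satellite_offset Range (bp) of satellite center offsets from the
#'   parent (either side).
#' @param satellite_strength Satellite strength as a fraction of the parent.
#' @param min_separation Minimum distance between primary centers; defaults
#'   to the larger of one motif width and `stagger + 1`, plus satellite room.
#' @param seed Integer seed.
#' @return A list with `sites` (truth tibble sorted by center: `center`,
#'   `strength`, `kind`, `parent`, `stagger`) and `genome` (edited if a motif
#'   was given).
#' @export
plant_sites <- function(genome, n_sites,
                        strengths = c(meanlog = log(100), sdlog = 0.5),
                        motif = NULL, kind = "canonical", stagger = 5L,
                        satellites = 0L, satellite_offset = c(8L, 30L),
                        satellite_strength = 0.2,
                        min_separation = NULL, seed = 1L) {
  if (n_sites < 0) abort("`n_sites` must be >= 0.")
  empty <- tibble(center = integer(), strength = double(),
                  kind = character(), parent = integer(), stagger = integer())
  if (n_sites == 0) return(list(sites = empty, genome = genome))
  if (!kind %in% c("canonical", "composite")) {
    abort("`kind` must be 'canonical' or 'composite'.")
  }
  L <- genome$length
  motif_w <- if (is.null(motif)) 0L else 2L * motif$halfwidth + motif$overhang
  if (is.null(min_separation)) {
    min_separation <- max(stagger + 1L, motif_w) +
      if (satellites > 0) 2L * max(satellite_offset) else 0L
  }
  margin <- if (genome$circular) 0L else {
    max(motif_w, stagger + 1L, if (satellites > 0) max(satellite_offset) else 0L)
  }
  # place centers with guaranteed pairwise (and wrap) gaps >= min_separation:
  # sort n draws from the slack space and re-inflate by the separation
  slack <- L - 2L * margin - n_sites * min_separation
  if (slack <= 0) {
    abort("`n_sites` too large to place without overlap.")
  }
  withr::with_seed(seed, {
    y <- sort(sample.int(slack + 1L, n_sites, replace = TRUE) - 1L)
    centers <- y + (seq_len(n_sites) - 1L) * min_separation + margin
    str <- if (length(strengths) == n_sites && is.null(names(strengths))) {
      as.numeric(strengths)
    } else {
      rlnorm(n_sites, meanlog = strengths[["meanlog"]],
             sdlog = strengths[["sdlog"]])
    }
    sites <- tibble(center = centers, strength = str, kind = kind,
                    parent = NA_integer_, stagger = as.integer(stagger))
    if (satellites > 0) {
      sat <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
        off <- sample(satellite_offset[1]:satellite_offset[2], satellites,
                      replace = TRUE) *
          sample(c(-1L, 1L), satellites, replace = TRUE)
        tibble(center = (sites$center[i] + off) %% L,
               strength = sites$strength[i] * satellite_strength,
               kind = "satellite", parent = sites$center[i],
               stagger = as.integer(stagger))
      })
      sites <- bind_rows(sites, sat)
    }
    sites <- sites |> distinct(.data$center, .keep_all = TRUE) |>
      arrange(.data$center)
    if (!is.null(motif)) {
      seqs <- sample_motif_sequences(motif, nrow(sites))
      for (i in seq_len(nrow(sites))) {
        genome <- replace_genome_window(
          genome, sites$center[i] - motif$halfwidth, seqs[i])
      }
    }
    list(sites = sites, genome = genome)
  })
}

# Uniform sonication lengths within the configured range.
frag_lengths <- function(n, cfg) {
  if (n == 0) return(integer())
  sample(seq(cfg$fragment_length_min, cfg$fragment_length_max), n,
         replace = TRUE)
}

# Normalize raw (possibly negative / overhanging) fragment coordinates:
# circular genomes wrap (start stored mod L, end = start + len, possibly > L);
# linear genomes are truncated at the ends.
normalize_frags <- function(start, end, strand, L, circular) {
  keep <- end > start
  start <- start[keep]; end <- end[keep]; strand <- strand[keep]
  if (circular) {
    len <- end - start
    start <- ((start %% L) + L) %% L
    end <- start + len
  } else {
    start <- pmax(start, 0L)
    end <- pmin(end, L)
    keep <- end > start
    start <- start[keep]; end <- end[keep]; strand <- strand[keep]
  }
  tibble(start = as.integer(start), end = as.integer(end), strand = strand)
}

background_frags <- function(n, cfg, L, circular) {
  if (n == 0) {
    return(tibble(start = integer(), end = integer(), strand = character()))
  }
  len <- frag_lengths(n, cfg)
  start <- if (circular) {
    sample.int(L, n, replace = TRUE) - 1L
  } else {
    floor(runif(n) * (L - len + 1))
  }
  tibble(start = as.integer(start), end = as.integer(start + len),
         strand = sample(c("+", "-"), n, replace = TRUE))
}

# One canonical trapped complex at center c emits up to four fragments:
# top-strand scissile bond between c-1 and c, bottom-strand bond between
# c+stagger-2 and c+stagger-1 (top-strand coordinates). Free-3'-OH sides:
# forward [s, c) (3' end c-1) and reverse [c+stagger-1, s') (3' end, leftmost
# coordinate, c+stagger-1). Covalent-5' sides: forward [c, s'') and reverse
# [s''', c+stagger-1) (5' end c+stagger-2).
canonical_site_frags <- function(center, stagger, k, cfg, L, circular) {
  if (k == 0) {
    return(tibble(start = integer(), end = integer(), strand = character()))
  }
  piece <- function(n, eff, start_fun) {
    keep <- stats::rbinom(n, 1L, eff) == 1L
    m <- sum(keep)
    if (m == 0) {
      return(tibble(start = integer(), end = integer(), strand = character()))
    }
    len <- frag_lengths(m, cfg)
    start_fun(len)
  }
  bind_rows(
    piece(k, cfg$capture_efficiency_3p, function(len) {
      tibble(start = center - len, end = center, strand = "+")
    }),
    piece(k, cfg$capture_efficiency_3p, function(len) {
      tibble(start = center + stagger - 1L,
             end = center + stagger - 1L + len, strand = "-")
    }),
    piece(k, cfg$capture_efficiency_5p, function(len) {
      tibble(start = center, end = center + len, strand = "+")
    }),
    piece(k, cfg$capture_efficiency_5p, function(len) {
      tibble(start = center + stagger - 1L - len,
             end = center + stagger - 1L, strand = "-")
    })
  ) |>
    (\(d) normalize_frags(d$start, d$end, d$strand, L, circular))()
}

# A composite locus is the superposition of two independent single-strand
# cleavage events with inverted strand roles: a top-strand nick between f and
# f+1 (forward 3' ends at f) and a bottom-strand nick between r-1 and r where
# r = f - stagger (reverse 3' ends at r). No uncovered gap results; coverage
# from the two streams overlaps on the stagger+1 positions [r, f].
composite_locus_frags <- function(f, stagger, kf, kr, cfg, L, circular) {
  piece <- function(n, eff, start_fun) {
    if (n == 0) {
      return(tibble(start = integer(), end = integer(), strand = character()))
    }
    keep <- stats::rbinom(n, 1L, eff) == 1L
    m <- sum(keep)
    if (m == 0) {
      return(tibble(start = integer(), end = integer(), strand = character()))
    }
    len <- frag_lengths(m, cfg)
    start_fun(len)
  }
  r <- f - stagger
  bind_rows(
    piece(kf, cfg$capture_efficiency_3p, function(len) {
      tibble(start = f + 1L - len, end = f + 1L, strand = "+")
    }),
    piece(kf, cfg$capture_efficiency_5p, function(len) {
      tibble(start = f + 1L, end = f + 1L + len, strand = "+")
    }),
    piece(kr, cfg$capture_efficiency_3p, function(len) {
      tibble(start = r, end = r + len, strand = "-")
    }),
    piece(kr, cfg$capture_efficiency_5p, function(len) {
      tibble(start = r - len, end = r, strand = "-")
    })
  ) |>
    (\(d) normalize_frags(d$start, d$end, d$strand, L, circular))()
}

#' Emit fragments for a fixed number of trapping events
#'
#' Low-level access to the staggered-cut fragment geometry with an exact
#' event count (no Poisson draw): `trapped_complex_fragments()` emits the
#' canonical four-fragment pattern for `events` trapped complexes at
#' `center`; `composite_fragments()` emits the two inverted single-strand
#' streams of a composite locus whose forward wall is at `fwd_wall`.
#' Randomness (capture Bernoullis, sonication lengths) comes from the
#' current RNG state.
#'
#' @param center 0-based cleavage center (first overhang base).
#' @param stagger Wall offset.
#' @param events Number of trapping events.
#' @param config A `simulation_config`.
#' @param genome_length Genome length in bp.
#' @param circular Wrap origin-crossing fragments?
#' @return A tibble: `start`, `end`, `strand`.
#' @export
trapped_complex_fragments <- function(center, stagger, events, config,
                                      genome_length, circular = TRUE) {
  canonical_site_frags(center, stagger, events, config, genome_length,
                       circular)
}

#' @rdname trapped_complex_fragments
#' @param fwd_wall Forward-wall coordinate f (the reverse wall sits at
#'   `f - stagger`).
#' @param events_fwd,events_rev Events in the forward-only and reverse-only
#'   cleavage streams.
#' @export
composite_fragments <- function(fwd_wall, stagger, events_fwd, events_rev,
                                config, genome_length, circular = TRUE) {
  composite_locus_frags(fwd_wall, stagger, events_fwd, events_rev, config,
                        genome_length, circular)
}

site_event_count <- function(strength, condition, cfg) {
  if (!condition$drug) return(0L)
  lambda <- strength * if (condition$ip) 1 else cfg$mock_dilution
  rpois(1L, lambda)
}

#' Simulate one sequencing sample
#'
#' Emits background fragments (uniform intervals, lengths uniform in the
#' sonication range, both strands) for every condition, plus, for +drug
#' conditions, trapped-complex fragments at each planted site: canonical and
#' satellite sites emit the four-fragment staggered-cut geometry (see
#' [simulation_config()]); composite sites emit two inverted single-strand
#' streams. Events per site are Poisson with the site strength; -IP (mock)
#' samples dilute site fragments by `mock_dilution`; -drug samples carry
#' none. For composite-kind rows in `sites`, `center` follows the TCS
#' convention (the reverse wall), i.e. the forward wall sits at
#' `center + stagger`.
#'
#' @param genome A `synthetic_genome`.
#' @param sites Truth tibble from [plant_sites()] (may be empty).
#' @param condition A one-row condition tibble from [sample_condition()].
#' @param config A `simulation_config`.
#' @param seed Integer seed; defaults to `derive_seed(config$seed, label)`.
#' @return A fragment tibble: `sample`, `chrom`, `start`, `end` (0-based
#'   half-open; `end` may exceed the genome length for origin-wrapping
#'   fragments on circular genomes), `strand` ("+"/"-"), `count`.
#' @export
simulate_sample <- function(genome, sites, condition, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(condition) != 1) abort("`condition` must be a single condition row.")
  L <- genome$length
  if (nrow(sites) > 0 && any(sites$center < 0 | sites$center >= L)) {
    abort("Site center outside the genome.")
  }
  if (is.null(seed)) seed <- derive_seed(config$seed, condition$label)
  withr::with_seed(seed, {
    frags <- list(background_frags(config$background_fragments, config, L,
                                   genome$circular))
    if (nrow(sites) > 0 && condition$drug) {
      for (i in seq_len(nrow(sites))) {
        st <- sites$stagger[i]
        if (sites$kind[i] == "composite") {
          kf <- site_event_count(sites$strength[i], condition, config)
          kr <- site_event_count(sites$strength[i], condition, config)
          frags[[length(frags) + 1L]] <- composite_locus_frags(
            sites$center[i] + st, st, kf, kr, config, L, genome$circular)
        } else {
          k <- site_event_count(sites$strength[i], condition, config)
          frags[[length(frags) + 1L]] <- canonical_site_frags(
            sites$center[i], st, k, config, L, genome$circular)
        }
      }
    }
    bind_rows(frags) |>
      mutate(sample = condition$label, chrom = genome$name, count = 1L) |>
      select("sample", "chrom", "start", "end", "strand", "count")
  })
}

#' Simulate a composite (inverted single-strand) cleavage locus
#'
#' Background fragments plus two independent single-strand cleavage streams
#' with inverted strand roles relative to a canonical site: forward-strand
#' 3' ends pile up at `center` (= f) and reverse-strand 3' ends at
#' `center - stagger`. Instead of a 4-bp uncovered gap, both-strand coverage
#' overlaps on `stagger + 1` positions. With `strength = 0` the output is
#' identical to a background-only sample under the same seed.
#'
#' @param genome A `synthetic_genome`.
#' @param center Forward-wall coordinate f (forward-strand N3E maximum).
#' @param stagger Wall offset; the reverse wall sits at `center - stagger`.
#' @param strength Expected events per stream.
#' @param condition One-row condition tibble.
#' @param config A `simulation_config`.
#' @param seed Integer seed (defaults as in [simulate_sample()]).
#' @return A fragment tibble as in [simulate_sample()].
#' @export
simulate_composite_site <- function(genome, center, stagger = 5L, strength,
                                    condition, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  L <- genome$length
  if (center < 0 || center >= L) abort("Site center outside the genome.")
  if (is.null(seed)) seed <- derive_seed(config$seed, condition$label)
  withr::with_seed(seed, {
    bg <- background_frags(config$background_fragments, config, L,
                           genome$circular)
    kf <- site_event_count(strength, condition, config)
    kr <- site_event_count(strength, condition, config)
    site <- composite_locus_frags(center, stagger, kf, kr, config, L,
                                  genome$circular)
    bind_rows(bg, site) |>
      mutate(sample = condition$label, chrom = genome$name, count = 1L) |>
      select("sample", "chrom", "start", "end", "strand", "count")
  })
}

#' Simulate a full experiment
#'
#' Runs [simulate_sample()] for every condition row (by default the full
#' +/-drug x +/-IP grid in `config$n_replicates` replicates) and binds the
#' fragment tibbles.
#'
#' @inheritParams simulate_sample
#' @param conditions Condition tibble; defaults to
#'   `condition_grid(config$n_replicates)`.
#' @return A fragment tibble with one row per fragment across all samples.
#' @export
simulate_experiment <- function(genome, sites, config, conditions = NULL) {
  if (is.null(conditions)) conditions <- condition_grid(config$n_replicates)
  purrr::map_dfr(seq_len(nrow(conditions)), function(i) {
    simulate_sample(genome, sites, conditions[i, ], config)
  })
}

#' Write / read planted-site truth files
#'
#' The BED file records each site as the 0-based half-open overhang interval
#' `[center, center + stagger - 1)`... more precisely `[c, c + overhang]`
#' with `overhang = stagger - 1` (so `[1000, 1004)` for the default 4-nt
#' overhang), name = kind, score = rounded strength. The TSV carries the full
#' truth table and round-trips exactly.
#'
#' @param sites Truth tibble from [plant_sites()].
#' @param bed_path,tsv_path Output paths.
#' @param chrom Chromosome name for the BED file.
#' @return Paths, invisibly.
#' @export
write_truth <- function(sites, bed_path, tsv_path, chrom = "chr_synth") {
  overhang <- if (nrow(sites) > 0) sites$stagger - 1L else integer()
  bed <- tibble(
    chrom = rep(chrom, nrow(sites)),
    start = sites$center,
    end = sites$center + overhang,
    name = sites$kind,
    score = round(sites$strength),
    strand = rep("+", nrow(sites))
  )
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  readr::write_tsv(sites, tsv_path)
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' @rdname write_truth
#' @param path Truth TSV path.
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    center = readr::col_integer(),
    strength = readr::col_double(),
    kind = readr::col_character(),
    parent = readr::col_integer(),
    stagger = readr::col_integer()
  ))
}
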