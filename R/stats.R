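#' Binomial enrichment of cleavage sites in genomic regions
#'
#' For each region, counts sites whose center falls inside the half-open
#' interval `[start, end)` (regions with `start > end` wrap the origin on a
#' circular genome), computes the expected count
#' `n_total * region_length / genome_length`, and an exact two-sided
#' binomial p-value by doubling the smaller tail (capped at 1). Direction is
#' "enriched" when fold > 1, "depleted" otherwise.
#'
#' @param tcs TCS tibble with a `center` column.
#' @param regions Region tibble with `name`, `start`, `end` (0-based
#'   half-open bp).
#' @param genome_length Genome length in bp.
#' @return A tibble with one row per region: `region`, `observed`,
#'   `expected`, `fold`, `p`, `n_total`, `direction`.
#' @export
region_enrichment <- function(tcs, regions, genome_length) {
  n <- nrow(tcs)
  if (n == 0) abort("Empty site set.")
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    start <- regions$start[i]
    end <- regions$end[i]
    len <- end - start
    if (len <= 0) len <- len + genome_length
    if (len <= 0 || len > genome_length) abort("Zero-length or invalid region.")
    inside <- if (end > start) {
      tcs$center >= start & tcs$center < end
    } else {
      tcs$center >= start | tcs$center < end
    }
    observed <- sum(inside)
    pr <- len / genome_length
    expected <- n * pr
    p_lo <- pbinom(observed, n, pr)
    p_hi <- pbinom(observed - 1, n, pr, lower.tail = FALSE)
    tibble(
      region = regions$name[i],
      observed = observed,
      expected = expected,
      fold = observed / expected,
      p = min(1, 2 * min(p_lo, p_hi)),
      n_total = n,
      direction = if (observed / expected > 1) "enriched" else "depleted"
    )
  })
}

#' Count cleavage sites in fixed-width genomic bins
#'
#' Half-open bins `[k*bin, (k+1)*bin)`; the final partial bin is kept, so bin
#' counts always sum to the number of sites.
#'
#' @param tcs TCS tibble with a `center` column.
#' @param bin Bin width in bp (> 0).
#' @param genome_length Genome length in bp.
#' @return A tibble: `bin_start`, `bin_end`, `count`.
#' @export
bin_density <- function(tcs, bin, genome_length) {
  if (bin <= 0) abort("`bin` must be > 0.")
  starts <- seq(0, genome_length - 1, by = bin)
  ends <- pmin(starts + bin, genome_length)
  idx <- findInterval(tcs$center, starts)
  counts <- tabulate(idx, nbins = length(starts))
  tibble(bin_start = as.integer(starts), bin_end = as.integer(ends),
         count = counts)
}

region_values <- function(tcs, regions, genome_length, value = "score") {
  unlist(purrr::map(seq_len(nrow(regions)), function(i) {
    start <- regions$start[i]
    end <- regions$end[i]
    inside <- if (end > start) {
      tcs$center >= start & tcs$center < end
    } else {
      tcs$center >= start | tcs$center < end
    }
    tcs[[value]][inside]
  }))
}

#' Compare mean site enrichment between two region groups
#'
#' Welch two-tailed t-test on per-site scores (e.g. mean wall fold
#' enrichment) of sites falling in two groups of regions — e.g. the 500-kb
#' flanks on either side of a macrodomain versus the next 500-kb windows.
#'
#' @param tcs TCS tibble with `center` and a value column.
#' @param regions_a,regions_b Region tibbles (`name`, `start`, `end`).
#' @param genome_length Genome length in bp.
#' @param value Column of `tcs` to compare (default `"score"`).
#' @return A one-row tibble: `mean_a`, `mean_b`, `t`, `df`, `p`, `n_a`,
#'   `n_b`.
#' @export
compare_region_means <- function(tcs, regions_a, regions_b, genome_length,
                                 value = "score") {
  va <- region_values(tcs, regions_a, genome_length, value)
  vb <- region_values(tcs, regions_b, genome_length, value)
  if (length(va) < 2 || length(vb) < 2) {
    abort("Each region group must contain at least 2 site values.")
  }
  if (stats::sd(c(va, vb)) == 0) {
    abort("Degenerate samples: all values are constant.")
  }
  tt <- t.test(va, vb, var.equal = FALSE, alternative = "two.sided")
  tibble(
    mean_a = mean(va), mean_b = mean(vb),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, n_a = length(va), n_b = length(vb)
  )
}

fe_values <- function(track) {
  if (inherits(track, "fe_track")) track$fe else as.numeric(track)
}

wrap_index <- function(pos, L, circular) {
  if (circular) {
    (pos %% L) + 1L
  } else {
    out <- pos + 1L
    out[pos < 0 | pos >= L] <- NA_integer_
    out
  }
}

# Orient one TU 5'->3' and return its profile: flank upstream at native
# resolution, body averaged into body_bins, flank downstream.
tu_profile <- function(values, L, circular, start, end, strand, flank,
                       body_bins) {
  if (strand == "+") {
    up <- seq(start - flank, start - 1)
    body <- seq(start, end - 1)
    down <- seq(end, end + flank - 1)
  } else {
    up <- base::rev(seq(end, end + flank - 1))
    body <- base::rev(seq(start, end - 1))
    down <- base::rev(seq(start - flank, start - 1))
  }
  bvals <- values[wrap_index(body, L, circular)]
  bins <- floor((seq_along(bvals) - 1) / length(bvals) * body_bins) + 1
  body_means <- as.numeric(tapply(bvals, bins, mean))
  c(
    if (flank > 0) values[wrap_index(up, L, circular)] else numeric(),
    body_means,
    if (flank > 0) values[wrap_index(down, L, circular)] else numeric()
  )
}

#' Metagene profile of fold enrichment over transcription units
#'
#' Each transcription unit (TU) is oriented 5'->3' by strand; its body is
#' length-normalized into `body_bins` bins and its flanks are kept at native
#' single-bp resolution. Per-bin values are averaged within each TU and then
#' across TUs (mean of means, so long TUs do not dominate). TUs are
#' stratified by expression quantiles: "all", "HETU" (top `strata` fraction)
#' and "LETU" (bottom `strata` fraction). TUs with a body shorter than 2 bp
#' per bin are skipped with a message.
#'
#' @param track An `fe_track` or numeric per-position vector.
#' @param tus TU tibble: `name`, `start`, `end` (0-based half-open),
#'   `strand` ("+"/"-"), `expression` (>= 0).
#' @param flank Flank width in bp (>= 0).
#' @param body_bins Number of body bins (>= 1).
#' @param strata Quantile fraction defining the HETU/LETU strata.
#' @param min_stratum Minimum TUs per stratum; smaller strata are dropped
#'   with a message.
#' @param circular Wrap flanks at the genome ends (used when `track` is a
#'   bare vector; an `fe_track` carries its own flag).
#' @return A tibble: `stratum`, `n_tus`, `bin` (1-based along the oriented
#'   profile), `region` ("upstream"/"body"/"downstream"), `offset` (bp from
#'   TU start/end for flanks, bin index within body), `mean_fe`.
#' @export
metagene <- function(track, tus, flank = 1000L, body_bins = 50L,
                     strata = 0.1, min_stratum = 20L, circular = TRUE) {
  if (flank < 0) abort("`flank` must be >= 0.")
  if (body_bins < 1) abort("`body_bins` must be >= 1.")
  values <- fe_values(track)
  if (inherits(track, "fe_track")) circular <- track$circular
  L <- length(values)
  keep <- (tus$end - tus$start) >= 2 * body_bins
  if (any(!keep)) {
    inform(sprintf("Skipping %d TU(s) shorter than 2 bp per body bin.",
                   sum(!keep)))
  }
  tus <- tus[keep, , drop = FALSE]
  if (nrow(tus) == 0) abort("No TUs left after length filtering.")

  profiles <- vapply(seq_len(nrow(tus)), function(i) {
    tu_profile(values, L, circular, tus$start[i], tus$end[i], tus$strand[i],
               flank, body_bins)
  }, numeric(2L * flank + body_bins))
  profiles <- matrix(profiles, ncol = nrow(tus))

  qs <- stats::quantile(tus$expression, c(strata, 1 - strata))
  groups <- list(
    all = rep(TRUE, nrow(tus)),
    HETU = tus$expression >= qs[[2]],
    LETU = tus$expression <= qs[[1]]
  )
  nbin <- 2L * flank + body_bins
  region <- c(rep("upstream", flank), rep("body", body_bins),
              rep("downstream", flank))
  offset <- c(if (flank > 0) seq(-flank, -1) else integer(),
              seq_len(body_bins),
              if (flank > 0) seq_len(flank) else integer())
  purrr::imap_dfr(groups, function(sel, nm) {
    if (sum(sel) < min_stratum && nm != "all") {
      inform(sprintf("Dropping stratum %s (%d TUs < %d).", nm, sum(sel),
                     min_stratum))
      return(NULL)
    }
    tibble(
      stratum = nm, n_tus = sum(sel), bin = seq_len(nbin), region = region,
      offset = offset,
      mean_fe = rowMeans(profiles[, sel, drop = FALSE], na.rm = TRUE)
    )
  })
}

#' Correlation of two enrichment tracks downstream of transcription units
#'
#' For each TU, takes the mean of each track over the strand-aware window
#' immediately downstream (`[end, end + window)` for forward TUs,
#' `[start - window, start)` for reverse TUs) and reports the Pearson
#' correlation of the two per-TU means.
#'
#' @param track_a,track_b `fe_track`s or numeric vectors of equal length.
#' @param tus TU tibble (see [metagene()]).
#' @param window Downstream window width in bp (> 0).
#' @param circular Wrap windows at the genome ends.
#' @return A one-row tibble: `r`, `p`, `n` (TUs used).
#' @export
downstream_correlation <- function(track_a, track_b, tus, window = 5000L,
                                   circular = TRUE) {
  if (window <= 0) abort("`window` must be > 0.")
  va <- fe_values(track_a)
  vb <- fe_values(track_b)
  if (length(va) != length(vb)) abort("Track lengths differ.")
  if (inherits(track_a, "fe_track")) circular <- track_a$circular
  L <- length(va)
  if (nrow(tus) < 3) abort("Need at least 3 TUs.")
  down_mean <- function(values, i) {
    pos <- if (tus$strand[i] == "+") {
      seq(tus$end[i], tus$end[i] + window - 1)
    } else {
      seq(tus$start[i] - window, tus$start[i] - 1)
    }
    mean(values[wrap_index(pos, L, circular)], na.rm = TRUE)
  }
  ma <- vapply(seq_len(nrow(tus)), function(i) down_mean(va, i), numeric(1))
  mb <- vapply(seq_len(nrow(tus)), function(i) down_mean(vb, i), numeric(1))
  if (stats::sd(ma) == 0 || stats::sd(mb) == 0) {
    abort("Zero variance in downstream means.")
  }
  ct <- cor.test(ma, mb, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = nrow(tus))
}
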