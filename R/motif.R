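#' Cleavage-motif frame
#'
#' Motif coordinates are anchored on the cleavage center `c` (the first base
#' of the 4-nt 5'-overhang). There is no position 0: position `+1` is the base
#' at `c`, so motif position `k` maps to genome coordinate `c + k - 1` for
#' `k >= 1` and `c + k` for `k <= -1`. A matrix with halfwidth `W` and
#' overhang `v` spans positions `-W..-1, +1..+(W+v)` (width `2W + v`),
#' symmetric about the dyad axis between `+2` and `+3` so that position `i`
#' pairs with `j = 4 - i`.
#'
#' @param halfwidth Number of positions left of the cut.
#' @param overhang Overhang length in nt (4 for type-IIA enzymes).
#' @return Integer vector of motif position labels.
#' @export
motif_positions <- function(halfwidth, overhang = 4L) {
  left <- if (halfwidth > 0) seq(-halfwidth, -1L) else integer()
  c(left, seq(1L, halfwidth + overhang))
}

BASES <- c("A", "C", "G", "T")

new_motif_matrix <- function(counts, halfwidth, overhang = 4L) {
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  rownames(counts) <- BASES
  pos <- motif_positions(halfwidth, overhang)
  stopifnot(ncol(counts) == length(pos))
  colnames(counts) <- as.character(pos)
  totals <- colSums(counts)
  freq <- sweep(counts, 2, pmax(totals, .Machine$double.eps), "/")
  plogp <- ifelse(freq > 0, freq * log2(freq), 0)
  structure(
    list(
      counts = counts,
      freq = freq,
      positions = pos,
      halfwidth = as.integer(halfwidth),
      overhang = as.integer(overhang),
      weights_total = unname(totals[1]),
      ic = 2 + colSums(plogp),
      gc = unname(freq["G", ] + freq["C", ])
    ),
    class = "motif_matrix"
  )
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf(
    "<motif_matrix> positions %d..%d (no 0), overhang %d, effective n = %.1f\n",
    min(x$positions), max(x$positions), x$overhang, x$weights_total))
  cat(sprintf("  consensus: %s\n", motif_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a motif
#'
#' @param m A `motif_matrix`.
#' @return Character string, the modal base per column.
#' @export
motif_consensus <- function(m) {
  paste(BASES[apply(m$freq, 2, which.max)], collapse = "")
}

#' Build a motif with fixed determinant positions
#'
#' Constructs a position frequency matrix carrying the dyad-symmetric
#' determinants of the type-IIA cleavage consensus: G at -4 / C at +8,
#' A at -2 / T at +6, T at -1 / A at +5 and, with `extended = TRUE`, also
#' C at -7 / G at +11 and C at -6 / G at +10. Determinant columns assign
#' probability `prob` to the preferred base ((1 - prob)/3 to each other
#' base); all remaining columns are uniform. Used to plant recoverable motifs
#' in synthetic genomes.
#'
#' @param halfwidth Positions left of the cut (must cover the determinants).
#' @param prob Probability of the preferred base at determinant columns.
#' @param extended Include the -7/-6 (and +10/+11) determinants?
#' @param overhang Overhang length.
#' @return A `motif_matrix`.
#' @examples
#' m <- determinant_motif()
#' motif_consensus(m)
#' @export
determinant_motif <- function(halfwidth = 8L, prob = 0.8, extended = FALSE,
                              overhang = 4L) {
  det <- c("-4" = "G", "-2" = "A", "-1" = "T",
           "5" = "A", "6" = "T", "8" = "C")
  if (extended) {
    det <- c(det, "-7" = "C", "-6" = "C", "10" = "G", "11" = "G")
  }
  pos <- motif_positions(halfwidth, overhang)
  need <- as.integer(names(det))
  if (!all(need %in% pos)) {
    abort("`halfwidth` too small to hold the determinant positions.")
  }
  counts <- matrix(25, nrow = 4, ncol = length(pos),
                   dimnames = list(BASES, as.character(pos)))
  for (p in names(det)) {
    col <- rep((1 - prob) / 3, 4)
    col[match(det[[p]], BASES)] <- prob
    counts[, p] <- col * 100
  }
  new_motif_matrix(counts, halfwidth, overhang)
}

#' Sample sequences from a motif
#'
#' Draws `n` sequences column-wise from the motif's per-position base
#' frequencies. Randomness comes from the current RNG state (wrap in a seed
#' context for reproducibility).
#'
#' @param m A `motif_matrix`.
#' @param n Number of sequences.
#' @return Character vector of `n` sequences of the motif's width.
#' @export
sample_motif_sequences <- function(m, n) {
  cols <- lapply(seq_len(ncol(m$freq)), function(j) {
    sample(BASES, n, replace = TRUE, prob = m$freq[, j])
  })
  do.call(paste0, cols)
}

#' Extract sequence windows around cleavage centers
#'
#' Returns the top-strand sequence around each site in the fixed motif frame:
#' genome coordinates `c - halfwidth .. c + halfwidth + overhang - 1` for a
#' site with center `c`. Windows wrap on circular genomes; on a linear genome
#' a window off either end is an error.
#'
#' @param genome A `synthetic_genome`.
#' @param sites A tibble of sites with a `center` column (e.g. a TCS table or
#'   a planted-site truth table); a `score` column supplies weights.
#' @param halfwidth Positions left of the cut.
#' @param weighted Use the `score` column as window weight (weight 1 when
#'   `FALSE` or when no score column is present).
#' @param overhang Overhang length.
#' @return A tibble with columns `center`, `sequence`, `weight`.
#' @export
extract_windows <- function(genome, sites, halfwidth = 13L, weighted = TRUE,
                            overhang = 4L) {
  if (halfwidth < 1) abort("`halfwidth` must be >= 1.")
  if (nrow(sites) == 0) {
    return(tibble(center = integer(), sequence = character(),
                  weight = double()))
  }
  width <- 2L * halfwidth + overhang
  seqs <- vapply(sites$center, function(c0) {
    genome_window(genome, c0 - halfwidth, width)
  }, character(1))
  if (any(grepl("[^ACGTN]", seqs))) {
    abort("Windows may contain only A/C/G/T/N.")
  }
  w <- if (weighted && "score" %in% names(sites)) {
    as.numeric(sites$score)
  } else {
    rep(1, nrow(sites))
  }
  tibble(center = sites$center, sequence = seqs, weight = w)
}

#' Build a position frequency matrix from sequence windows
#'
#' Column counts are weight sums of the sequences carrying each base; an `N`
#' contributes 1/4 of its weight to each base. Per-column information content
#' is `2 + sum_b f_b log2 f_b` bits (uniform background) and GC is
#' `f_G + f_C`.
#'
#' @param windows A tibble with `sequence` and (optionally) `weight` columns,
#'   as from [extract_windows()]. All sequences must have equal length
#'   `2*halfwidth + overhang`.
#' @param overhang Overhang length used to recover the motif frame.
#' @return A `motif_matrix`.
#' @export
build_pfm <- function(windows, overhang = 4L) {
  seqs <- windows$sequence
  if (length(seqs) == 0) abort("No windows supplied.")
  w <- if ("weight" %in% names(windows)) as.numeric(windows$weight) else {
    rep(1, length(seqs))
  }
  if (any(w < 0) || all(w == 0)) abort("Weights must be >= 0 and not all 0.")
  widths <- unique(nchar(seqs))
  if (length(widths) != 1) abort("Windows have mixed lengths.")
  if ((widths - overhang) %% 2 != 0 || widths < overhang) {
    abort("Window width does not match the motif frame (2*halfwidth + overhang).")
  }
  if (any(grepl("[^ACGTN]", seqs))) abort("Windows may contain only A/C/G/T/N.")
  halfwidth <- (widths - overhang) / 2
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  counts <- matrix(0, nrow = 4, ncol = widths, dimnames = list(BASES, NULL))
  for (b in BASES) {
    counts[b, ] <- colSums((chars == b) * w)
  }
  n_mask <- chars == "N"
  if (any(n_mask)) {
    add <- colSums(n_mask * w) / 4
    counts <- sweep(counts, 2, add, "+")
  }
  new_motif_matrix(counts, halfwidth, overhang)
}

#' Check dyad symmetry of motif determinants
#'
#' The staggered cut places the dyad axis between motif positions +2 and +3,
#' so position `i` pairs with `j = 4 - i`. For each candidate position the
#' modal base is taken if its frequency reaches `dominance`; the pair is
#' flagged complementary when both modal bases exist and are Watson-Crick
#' complements.
#'
#' @param m A `motif_matrix`.
#' @param candidates Integer motif positions to test (no 0).
#' @param dominance Minimum modal-base frequency (the motif is weak, so the
#'   default only asks for enrichment above the 0.25 background).
#' @return A tibble with columns `i`, `j`, `base_i`, `base_j`,
#'   `complementary`.
#' @export
dyad_check <- function(m, candidates, dominance = 0.3) {
  if (!all(candidates %in% m$positions)) {
    abort("Candidate positions outside the motif frame.")
  }
  partners <- 4L - as.integer(candidates)
  if (!all(partners %in% m$positions)) {
    abort("Dyad partner position outside the motif frame.")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  modal <- function(p) {
    f <- m$freq[, as.character(p)]
    b <- BASES[which.max(f)]
    if (max(f) >= dominance) b else NA_character_
  }
  bi <- vapply(candidates, modal, character(1))
  bj <- vapply(partners, modal, character(1))
  tibble(
    i = as.integer(candidates),
    j = partners,
    base_i = bi,
    base_j = bj,
    complementary = !is.na(bi) & !is.na(bj) & comp[bi] == bj
  )
}

#' Long-range GC profile around cleavage centers
#'
#' Column-wise GC fraction over windows around all site centers, optionally
#' smoothed, with an autocorrelation scan of the mean-subtracted profile to
#' expose periodicity (reported, not thresholded). A DNA-wrapping enzyme
#' leaves ~10-bp periodic GC structure in its flanks; its absence supports a
#' wrapping-free binding mode.
#'
#' @param genome A `synthetic_genome`.
#' @param sites Site tibble with `center` column.
#' @param halfwidth Flank width in bp (up to 2000 supported).
#' @param smooth_window Odd moving-average window (1 = no smoothing).
#' @param max_lag Maximum autocorrelation lag reported.
#' @return A tibble with columns `position` (motif frame), `gc` and
#'   `gc_smoothed`, with the autocorrelation tibble (`lag`, `acf`) attached
#'   as attribute `"autocorrelation"` (see [profile_autocorrelation()]).
#' @export
gc_profile <- function(genome, sites, halfwidth = 2000L, smooth_window = 1L,
                       max_lag = 50L) {
  if (nrow(sites) == 0) abort("Empty site set.")
  win <- extract_windows(genome, sites, halfwidth = halfwidth,
                         weighted = FALSE)
  chars <- matrix(unlist(strsplit(win$sequence, "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = nrow(win), byrow = TRUE)
  gc <- colMeans(chars == "G" | chars == "C")
  smoothed <- smooth_values(gc, smooth_window, circular = FALSE)
  out <- tibble(
    position = motif_positions(halfwidth),
    gc = gc,
    gc_smoothed = smoothed
  )
  attr(out, "autocorrelation") <- profile_autocorrelation(gc, max_lag)
  out
}

#' Autocorrelation of a positional profile
#'
#' Mean-subtracts the profile and reports its autocorrelation at lags
#' `1..max_lag` (a peak at lag 10 indicates helical-period structure).
#'
#' @param values Numeric profile.
#' @param max_lag Maximum lag.
#' @return A tibble with columns `lag` and `acf`.
#' @export
profile_autocorrelation <- function(values, max_lag = 50L) {
  max_lag <- min(max_lag, length(values) - 2L)
  a <- stats::acf(values - mean(values), lag.max = max_lag, plot = FALSE,
                  demean = FALSE)
  tibble(lag = seq_len(max_lag), acf = as.numeric(a$acf)[-1][seq_len(max_lag)])
}

#' @describeIn build_pfm Tidy a motif matrix into one row per position/base
#'   with counts, frequencies and per-position information content and GC.
#' @param x A `motif_matrix`.
#' @param ... Unused.
#' @export
tidy.motif_matrix <- function(x, ...) {
  tibble(
    position = rep(x$positions, each = 4L),
    base = rep(BASES, times = length(x$positions)),
    count = as.numeric(x$counts),
    freq = as.numeric(x$freq),
    ic = rep(unname(x$ic), each = 4L),
    gc = rep(unname(x$gc), each = 4L)
  )
}

#' @describeIn build_pfm One-row summary of a motif matrix.
#' @export
glance.motif_matrix <- function(x, ...) {
  tibble(
    width = length(x$positions),
    halfwidth = x$halfwidth,
    overhang = x$overhang,
    n_eff = x$weights_total,
    total_ic = sum(x$ic),
    max_ic_position = x$positions[which.max(x$ic)]
  )
}

#' Write / read a motif as TSV or JASPAR-style text
#'
#' @param m A `motif_matrix`.
#' @param path Output path.
#' @param name Motif name for the JASPAR header.
#' @return The path, invisibly.
#' @export
write_motif_tsv <- function(m, path) {
  readr::write_tsv(tidy(m), path)
  invisible(path)
}

#' @rdname write_motif_tsv
#' @export
write_motif_jaspar <- function(m, path, name = "cleavage_motif") {
  lines <- c(
    paste0(">", name),
    vapply(BASES, function(b) {
      sprintf("%s  [ %s ]", b,
              paste(formatC(m$counts[b, ], format = "f", digits = 2),
                    collapse = " "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
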