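#' Build per-position signal tracks from aligned fragments
#'
#' Converts a fragment table into strand-specific per-position counts of
#' fragment 3'-ends (N3E), 5'-ends (N5E) and coverage. A forward fragment
#' `[s, e)` has its 5' end at `s` and its 3' end at `e - 1`; a reverse
#' fragment `[s, e)` has its 5' end at `e - 1` and its 3' end at `s` (in
#' top-strand coordinates the reverse-strand 3' end is the leftmost
#' position — the placement forced by the staggered-cut geometry). Fragments
#' with `end > length` wrap the origin on circular genomes.
#'
#' @param fragments Fragment tibble with columns `start`, `end` (0-based
#'   half-open), `strand` ("+"/"-") and optionally `count` and `sample`.
#' @param length Genome length (bp).
#' @param circular Wrap origin-crossing fragments?
#' @param sample Optional sample label to filter on (and record).
#' @return A `signal_tracks` object: integer vectors `n3e_fwd`, `n3e_rev`,
#'   `n5e_fwd`, `n5e_rev`, `cov_fwd`, `cov_rev` of length `length`, plus
#'   per-strand fragment totals.
#' @examples
#' fr <- tibble::tibble(start = 10L, end = 20L, strand = "+")
#' tr <- compute_tracks(fr, length = 50, circular = FALSE)
#' which(tr$n3e_fwd > 0) - 1  # 3' end at position 19
#' @export
compute_tracks <- function(fragments, length, circular = TRUE,
                           sample = NULL) {
  L <- as.integer(length)
  if (!is.null(sample)) {
    fragments <- dplyr::filter(fragments, .data$sample == !!sample)
  } else if ("sample" %in% names(fragments)) {
    labs <- unique(fragments$sample)
    sample <- if (NROW(labs) == 1) labs else NA_character_
  }
  if (!all(fragments$strand %in% c("+", "-"))) {
    abort("Unknown strand value; use '+' or '-'.")
  }
  s <- as.numeric(fragments$start)
  e <- as.numeric(fragments$end)
  w <- if ("count" %in% names(fragments)) as.numeric(fragments$count) else {
    rep(1, nrow(fragments))
  }
  if (any(s >= e)) abort("Fragments must satisfy start < end.")
  if (any(e - s > L)) abort("Fragment longer than the genome.")
  if (!circular && (any(s < 0) || any(e > L))) {
    abort("Fragment outside a linear genome.")
  }
  len <- e - s
  s <- ((s %% L) + L) %% L
  e <- s + len
  fwd <- fragments$strand == "+"

  deposit <- function(pos, wt) {
    v <- numeric(L)
    if (NROW(pos) > 0) {
      agg <- rowsum(wt, pos)
      v[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    }
    v
  }
  coverage <- function(ss, ee, wt) {
    delta <- numeric(L + 1L)
    add <- function(pos, wv) {
      agg <- rowsum(wv, pos)
      idx <- as.integer(rownames(agg)) + 1L
      delta[idx] <<- delta[idx] + agg[, 1]
    }
    if (NROW(ss) > 0) {
      # origin-wrapping fragments deposit as two pieces
      wrap <- ee > L
      add(ss, wt)
      add(pmin(ee, L), -wt)
      if (any(wrap)) {
        add(rep(0, sum(wrap)), wt[wrap])
        add(ee[wrap] - L, -wt[wrap])
      }
    }
    cumsum(delta[seq_len(L)])
  }

  last <- (e - 1) %% L
  structure(
    list(
      sample = if (is.null(sample)) NA_character_ else sample,
      length = L,
      circular = circular,
      n3e_fwd = deposit(last[fwd], w[fwd]),
      n3e_rev = deposit(s[!fwd], w[!fwd]),
      n5e_fwd = deposit(s[fwd], w[fwd]),
      n5e_rev = deposit(last[!fwd], w[!fwd]),
      cov_fwd = coverage(s[fwd], e[fwd], w[fwd]),
      cov_rev = coverage(s[!fwd], e[!fwd], w[!fwd]),
      total_fwd = sum(w[fwd]),
      total_rev = sum(w[!fwd])
    ),
    class = "signal_tracks"
  )
}

#' @export
print.signal_tracks <- function(x, ...) {
  cat(sprintf(
    "<signal_tracks> sample %s: %s bp, %s fwd / %s rev fragments\n",
    x$sample, format(x$length, big.mark = ","),
    format(x$total_fwd, big.mark = ","), format(x$total_rev, big.mark = ",")))
  invisible(x)
}

#' Extract one field of a signal-tracks object
#'
#' `"n3e"`, `"n5e"` and `"coverage"` are strand sums; per-strand fields are
#' `"n3e_fwd"`, `"n3e_rev"`, `"n5e_fwd"`, `"n5e_rev"`, `"cov_fwd"`,
#' `"cov_rev"`.
#'
#' @param tracks A `signal_tracks`.
#' @param field Field name.
#' @return Numeric vector of per-position values.
#' @export
track_field <- function(tracks, field = "n3e") {
  switch(field,
    n3e = tracks$n3e_fwd + tracks$n3e_rev,
    n5e = tracks$n5e_fwd + tracks$n5e_rev,
    coverage = tracks$cov_fwd + tracks$cov_rev,
    n3e_fwd = tracks$n3e_fwd, n3e_rev = tracks$n3e_rev,
    n5e_fwd = tracks$n5e_fwd, n5e_rev = tracks$n5e_rev,
    cov_fwd = tracks$cov_fwd, cov_rev = tracks$cov_rev,
    abort(paste0("Unknown track field: ", field))
  )
}

#' @describeIn compute_tracks Tidy tracks into a long tibble (`position`,
#'   `strand`, `metric`, `value`), optionally restricted to a position range.
#' @param x A `signal_tracks`.
#' @param from,to Optional 0-based position range (inclusive) to tidy.
#' @param ... Unused.
#' @export
tidy.signal_tracks <- function(x, from = 0L, to = x$length - 1L, ...) {
  idx <- seq(from, to) + 1L
  pos <- seq(from, to)
  metrics <- list(n3e = c("n3e_fwd", "n3e_rev"), n5e = c("n5e_fwd", "n5e_rev"),
                  coverage = c("cov_fwd", "cov_rev"))
  purrr::imap_dfr(metrics, function(fields, metric) {
    bind_rows(
      tibble(position = pos, strand = "+", metric = metric,
             value = x[[fields[1]]][idx]),
      tibble(position = pos, strand = "-", metric = metric,
             value = x[[fields[2]]][idx])
    )
  })
}

#' Fold-enrichment track
#'
#' Position-wise ratio of a treatment track to a control track after
#' library-size scaling in the track's own units:
#' `fe[i] = (num[i] + pseudocount) / (scale * den[i] + pseudocount)` with
#' `scale = sum(num) / sum(den)`. The pseudocount keeps the ratio finite at
#' zero-coverage positions; identical numerator and denominator give
#' `fe == 1` everywhere.
#'
#' @param numerator,denominator `signal_tracks` of equal length.
#' @param field Track field to compare (see [track_field()]).
#' @param pseudocount Positive pseudocount (counts).
#' @return An `fe_track` object with elements `fe` (numeric per position),
#'   `scale`, `pseudocount`, `field`, sample labels, `length`, `circular`.
#' @export
normalize_tracks <- function(numerator, denominator, field = "n3e",
                             pseudocount = 1) {
  if (numerator$length != denominator$length) {
    abort("Track lengths differ.")
  }
  if (pseudocount <= 0) abort("`pseudocount` must be > 0.")
  num <- track_field(numerator, field)
  den <- track_field(denominator, field)
  if (sum(den) == 0) abort("Denominator track has zero total counts.")
  scale <- sum(num) / sum(den)
  structure(
    list(
      numerator = numerator$sample,
      denominator = denominator$sample,
      field = field,
      fe = (num + pseudocount) / (scale * den + pseudocount),
      pseudocount = pseudocount,
      scale = scale,
      length = numerator$length,
      circular = numerator$circular
    ),
    class = "fe_track"
  )
}

#' @export
print.fe_track <- function(x, ...) {
  cat(sprintf(
    "<fe_track> %s / %s (%s): %s bp, scale %.4f, median FE %.3f\n",
    x$numerator, x$denominator, x$field,
    format(x$length, big.mark = ","), x$scale, stats::median(x$fe)))
  invisible(x)
}

#' @describeIn normalize_tracks Tidy a fold-enrichment track into a tibble
#'   (`position`, `fe`).
#' @param x An `fe_track`.
#' @param from,to Optional 0-based position range (inclusive).
#' @param ... Unused.
#' @export
tidy.fe_track <- function(x, from = 0L, to = x$length - 1L, ...) {
  tibble(position = seq(from, to), fe = x$fe[seq(from, to) + 1L])
}

# Centered moving average; circular tracks wrap, linear tracks use partial
# windows at the edges so output length is preserved.
smooth_values <- function(values, window, circular = TRUE) {
  if (window %% 2 == 0 || window < 1) {
    abort("`window` must be odd and >= 1.")
  }
  if (window == 1) return(values)
  n <- length(values)
  if (circular) {
    as.numeric(stats::filter(values, rep(1 / window, window), sides = 2,
                             circular = TRUE))
  } else {
    h <- (window - 1L) / 2L
    cs <- cumsum(c(0, values))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
}

#' Smooth a track with a centered moving average
#'
#' @param x A numeric vector, `fe_track`, or `signal_tracks` field values.
#' @param window Odd window width (bp); 1 is the identity.
#' @param circular Wrap at the ends (ignored for `fe_track`, which carries
#'   its own flag).
#' @return Same type as the input (`fe_track` in, `fe_track` out).
#' @export
smooth_track <- function(x, window, circular = TRUE) {
  if (inherits(x, "fe_track")) {
    x$fe <- smooth_values(x$fe, window, x$circular)
    return(x)
  }
  smooth_values(x, window, circular)
}

#' Measure the cleavage geometry at a locus
#'
#' Locates the forward- and reverse-strand N3E maxima (the gap "walls")
#' within a window and reports the interior gap (positions strictly between
#' the walls), the inclusive wall-to-wall span, and the number of positions
#' between the walls (inclusive) covered by fragments of both strands. For a
#' canonical staggered cut the interior gap is `stagger - 1` (4 at defaults)
#' with the reverse wall right of the forward wall; a composite locus
#' inverts the wall order and shows `stagger + 1` both-strand-covered
#' positions instead of a gap.
#'
#' @param tracks A `signal_tracks`.
#' @param from,to Optional 0-based window (inclusive) to search.
#' @return A one-row tibble: `fwd_wall`, `rev_wall`, `wall_order`
#'   ("canonical" or "inverted"), `interior_gap`, `inclusive_span`,
#'   `both_covered`.
#' @export
wall_geometry <- function(tracks, from = 0L, to = tracks$length - 1L) {
  idx <- seq(from, to) + 1L
  fwd_wall <- from + which.max(tracks$n3e_fwd[idx]) - 1L
  rev_wall <- from + which.max(tracks$n3e_rev[idx]) - 1L
  lo <- min(fwd_wall, rev_wall)
  hi <- max(fwd_wall, rev_wall)
  between <- seq(lo, hi) + 1L
  tibble(
    fwd_wall = fwd_wall,
    rev_wall = rev_wall,
    wall_order = if (rev_wall >= fwd_wall) "canonical" else "inverted",
    interior_gap = hi - lo - 1L,
    inclusive_span = hi - lo + 1L,
    both_covered = sum(tracks$cov_fwd[between] > 0 &
                         tracks$cov_rev[between] > 0)
  )
}
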