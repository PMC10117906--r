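#' Audic-Claverie tail probability for count enrichment
#'
#' One-sided probability of observing at least `x` counts in the treatment
#' library given `y` counts at the same position in a control library, with
#' library totals `n1` (treatment) and `n2` (control):
#' `p = sum_{k >= x} (n1/n2)^k (y+k)! / (y! k! (1 + n1/n2)^{y+k+1})`.
#' The series is the tail of a negative binomial with size `y + 1` and
#' success probability `n2 / (n1 + n2)`, which is how it is evaluated.
#'
#' @param x Treatment count(s) at the position.
#' @param y Control count(s) at the position.
#' @param n1,n2 Library totals (treatment, control).
#' @return Vector of tail probabilities.
#' @examples
#' audic_claverie_pvalue(50, 1, 1e6, 1e6)
#' @export
audic_claverie_pvalue <- function(x, y, n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) abort("Library totals must be > 0.")
  pnbinom(x - 1, size = y + 1, prob = n2 / (n1 + n2), lower.tail = FALSE)
}

#' Call significant strand-specific N3E spikes
#'
#' Per-position one-sided Audic-Claverie comparison of treatment versus
#' control N3E counts on one strand, using total N3E counts (both strands)
#' as library sizes. Positions with `p <= alpha` and treatment height
#' `>= min_height` are returned with their fold enrichment
#' `(x + pseudocount) / (scale * y + pseudocount)`, `scale = n1/n2`.
#'
#' @param treatment,control `signal_tracks` of equal length.
#' @param strand "forward" or "reverse".
#' @param alpha Significance threshold in (0, 1).
#' @param min_height Minimum treatment N3E count at the position.
#' @param pseudocount Pseudocount for the fold-enrichment report.
#' @return A tibble: `position` (0-based), `strand`, `height`, `control`,
#'   `fold`, `p`, sorted by position.
#' @export
call_strand_spikes <- function(treatment, control,
                               strand = c("forward", "reverse"),
                               alpha = 1e-5, min_height = 5,
                               pseudocount = 1) {
  strand <- match.arg(strand)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (treatment$length != control$length) abort("Track lengths differ.")
  field <- if (strand == "forward") "n3e_fwd" else "n3e_rev"
  x <- track_field(treatment, field)
  y <- track_field(control, field)
  n1 <- sum(track_field(treatment, "n3e"))
  n2 <- sum(track_field(control, "n3e"))
  if (n2 == 0) abort("Control track has zero total counts.")
  cand <- which(x >= max(min_height, 1))
  if (length(cand) == 0) {
    return(tibble(position = integer(), strand = character(),
                  height = double(), control = double(), fold = double(),
                  p = double()))
  }
  p <- audic_claverie_pvalue(x[cand], y[cand], n1, n2)
  scale <- n1 / n2
  keep <- p <= alpha
  tibble(
    position = cand[keep] - 1L,
    strand = if (strand == "forward") "+" else "-",
    height = x[cand][keep],
    control = y[cand][keep],
    fold = (x[cand][keep] + pseudocount) /
      (scale * y[cand][keep] + pseudocount),
    p = p[keep]
  )
}

#' Pair strand-specific spikes into cleavage sites
#'
#' A forward spike at `f` and a reverse spike at `r` form a canonical site
#' when `r - f` lies in `[stagger - jitter, stagger + jitter]` (center
#' `f + 1`, the first overhang base) and a composite site when `f - r` lies
#' in that range (center `r`, the reverse wall). Pairing is greedy by
#' descending summed spike height (ties: leftmost center); each spike is
#' used at most once; unpaired spikes are returned in the `"orphans"`
#' attribute.
#'
#' @param fwd,rev Spike tibbles from [call_strand_spikes()].
#' @param stagger Wall offset (overhang + 1).
#' @param jitter Pairing tolerance in bp (0 = strict single-nucleotide
#'   geometry).
#' @return A TCS tibble: `center`, `geometry`, `fwd_wall`, `rev_wall`,
#'   `height_fwd`, `height_rev`, `p_fwd`, `p_rev`, `score` (mean wall fold
#'   enrichment), sorted by center, with unpaired spikes in
#'   `attr(, "orphans")`.
#' @export
pair_spikes <- function(fwd, rev, stagger = 5L, jitter = 0L) {
  if (jitter < 0) abort("`jitter` must be >= 0.")
  empty <- tibble(center = integer(), geometry = character(),
                  fwd_wall = integer(), rev_wall = integer(),
                  height_fwd = double(), height_rev = double(),
                  p_fwd = double(), p_rev = double(), score = double())
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    attr(empty, "orphans") <- bind_rows(fwd, rev)
    return(empty)
  }
  fwd <- arrange(fwd, .data$position)
  rev <- arrange(rev, .data$position)
  # candidate pairs within the jitter window, both orientations
  cand_for <- function(offsets, geometry) {
    purrr::map_dfr(offsets, function(d) {
      idx <- match(fwd$position + d, rev$position)
      ok <- !is.na(idx)
      if (!any(ok)) return(NULL)
      tibble(fi = which(ok), ri = idx[ok], geometry = geometry)
    })
  }
  cands <- bind_rows(
    cand_for(stagger + seq(-jitter, jitter), "canonical"),
    cand_for(-stagger + seq(-jitter, jitter), "composite")
  )
  if (nrow(cands) == 0) {
    attr(empty, "orphans") <- bind_rows(fwd, rev)
    return(empty)
  }
  cands <- cands |>
    mutate(
      f_pos = fwd$position[.data$fi],
      r_pos = rev$position[.data$ri],
      center = ifelse(.data$geometry == "canonical",
                      .data$f_pos + 1L, .data$r_pos),
      hsum = fwd$height[.data$fi] + rev$height[.data$ri]
    ) |>
    arrange(desc(.data$hsum), .data$center)
  used_f <- logical(nrow(fwd))
  used_r <- logical(nrow(rev))
  take <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    fi <- cands$fi[i]; ri <- cands$ri[i]
    if (!used_f[fi] && !used_r[ri]) {
      used_f[fi] <- TRUE
      used_r[ri] <- TRUE
      take[i] <- TRUE
    }
  }
  cands <- cands[take, , drop = FALSE]
  out <- tibble(
    center = as.integer(cands$center),
    geometry = cands$geometry,
    fwd_wall = as.integer(cands$f_pos),
    rev_wall = as.integer(cands$r_pos),
    height_fwd = fwd$height[cands$fi],
    height_rev = rev$height[cands$ri],
    p_fwd = fwd$p[cands$fi],
    p_rev = rev$p[cands$ri],
    score = (fwd$fold[cands$fi] + rev$fold[cands$ri]) / 2
  ) |>
    arrange(.data$center)
  attr(out, "orphans") <- bind_rows(fwd[!used_f, , drop = FALSE],
                                    rev[!used_r, , drop = FALSE])
  out
}

#' Call cleavage sites from treatment and control tracks
#'
#' Convenience wrapper: calls significant N3E spikes on both strands
#' ([call_strand_spikes()]) and pairs them into canonical / composite sites
#' ([pair_spikes()]).
#'
#' @inheritParams call_strand_spikes
#' @inheritParams pair_spikes
#' @return A TCS tibble (see [pair_spikes()]) with calling parameters in
#'   `attr(, "params")` and unpaired spikes in `attr(, "orphans")`.
#' @export
call_tcs <- function(treatment, control, alpha = 1e-5, min_height = 5,
                     stagger = 5L, jitter = 0L, pseudocount = 1) {
  fwd <- call_strand_spikes(treatment, control, "forward", alpha, min_height,
                            pseudocount)
  rev <- call_strand_spikes(treatment, control, "reverse", alpha, min_height,
                            pseudocount)
  out <- pair_spikes(fwd, rev, stagger = stagger, jitter = jitter)
  attr(out, "params") <- list(alpha = alpha, min_height = min_height,
                              stagger = stagger, jitter = jitter,
                              treatment = treatment$sample,
                              control = control$sample)
  out
}

#' Predicted signal geometry after DNA-repair fill-in
#'
#' If repair polymerases extended the free 3' ends across the 4-nt overhang
#' of a trapped cleavage complex, the forward wall would move from `c - 1` to
#' `c + stagger - 2` and the reverse wall from `c + stagger - 1` to `c`:
#' coverage from the two strands would then overlap on `stagger - 1`
#' positions and the two (shifted) cleavage signals would be separated by
#' `stagger - 3` interior positions — 4 bp overlap and 2 bp separation at the
#' default stagger. This transform distinguishes a repair-extended canonical
#' cut from a genuine composite locus, whose overlap is `stagger + 1`.
#'
#' @param stagger Wall offset (>= 3).
#' @return A one-row tibble with `overlap` and `separation` (bp).
#' @examples
#' predict_repair_extension(5)
#' @export
predict_repair_extension <- function(stagger = 5L) {
  if (stagger < 3) abort("`stagger` must be >= 3.")
  tibble(overlap = as.integer(stagger - 1L),
         separation = as.integer(stagger - 3L))
}

#' Label primary and satellite sites
#'
#' Clusters sites whose centers are within `window` bp of a neighbor
#' (transitive closure); within each cluster the highest-score site is
#' primary and the rest are satellites (ties: leftmost center).
#'
#' @param tcs TCS tibble with `center` and `score` columns.
#' @param window Clustering distance in bp (> 0).
#' @return The input with a `rank` column ("primary"/"satellite").
#' @export
classify_primary_satellite <- function(tcs, window = 100L) {
  if (window <= 0) abort("`window` must be > 0.")
  if (nrow(tcs) == 0) return(mutate(tcs, rank = character()))
  tcs <- arrange(tcs, .data$center)
  cluster <- cumsum(c(1L, as.integer(diff(tcs$center) > window)))
  tcs |>
    mutate(.cluster = cluster) |>
    group_by(.data$.cluster) |>
    mutate(rank = ifelse(
      row_number() == order(-.data$score, .data$center)[1],
      "primary", "satellite")) |>
    ungroup() |>
    select(-".cluster")
}

#' Reconcile cleavage sites across replicates
#'
#' Pools the replicate site tables, clusters centers within `tolerance`
#' (transitive closure; `tolerance = 0` keeps exact-coordinate groups), and
#' keeps clusters supported by at least `min_support` distinct replicates.
#' The consensus row for a cluster is the supporting site with the highest
#' score (ties: leftmost center, lowest replicate index); its `support`
#' column records the number of supporting replicates. With
#' `min_support = 1` this is the tolerance-deduplicated union. The result is
#' invariant to the order of the replicate list.
#'
#' @param sets List of TCS tibbles (one per replicate).
#' @param min_support Minimum number of replicates (>= 1).
#' @param tolerance Center matching tolerance in bp.
#' @return A TCS tibble with a `support` column, sorted by center.
#' @export
reconcile_replicates <- function(sets, min_support = 2L, tolerance = 0L) {
  if (min_support < 1) abort("`min_support` must be >= 1.")
  if (length(sets) < min_support) {
    abort("Fewer replicate sets than `min_support`.")
  }
  pooled <- purrr::imap_dfr(sets, function(s, i) {
    mutate(s, .replicate = as.integer(i))
  })
  if (nrow(pooled) == 0) return(mutate(pooled, support = integer()))
  pooled <- arrange(pooled, .data$center)
  cluster <- cumsum(c(1L, as.integer(diff(pooled$center) > tolerance)))
  pooled |>
    mutate(.cluster = cluster) |>
    group_by(.data$.cluster) |>
    mutate(support = dplyr::n_distinct(.data$.replicate)) |>
    filter(.data$support >= min_support) |>
    arrange(desc(.data$score), .data$center, .data$.replicate,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".cluster", -".replicate") |>
    arrange(.data$center)
}

#' Intersect two cleavage-site sets
#'
#' One-to-one greedy matching of centers within `tolerance` (closest pair
#' first; ties: leftmost). Symmetric in its two arguments.
#'
#' @param a,b TCS tibbles (need a `center` column).
#' @param tolerance Matching tolerance in bp (0 = exact coordinates;
#'   cross-method comparisons against region-scale methods typically use
#'   200).
#' @return A one-row tibble: `shared`, `only_a`, `only_b`, `union`
#'   (`= |a| + |b| - shared`).
#' @export
intersect_sets <- function(a, b, tolerance = 0L) {
  if (tolerance < 0) abort("`tolerance` must be >= 0.")
  ca <- sort(a$center)
  cb <- sort(b$center)
  shared <- 0L
  if (length(ca) > 0 && length(cb) > 0) {
    cands <- purrr::map_dfr(seq_along(ca), function(i) {
      lo <- findInterval(ca[i] - tolerance - 1, cb) + 1L
      hi <- findInterval(ca[i] + tolerance, cb)
      if (lo > hi) return(NULL)
      tibble(ai = i, bi = seq(lo, hi),
             dist = abs(ca[i] - cb[seq(lo, hi)]))
    })
    if (nrow(cands) > 0) {
      cands <- arrange(cands, .data$dist, .data$ai, .data$bi)
      used_a <- logical(length(ca))
      used_b <- logical(length(cb))
      for (i in seq_len(nrow(cands))) {
        ai <- cands$ai[i]; bi <- cands$bi[i]
        if (!used_a[ai] && !used_b[bi]) {
          used_a[ai] <- TRUE
          used_b[bi] <- TRUE
          shared <- shared + 1L
        }
      }
    }
  }
  tibble(
    shared = shared,
    only_a = length(ca) - shared,
    only_b = length(cb) - shared,
    union = length(ca) + length(cb) - shared
  )
}

#' @describeIn call_tcs One-row summary of a TCS table: site counts by
#'   geometry and rank.
#' @param x A TCS tibble.
#' @param ... Unused.
#' @export
glance_tcs <- function(x, ...) {
  tibble(
    n_sites = nrow(x),
    n_canonical = sum(x$geometry == "canonical"),
    n_composite = sum(x$geometry == "composite"),
    n_primary = if ("rank" %in% names(x)) sum(x$rank == "primary") else NA_integer_,
    n_orphans = if (!is.null(attr(x, "orphans"))) nrow(attr(x, "orphans")) else NA_integer_,
    mean_score = mean(x$score)
  )
}
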