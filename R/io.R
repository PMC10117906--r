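#' Write / read fragment tables as TSV
#'
#' Six columns: `sample`, `chrom`, `start`, `end` (0-based half-open),
#' `strand`, `count`. Round-trips exactly.
#'
#' @param fragments Fragment tibble.
#' @param path File path.
#' @return The path (write) or a fragment tibble (read).
#' @export
write_fragments_tsv <- function(fragments, path) {
  readr::write_tsv(
    select(fragments, "sample", "chrom", "start", "end", "strand", "count"),
    path)
  invisible(path)
}

#' @rdname write_fragments_tsv
#' @export
read_fragments_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    strand = readr::col_character(),
    count = readr::col_integer()
  ))
}

#' Write / read fragments as minimal SAM
#'
#' A deliberately small SAM subset: `@HD`/`@SQ` header, FLAG 0 (forward) or
#' 16 (reverse), 1-based POS, CIGAR `<len>M`, no sequence or qualities.
#' Origin-wrapping fragments cannot be represented and are dropped with a
#' warning on write. Malformed records are reported with their line number
#' on read.
#'
#' @param fragments Fragment tibble.
#' @param genome A `synthetic_genome` (for the `@SQ` line).
#' @param path File path.
#' @export
write_fragments_sam <- function(fragments, genome, path) {
  wrap <- fragments$end > genome$length
  if (any(wrap)) {
    warn(sprintf("Dropping %d origin-wrapping fragment(s) not representable in SAM.",
                 sum(wrap)))
    fragments <- fragments[!wrap, , drop = FALSE]
  }
  n <- nrow(fragments)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$name, genome$length))
  recs <- if (n > 0) {
    sprintf("frag%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
            seq_len(n),
            ifelse(fragments$strand == "-", 16L, 0L),
            fragments$chrom,
            fragments$start + 1L,
            fragments$end - fragments$start)
  } else character()
  writeLines(c(header, recs), path)
  invisible(path)
}

#' @rdname write_fragments_sam
#' @param sample Sample label to attach to the fragments read.
#' @export
read_fragments_sam <- function(path, sample = NA_character_) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  recs <- purrr::map_dfr(body, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) {
      abort(sprintf("Malformed SAM record at line %d: fewer than 6 fields.", i))
    }
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    m <- regmatches(f[6], regexec("^([0-9]+)M$", f[6]))[[1]]
    if (is.na(flag) || is.na(pos) || length(m) < 2) {
      abort(sprintf("Malformed SAM record at line %d: FLAG/POS/CIGAR.", i))
    }
    len <- as.integer(m[2])
    tibble(
      chrom = f[3],
      start = pos - 1L,
      end = pos - 1L + len,
      strand = if (bitwAnd(flag, 16L) > 0) "-" else "+"
    )
  })
  mutate(recs, sample = sample, count = 1L) |>
    select("sample", "chrom", "start", "end", "strand", "count")
}

track_granges <- function(values, chrom, drop_zero = TRUE) {
  r <- rle(as.numeric(values))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- if (drop_zero) r$values != 0 else rep(TRUE, length(r$values))
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
    score = r$values[keep]
  )
}

#' Write / read a per-position track as bedGraph
#'
#' bedGraph is 0-based half-open; runs of equal value are collapsed and
#' zero runs omitted. Reading restores the dense per-position vector.
#'
#' @param values Numeric per-position vector (position 0 first).
#' @param chrom Chromosome name.
#' @param path File path.
#' @param length Genome length (read).
#' @export
write_track_bedgraph <- function(values, chrom, path) {
  rtracklayer::export(track_granges(values, chrom), path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_track_bedgraph
#' @export
read_track_bedgraph <- function(path, length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- numeric(length)
  for (i in seq_along(gr)) {
    values[IRanges::start(gr)[i]:IRanges::end(gr)[i]] <- gr$score[i]
  }
  values
}

#' Write a per-position track as fixedStep WIG (1-based)
#'
#' @inheritParams write_track_bedgraph
#' @export
write_track_wig <- function(values, chrom, path) {
  writeLines(c(
    sprintf("fixedStep chrom=%s start=1 step=1", chrom),
    format(as.numeric(values), trim = TRUE, scientific = FALSE)
  ), path)
  invisible(path)
}

#' @rdname write_track_wig
#' @export
read_track_wig <- function(path) {
  lines <- readLines(path)
  as.numeric(lines[!grepl("^(fixedStep|variableStep|track)", lines)])
}

#' Write / read a TCS table as BED6
#'
#' Each site becomes the 0-based half-open overhang interval
#' `[center, center + overhang)`, name `geometry`, score = mean wall fold
#' enrichment linearly scaled to 0-1000 across the table, strand ".".
#'
#' @param tcs TCS tibble.
#' @param chrom Chromosome name.
#' @param path File path.
#' @param overhang Overhang width in bp.
#' @export
write_tcs_bed <- function(tcs, chrom, path, overhang = 4L) {
  score <- if (nrow(tcs) > 0 && max(tcs$score) > 0) {
    round(tcs$score / max(tcs$score) * 1000)
  } else {
    rep(0, nrow(tcs))
  }
  bed <- tibble(
    chrom = rep(chrom, nrow(tcs)),
    start = tcs$center,
    end = tcs$center + overhang,
    name = tcs$geometry,
    score = score,
    strand = rep(".", nrow(tcs))
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_tcs_bed
#' @export
read_tcs_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    center = IRanges::start(gr) - 1L,
    geometry = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_
  )
}

#' Write / read a full TCS table as TSV
#'
#' @param tcs TCS tibble.
#' @param path File path.
#' @export
write_tcs_tsv <- function(tcs, path) {
  readr::write_tsv(tcs, path)
  invisible(path)
}

#' @rdname write_tcs_tsv
#' @export
read_tcs_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a transcription-unit annotation TSV
#'
#' Five columns: `name`, `start`, `end` (0-based half-open), `strand`
#' ("+"/"-"), `expression` (arbitrary units >= 0).
#'
#' @param path File path.
#' @return A TU tibble.
#' @export
read_tu_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    strand = readr::col_character(),
    expression = readr::col_double()
  ))
}

#' @rdname read_tu_tsv
#' @param tus TU tibble.
#' @export
write_tu_tsv <- function(tus, path) {
  readr::write_tsv(select(tus, "name", "start", "end", "strand", "expression"),
                   path)
  invisible(path)
}

#' Read a BED file of genomic regions
#'
#' @param path BED path (0-based half-open intervals).
#' @return A tibble: `name`, `start`, `end`.
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    name = if (!is.null(gr$name)) gr$name else paste0("region", seq_along(gr)),
    start = IRanges::start(gr) - 1L,
    end = IRanges::end(gr)
  )
}
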