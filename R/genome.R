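#' Generate a random synthetic genome
#'
#' Draws an i.i.d. nucleotide sequence with a specified GC content, as a
#' stand-in bacterial chromosome for simulations. Bases are sampled
#' independently with `P(G) + P(C) = gc` (split equally between G and C, and
#' between A and T).
#'
#' @param length Genome length in bp (positive integer).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param circular Should the genome be treated as circular? Circular genomes
#'   allow fragments and windows to wrap the origin.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param name Sequence name used in FASTA/SAM/BED output.
#'
#' @return A `synthetic_genome` object: a list with elements `name`,
#'   `sequence` (single character string over A/C/G/T), `length`, `circular`
#'   and `gc_content` (observed fraction).
#' @examples
#' g <- generate_genome(1e4, gc = 0.5, seed = 1)
#' g$gc_content
#' @export
generate_genome <- function(length, gc = 0.5, circular = TRUE, seed = 1L,
                            name = "chr_synth") {
  if (!is.numeric(length) || length(length) != 1 || is.na(length) || length < 1) {
    abort("`length` must be a single positive number of base pairs.")
  }
  if (!is.numeric(gc) || gc < 0 || gc > 1) {
    abort("`gc` must lie in [0, 1].")
  }
  length <- as.integer(length)
  bases <- withr::with_seed(seed, {
    sample(c("A", "C", "G", "T"), size = length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  new_genome(name, paste(bases, collapse = ""), circular = circular)
}

new_genome <- function(name, sequence, circular = TRUE) {
  if (nchar(sequence) == 0L) abort("Genome sequence is empty.")
  if (grepl("[^ACGT]", sequence)) {
    abort("Genome sequence may contain only A/C/G/T.")
  }
  structure(
    list(
      name = name,
      sequence = sequence,
      length = nchar(sequence),
      circular = circular,
      gc_content = genome_gc(sequence)
    ),
    class = "synthetic_genome"
  )
}

genome_gc <- function(sequence) {
  dna <- Biostrings::DNAString(sequence)
  unname(Biostrings::letterFrequency(dna, "GC", as.prob = TRUE)[1])
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %s: %s bp, %s, GC %.3f\n",
              x$name, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", x$gc_content))
  invisible(x)
}

#' Extract a genome window
#'
#' Returns the top-strand sequence of the half-open interval
#' `[start, start + width)` in 0-based coordinates, wrapping the origin on
#' circular genomes.
#'
#' @param genome A `synthetic_genome`.
#' @param start 0-based start coordinate.
#' @param width Window width in bp.
#' @return A character string of `width` bases.
#' @export
genome_window <- function(genome, start, width) {
  L <- genome$length
  if (width < 1) abort("`width` must be >= 1.")
  start <- start %% L
  end <- start + width
  if (end <= L) {
    return(substr(genome$sequence, start + 1L, end))
  }
  if (!genome$circular) {
    abort("Window runs off the end of a linear genome.")
  }
  paste0(
    substr(genome$sequence, start + 1L, L),
    substr(genome$sequence, 1L, end - L)
  )
}

replace_genome_window <- function(genome, start, replacement) {
  L <- genome$length
  w <- nchar(replacement)
  start <- start %% L
  seq <- genome$sequence
  if (start + w <= L) {
    substr(seq, start + 1L, start + w) <- replacement
  } else {
    if (!genome$circular) abort("Window runs off the end of a linear genome.")
    k <- L - start
    substr(seq, start + 1L, L) <- substr(replacement, 1L, k)
    substr(seq, 1L, w - k) <- substr(replacement, k + 1L, w)
  }
  new_genome(genome$name, seq, genome$circular)
}

#' Write / read a genome as FASTA
#'
#' @param genome A `synthetic_genome`.
#' @param path Output FASTA path.
#' @return `write_genome_fasta()` returns `path` invisibly;
#'   `read_genome_fasta()` returns a `synthetic_genome`.
#' @param circular Circularity flag to attach on read (FASTA does not carry it).
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$name))
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 1) abort("No sequences in FASTA file.")
  name <- sub("\\s.*$", "", names(set)[1])
  new_genome(name, as.character(set[[1]]), circular = circular)
}
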