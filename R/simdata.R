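# Synthetic templates and read sets: pseudo-random sampling of a template
# and its reverse complement (error-free by default), plus a deterministic
# tiling generator used for reconstruction tests.

#' Random template genome
#'
#' Uniform i.i.d. bases; deterministic per seed. The caller's RNG state is
#' left untouched (the seed is applied locally).
#'
#' @param length template length in bases (>= 1).
#' @param seed integer RNG seed (Mersenne-Twister via [set.seed()]).
#' @return a single sequence string.
#' @export
random_genome <- function(length, seed = NULL) {
  if (length < 1) stop("template length must be >= 1")
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""))
}

#' Simulate reads by random sampling of a template and its reverse complement
#'
#' Draws `ceiling(coverage * |template| / mean(read_length))` reads at
#' uniform random start positions, each from the forward or reverse strand
#' with equal probability. Reads are error-free unless `error_rate > 0`, in
#' which case each base is substituted (uniformly among the three other
#' bases) independently with that probability.
#'
#' @param template template sequence (string).
#' @param coverage fold coverage (> 0).
#' @param read_length read length in bases; a scalar for constant length or
#'   `c(min, max)` for uniform variable lengths.
#' @param seed integer RNG seed; the caller's RNG state is preserved.
#' @param error_rate per-base substitution probability (default 0).
#' @param n_reads optional explicit read count (overrides `coverage`).
#' @return character vector of reads.
#' @export
simulate_reads <- function(template, coverage = 20, read_length = 100L,
                           seed = NULL, error_rate = 0, n_reads = NULL) {
  tl <- nchar(template)
  if (length(read_length) == 1L) read_length <- c(read_length, read_length)
  if (max(read_length) > tl) stop("read_length must not exceed the template length")
  if (is.null(n_reads) && coverage <= 0) stop("coverage must be > 0")
  count <- as.integer(n_reads %||% ceiling(coverage * tl / mean(read_length)))
  with_seed(seed, {
    lens <- if (read_length[1] == read_length[2]) rep(read_length[1], count)
    else read_length[1] + floor(runif(count) * (read_length[2] - read_length[1] + 1))
    starts <- 1L + floor(runif(count) * (tl - lens + 1))
    reads <- substring(template, starts, starts + lens - 1L)
    rev <- runif(count) < 0.5
    reads[rev] <- revcomp_dna(reads[rev])
    if (error_rate > 0) {
      for (i in seq_len(count)) {
        nmut <- rbinom(1L, lens[i], error_rate)
        if (nmut > 0) {
          pos <- sample.int(lens[i], nmut)
          chars <- strsplit(reads[i], "")[[1]]
          for (p in pos)
            chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
          reads[i] <- paste(chars, collapse = "")
        }
      }
    }
    reads
  })
}

#' Tile a template with overlapping reads
#'
#' Deterministic reads at offsets `0, step, 2*step, ...` plus one
#' flush-right read, guaranteeing consecutive overlaps of at least
#' `read_length - step` bases.
#'
#' @param template template sequence.
#' @param read_length read length in bases.
#' @param step offset step; must satisfy `step <= read_length - l_min` so
#'   that consecutive reads overlap by at least `l_min`.
#' @param l_min the minimum overlap length the tiling must guarantee.
#' @return character vector of forward-strand reads.
#' @export
tile_reads <- function(template, read_length, step, l_min = 45L) {
  tl <- nchar(template)
  if (read_length > tl) stop("read_length must not exceed the template length")
  if (step > read_length - l_min)
    stop("step too large: consecutive overlaps would drop below l_min = ", l_min)
  if (step < 1) stop("step must be >= 1")
  offsets <- unique(c(seq(0L, tl - read_length, by = step), tl - read_length))
  substring(template, offsets + 1L, offsets + read_length)
}

#' Write reads to a FASTA file
#'
#' @param reads character vector of sequences.
#' @param path output path.
#' @param prefix header prefix (`>prefix_<i>`).
#' @export
write_reads_fasta <- function(reads, path, prefix = "read") {
  if (length(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("%s_%d", prefix, seq_along(reads))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
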