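# Integer k-mer codes and the prefix/suffix code filters.
#
# A k-mer over {A,C,G,T} is encoded as the base-4 integer with digit map
# A -> 0, C -> 1, G -> 2, T -> 3 (most significant digit first), so the code
# order agrees with the lexicographic order of equal-length strings. The
# code of the k'-prefix is an integer division by 4^(k-k') (a right shift);
# the code of the k-mer's k''-suffix is the remainder modulo 4^k'' (a mask).

#' Parameter set for k-mer based overlap indexing
#'
#' Computes and validates the mer sizes used by the overlap stage. Defaults
#' follow the package's standard configuration: `k = min(l_min, 32)` (one
#' machine word holds a k-mer), `k_prime = ceil(log2(n)) - 8` clamped to
#' `[8, k]` (the prefix-filter mer), and `k_dbl_prime = k_prime - 1` with a
#' floor of 1 (the suffix-filter mer). The chain
#' `k'' <= k' <= k <= min(l_min, 32)` is enforced.
#'
#' @param l_min minimum overlap length (bases).
#' @param n total length of all (forward) reads in bases; used for the
#'   `k_prime` default.
#' @param k,k_prime,k_dbl_prime optional explicit mer sizes.
#' @return list of class `kmer_config` with elements `k`, `k_prime`,
#'   `k_dbl_prime`, `l_min`, `max_k` (32).
#' @export
kmer_config <- function(l_min, n = NULL, k = NULL, k_prime = NULL,
                        k_dbl_prime = NULL) {
  max_k <- 32L
  l_min <- as.integer(l_min)
  if (l_min < 1) stop("l_min must be >= 1")
  k <- as.integer(k %||% min(l_min, max_k))
  if (k > min(l_min, max_k) || k < 1) stop("k must satisfy 1 <= k <= min(l_min, 32)")
  if (is.null(k_prime)) {
    if (is.null(n)) stop("either n or k_prime must be given")
    k_prime <- min(k, max(8L, as.integer(ceiling(log2(max(n, 2))) - 8)))
  }
  k_prime <- as.integer(k_prime)
  k_dbl_prime <- as.integer(k_dbl_prime %||% max(1L, k_prime - 1L))
  if (k_prime < 1 || k_prime > k) stop("k_prime must satisfy 1 <= k' <= k")
  if (k_dbl_prime < 1 || k_dbl_prime > k_prime)
    stop("k_dbl_prime must satisfy 1 <= k'' <= k'")
  structure(list(k = k, k_prime = k_prime, k_dbl_prime = k_dbl_prime,
                 l_min = l_min, max_k = max_k),
            class = "kmer_config")
}

#' @export
print.kmer_config <- function(x, ...) {
  cat(sprintf("kmer_config: k = %d, k' = %d, k'' = %d (l_min = %d)\n",
              x$k, x$k_prime, x$k_dbl_prime, x$l_min))
  invisible(x)
}

phi_base <- c(A = 0, C = 1, G = 2, T = 3)

#' Integer code of the initial k-mer of a string
#'
#' `kmer_code(s, k)` returns `sum(4^(k-i) * phi(s[i]))` over the first `k`
#' symbols, with `phi = [A -> 0, C -> 1, G -> 2, T -> 3]`. Codes are
#' returned as doubles; `k <= 26` is required so that every code is an exact
#' integer in double range (the compiled pipeline itself uses 64-bit codes
#' and supports `k` up to 32).
#'
#' @param s character vector of strings over A, C, G, T, each of length at
#'   least `k`.
#' @param k mer size (1..26 at the R level).
#' @return numeric vector of codes in `[0, 4^k - 1]`.
#' @export
#' @examples
#' kmer_code("ACGT", 4)   # 27
kmer_code <- function(s, k = min(nchar(s))) {
  if (k < 1 || k > 26) stop("k must be in 1..26 for exact double codes")
  if (any(nchar(s) < k)) stop("window exceeds read end: nchar(s) < k")
  vapply(s, function(x) {
    d <- phi_base[strsplit(substr(x, 1, k), "")[[1]]]
    if (anyNA(d)) stop("non-ACGT symbol in k-mer")
    sum(d * 4^(k - seq_len(k)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Derive the code of the k'-prefix from a k-mer code
#'
#' Integer division by `4^(k - k_prime)` (a right shift in the compiled
#' code): `kmer_prefix_code(kmer_code(s, k), k, kp) == kmer_code(s, kp)`.
#'
#' @param code numeric vector of k-mer codes.
#' @param k mer size of `code`.
#' @param k_prime prefix mer size, `k_prime <= k`.
#' @return numeric vector of k'-mer codes.
#' @export
kmer_prefix_code <- function(code, k, k_prime) {
  stopifnot(k_prime >= 1, k_prime <= k)
  floor(code / 4^(k - k_prime))
}

#' Derive the code of the k-mer's k''-suffix from a k-mer code
#'
#' Remainder modulo `4^k_dbl_prime` (a bitwise mask in the compiled code):
#' the code of `s[k - k'' + 1 .. k]`.
#'
#' @inheritParams kmer_prefix_code
#' @param k_dbl_prime suffix mer size, `k_dbl_prime <= k`.
#' @return numeric vector of k''-mer codes.
#' @export
kmer_suffix_code <- function(code, k, k_dbl_prime) {
  stopifnot(k_dbl_prime >= 1, k_dbl_prime <= k)
  code %% 4^k_dbl_prime
}

#' Codes of all k-mer windows of a sequence
#'
#' Sweeps a window of width `k` over the sequence; each code is obtained
#' from the previous one in constant time (drop the high digit, shift, add
#' the new base).
#'
#' @param x a single sequence (character scalar) or an `encoded_reads`
#'   object.
#' @param k mer size (1..26 at the R level).
#' @param strand strand index, required when `x` is an `encoded_reads`.
#' @return data.frame with columns `pos` (1-based window start) and `code`.
#' @export
sliding_codes <- function(x, k, strand = NULL) {
  if (inherits(x, "encoded_reads")) {
    if (is.null(strand)) stop("strand index required for encoded_reads input")
    x <- strand_seq(x, strand)
  }
  if (k < 1 || k > 26) stop("k must be in 1..26 for exact double codes")
  n <- nchar(x)
  if (n < k) stop("read shorter than k")
  d <- unname(phi_base[strsplit(x, "")[[1]]])
  if (anyNA(d)) stop("non-ACGT symbol")
  codes <- numeric(n - k + 1)
  c0 <- sum(d[seq_len(k)] * 4^(k - seq_len(k)))
  codes[1] <- c0
  if (n > k) {
    for (q in 2:(n - k + 1)) {
      c0 <- (c0 %% 4^(k - 1)) * 4 + d[q + k - 1]
      codes[q] <- c0
    }
  }
  data.frame(pos = seq_len(n - k + 1), code = codes)
}

#' Build the P and Q membership filters
#'
#' `P` is the set of codes of the k'-prefixes of all initial k-mers, `Q` the
#' set of codes of their k''-suffixes. A proper suffix whose k'-prefix code
#' is not in `P` (or whose k''-code is not in `Q`) cannot match any read's
#' initial k-mer and is discarded before the counting/insertion phases.
#'
#' @param initial_codes sorted numeric vector of initial k-mer codes of all
#'   strands (see [collect_initial_kmers()]).
#' @param cfg a [kmer_config()].
#' @return list with sorted distinct code vectors `P` and `Q` and their mer
#'   sizes.
#' @export
build_filters <- function(initial_codes, cfg) {
  stopifnot(inherits(cfg, "kmer_config"))
  list(P = sort(unique(kmer_prefix_code(initial_codes, cfg$k, cfg$k_prime))),
       Q = sort(unique(kmer_suffix_code(initial_codes, cfg$k, cfg$k_dbl_prime))),
       k_prime = cfg$k_prime, k_dbl_prime = cfg$k_dbl_prime)
}
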