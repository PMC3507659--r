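# SPM-relevant suffix indexing: counting phase, partial sums, partitioned
# insertion phase, per-bucket sorting with lcp tables. Thin wrappers over
# the compiled core; the fused pipeline in spm_overlap() uses the same C++
# routines.

default_buffer <- function(E) {
  # gamma = 4 applied to the 2m upper bound on d (the number of distinct
  # initial k-mers is unknown before the dedup scan)
  max(1024L, as.integer(floor(2 * E$m / 4)))
}

#' Initial k-mer codes of all strands
#'
#' Collects the code of the initial k-mer of every strand (forward reads and
#' reverse complements) and sorts them; duplicates are preserved at this
#' stage.
#'
#' @param E an `encoded_reads` object whose reads all have length >= `k`.
#' @param cfg a [kmer_config()].
#' @param forward_only restrict to forward strands (testing aid).
#' @return sorted numeric vector of 2m (or m) codes.
#' @export
collect_initial_kmers <- function(E, cfg, forward_only = FALSE) {
  stopifnot(inherits(E, "encoded_reads"), inherits(cfg, "kmer_config"))
  .cpp_collect_initial_kmers(E$seq, cfg$k, !forward_only)
}

#' Deduplicate sorted initial k-mer codes, with counts and filters
#'
#' One linear scan of the sorted codes removes duplicates (yielding the key
#' table `K`), counts the multiplicity of each key (`C_init`), and builds
#' the `P` and `Q` filters from the derived prefix/suffix codes.
#'
#' @param sorted_codes sorted numeric vector of initial k-mer codes (from
#'   [collect_initial_kmers()]).
#' @param cfg a [kmer_config()].
#' @return list with `K` (strictly increasing key codes), `C_init`
#'   (multiplicities), `P`, `Q` (sorted distinct filter codes), `d`
#'   (number of keys).
#' @export
dedup_and_count <- function(sorted_codes, cfg) {
  stopifnot(inherits(cfg, "kmer_config"))
  if (is.unsorted(sorted_codes)) stop("codes must be sorted")
  if (length(sorted_codes) == 0)
    return(list(K = numeric(0), C_init = numeric(0), P = numeric(0),
                Q = numeric(0), d = 0L))
  r <- rle(sorted_codes)
  f <- build_filters(r$values, cfg)
  list(K = r$values, C_init = as.numeric(r$lengths), P = f$P, Q = f$Q,
       d = length(r$values))
}

#' Enumerate candidate proper suffixes
#'
#' Yields every proper suffix of every strand with start offset `q` in
#' `1..|r| - l_min` (0-based, hence of length at least `l_min`) that passes
#' the P- and Q-filters, together with its initial k-mer code, optionally
#' restricted to a code range (a partition part).
#'
#' @inheritParams collect_initial_kmers
#' @param code_range optional numeric `c(lo, hi)` of initial k-mer codes.
#' @return data.frame with columns `strand`, `offset` (0-based), `code`.
#' @export
enumerate_candidate_suffixes <- function(E, cfg, forward_only = FALSE,
                                         code_range = NULL) {
  stopifnot(inherits(E, "encoded_reads"), inherits(cfg, "kmer_config"))
  lo <- if (is.null(code_range)) -1 else code_range[1]
  hi <- if (is.null(code_range)) -1 else code_range[2]
  res <- .cpp_enumerate_candidates(E$seq, cfg$l_min, cfg$k, cfg$k_prime,
                                   cfg$k_dbl_prime, !forward_only, lo, hi)
  data.frame(strand = res$strand, offset = res$offset, code = res$code)
}

#' Counting phase over buffered candidate batches
#'
#' Counts, for every key in `K`, the number of SPM-relevant suffixes whose
#' initial k-mer equals that key: the key's own whole reads plus all
#' matching candidate suffixes. Candidates passing the P/Q filters are
#' buffered; each full buffer is sorted and merged against `K` in one
#' binary search plus simultaneous linear scan (candidates absent from `K`
#' are dropped). Results are independent of the buffer capacity.
#'
#' @inheritParams collect_initial_kmers
#' @param buffer_size buffer capacity `b` (default `max(1024, 2m/4)`).
#' @return list with `K`, final counts `C`, and `g = sum(C)` (the number of
#'   SPM-relevant suffixes).
#' @export
counting_phase <- function(E, cfg, buffer_size = NULL, forward_only = FALSE) {
  stopifnot(inherits(E, "encoded_reads"), inherits(cfg, "kmer_config"))
  .cpp_counting_phase(E$seq, cfg$l_min, cfg$k, cfg$k_prime, cfg$k_dbl_prime,
                      !forward_only, as.integer(buffer_size %||% default_buffer(E)))
}

#' Partial sums of the count table
#'
#' Computes `pi[0] = C[0]`, `pi[i] = pi[i-1] + C[i]` for `1 <= i <= d-1`,
#' and `pi[d] = pi[d-1]`; `pi[d]` is the total number `g` of SPM-relevant
#' suffixes. Bucket `i` (1-based key index) occupies `S[pi[i-1] .. pi[i]-1]`
#' in 0-based table coordinates, with `pi[0-1] := 0` for the first bucket.
#'
#' @param C numeric count vector of length `d`.
#' @return list with `pi` (length `d + 1`) and `g`.
#' @export
compute_partial_sums <- function(C) {
  pi <- .cpp_partial_sums(as.numeric(C))
  list(pi = pi, g = if (length(pi)) pi[length(pi)] else 0)
}

#' Plan contiguous partition parts
#'
#' Divides the key range into `parts` contiguous bucket ranges of roughly
#' equal total suffix count (greedy accumulation), or — given `mem_limit`
#' in bytes — into the minimal number of parts whose largest part fits a
#' simplified size model (16 bytes per suffix entry + 8 bytes per bucket).
#' The final sorted suffix table, the SPMs and the contigs are identical for
#' every partition count.
#'
#' @param C numeric bucket-size vector (final counts from
#'   [counting_phase()]).
#' @param parts desired part count `q >= 1`.
#' @param mem_limit optional memory limit in bytes (overrides `parts`).
#' @return integer matrix with columns `lo`, `hi`: 1-based bucket index
#'   ranges tiling `1..d`.
#' @export
plan_partitions <- function(C, parts = 1L, mem_limit = NULL) {
  .cpp_plan_partitions(as.numeric(C), as.integer(parts),
                       as.numeric(mem_limit %||% -1))
}

#' Insertion phase: bucket-partitioned suffix table
#'
#' Fills the suffix table `S` with (strand, offset) pairs using the
#' decrementing-cursor counting-sort insertion: whole reads (offset 0) are
#' inserted unconditionally, proper candidates are buffered, sorted, and
#' validated against `K` during the merge. With `parts > 1` each part is
#' processed independently over its code range; the concatenated result is
#' identical to the single-part run up to within-bucket order (which is
#' unspecified at this stage).
#'
#' @inheritParams counting_phase
#' @param parts,mem_limit partitioning controls (see [plan_partitions()]).
#' @return data.frame with columns `strand`, `offset` (0-based), `bucket`
#'   (1-based key index), grouped by bucket in key order.
#' @export
insertion_phase <- function(E, cfg, parts = 1L, mem_limit = NULL,
                            buffer_size = NULL, forward_only = FALSE) {
  stopifnot(inherits(E, "encoded_reads"), inherits(cfg, "kmer_config"))
  res <- .cpp_insertion_phase(E$seq, cfg$l_min, cfg$k, cfg$k_prime,
                              cfg$k_dbl_prime, !forward_only,
                              as.integer(buffer_size %||% default_buffer(E)),
                              as.integer(parts), as.numeric(mem_limit %||% -1))
  data.frame(strand = res$strand, offset = res$offset, bucket = res$bucket)
}

#' Sort one bucket of SPM-relevant suffixes
#'
#' Full lexicographic sort of the bucket's suffixes under the
#' virtual-sentinel order (equal suffix strings from different strands are
#' ordered by strand index). Only the parts beyond the shared initial k-mer
#' need comparing; the lcp table `L` (`L[j] >= k` within a bucket) is
#' computed alongside.
#'
#' @inheritParams collect_initial_kmers
#' @param strand,offset parallel vectors describing the bucket entries (all
#'   sharing one initial k-mer).
#' @param k the initial-mer size.
#' @return list with `order` (permutation of the input entries), `L` (lcp
#'   table of the sorted bucket, length `beta - 1`).
#' @export
sort_bucket <- function(E, strand, offset, k, forward_only = FALSE) {
  stopifnot(inherits(E, "encoded_reads"))
  .cpp_sort_bucket(E$seq, !forward_only, as.integer(strand),
                   as.integer(offset), as.integer(k))
}
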