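# Suffix-prefix match enumeration: Algorithm-2 style traversal over all
# buckets, redundancy filtering, transitivity classification via
# left-context dictionaries, containment detection, SPM file I/O.

#' Enumerate suffix-prefix matches
#'
#' Runs the full overlap stage on a suffix- and prefix-free read set: the
#' counting and (optionally partitioned) insertion phases build the bucketed
#' table of SPM-relevant suffixes; each bucket is sorted and its
#' lcp-interval tree traversed bottom-up, collecting whole-read leaves and
#' terminal edges and emitting the SPMs of each completed interval of
#' lcp-value at least `l_min` as cartesian products. A first pass flags
#' internally contained reads, whose entries are removed before SPM
#' enumeration. Each SPM is classified as irreducible or transitive by a
#' suffix search among the stored left contexts of the irreducible SPMs
#' already found on the same whole-read path; only non-redundant SPMs
#' (conditions on the strand combination, see [is_nonredundant()]) are
#' reported, and self-overlaps of a read with itself or its own reverse
#' complement are excluded.
#'
#' @param E an `encoded_reads` object, prefiltered (see [prefilter()]).
#' @param l_min minimum SPM length (default: `E$l_min`).
#' @param cfg optional [kmer_config()]; computed from `l_min` and `E$n` by
#'   default.
#' @param parts,mem_limit partitioning controls (see [plan_partitions()]);
#'   results are identical for every setting.
#' @param buffer_size counting/insertion buffer capacity.
#' @param forward_only consider forward strands only (for worked examples
#'   and tests).
#' @param with_stats collect per-bucket traversal callback counts in
#'   `attr(, "stats")`.
#' @return data.frame with one row per non-redundant SPM: `src`, `dst`
#'   (read ids as in `E$read_id`), `src_strand`, `dst_strand` (`"+"`/`"-"`),
#'   `length`, `status` (`"irreducible"`/`"transitive"`). Attributes:
#'   `contained` (named logical over `E$read_id`: internally contained
#'   reads), `m`, `stats`.
#' @export
spm_overlap <- function(E, l_min = NULL, cfg = NULL, parts = 1L,
                        mem_limit = NULL, buffer_size = NULL,
                        forward_only = FALSE, with_stats = FALSE) {
  stopifnot(inherits(E, "encoded_reads"))
  l_min <- as.integer(l_min %||% E$l_min)
  empty <- data.frame(src = integer(0), dst = integer(0),
                      src_strand = character(0), dst_strand = character(0),
                      length = integer(0), status = character(0))
  if (E$m == 0 || max(E$lengths, 0) < l_min) {
    attr(empty, "contained") <- stats::setNames(logical(E$m), E$read_id)
    attr(empty, "m") <- E$m
    return(empty)
  }
  if (any(E$lengths < l_min))
    stop("reads shorter than l_min present; re-encode with encode_reads(reads, l_min)")
  cfg <- cfg %||% kmer_config(l_min, n = E$n)
  if (cfg$l_min != l_min) stop("cfg$l_min does not match l_min")
  res <- .cpp_overlap(E$seq, l_min, cfg$k, cfg$k_prime, cfg$k_dbl_prime,
                      !forward_only,
                      as.integer(buffer_size %||% default_buffer(E)),
                      as.integer(parts), as.numeric(mem_limit %||% -1),
                      isTRUE(with_stats))
  m <- E$m
  src_read <- ifelse(res$src > m, res$src - m, res$src)
  dst_read <- ifelse(res$dst > m, res$dst - m, res$dst)
  out <- data.frame(
    src = E$read_id[src_read],
    dst = E$read_id[dst_read],
    src_strand = ifelse(res$src > m, "-", "+"),
    dst_strand = ifelse(res$dst > m, "-", "+"),
    length = res$length,
    status = ifelse(res$irreducible == 1L, "irreducible", "transitive")
  )
  attr(out, "contained") <- stats::setNames(as.logical(res$contained), E$read_id)
  attr(out, "m") <- m
  attr(out, "stats") <- res$stats
  out
}

#' Non-redundancy conditions for an SPM over strand indices
#'
#' Over the strand space of reads plus reverse complements every SPM appears
#' together with its mirror (the SPM of the two opposite strands in reversed
#' roles). Exactly one of the pair is non-redundant: both strands forward;
#' or source forward, destination reverse and the source read precedes the
#' destination read in input order; or source reverse, destination forward
#' and the destination read precedes the source read.
#'
#' @param src,dst strand indices in `1..2m`.
#' @param m number of forward reads.
#' @return logical vector.
#' @export
is_nonredundant <- function(src, dst, m) {
  sf <- src <= m
  df <- dst <= m
  (sf & df) |
    (sf & !df & src < dst - m) |
    (!sf & df & dst < src - m)
}

#' Left-context dictionary
#'
#' A dictionary of strings supporting `lcsearch(D, s)`: returns `TRUE` if
#' some previously added string is a suffix of `s`; otherwise adds `s` and
#' returns `FALSE`. Used to recognize transitive SPMs: an SPM is transitive
#' exactly if the left context of an irreducible SPM already found on the
#' same whole-read path is a suffix of its own left context.
#'
#' @return an empty dictionary (environment-based).
#' @export
lc_dict <- function() {
  d <- new.env(parent = emptyenv())
  d$strings <- character(0)
  class(d) <- "lc_dict"
  d
}

#' @rdname lc_dict
#' @param D a dictionary created by `lc_dict()`.
#' @param s a non-empty string.
#' @export
lcsearch <- function(D, s) {
  stopifnot(inherits(D, "lc_dict"), nzchar(s))
  if (any(endsWith(s, D$strings))) return(TRUE)
  D$strings <- c(D$strings, s)
  FALSE
}

#' Detect internally contained reads
#'
#' A read is internally contained if it occurs in another read (or in a
#' read's reverse complement) with non-empty flanks on both sides. In the
#' bucketed suffix index this is visible as the read's whole-read leaf being
#' attached to an lcp-interval whose lcp-value equals the read length (some
#' other SPM-relevant suffix has the read as a proper prefix); flags from
#' either strand map to the forward read.
#'
#' @inheritParams spm_overlap
#' @return named logical vector over `E$read_id`.
#' @export
detect_internally_contained <- function(E, l_min = NULL, cfg = NULL,
                                        buffer_size = NULL,
                                        forward_only = FALSE) {
  stopifnot(inherits(E, "encoded_reads"))
  l_min <- as.integer(l_min %||% E$l_min)
  if (E$m == 0 || max(E$lengths, 0) < l_min)
    return(stats::setNames(logical(E$m), E$read_id))
  cfg <- cfg %||% kmer_config(l_min, n = E$n)
  flags <- .cpp_detect_contained(E$seq, l_min, cfg$k, cfg$k_prime,
                                 cfg$k_dbl_prime, !forward_only,
                                 as.integer(buffer_size %||% default_buffer(E)))
  stats::setNames(as.logical(flags), E$read_id)
}

#' Write / read an SPM file
#'
#' Tab-separated, one SPM per line: source read id, source strand (`+`/`-`),
#' destination read id, destination strand, overlap length. Lines are sorted
#' by (source id, destination id, decreasing length) so output is
#' deterministic; the round trip is lossless.
#'
#' @param spms SPM data.frame (as from [spm_overlap()]; a `status` column,
#'   if present, is preserved through the sort but not written).
#' @param path file path.
#' @return `read_spm_file` returns the SPM data.frame (without `status`).
#' @export
write_spm_file <- function(spms, path) {
  ord <- order(spms$src, spms$dst, -spms$length)
  spms <- spms[ord, , drop = FALSE]
  lines <- sprintf("%d\t%s\t%d\t%s\t%d", spms$src, spms$src_strand,
                   spms$dst, spms$dst_strand, spms$length)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spm_file
#' @export
read_spm_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0)
    return(data.frame(src = integer(0), dst = integer(0),
                      src_strand = character(0), dst_strand = character(0),
                      length = integer(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 5 || !grepl("^\\d+$", p[1]) || !grepl("^\\d+$", p[3]) ||
        !p[2] %in% c("+", "-") || !p[4] %in% c("+", "-") ||
        !grepl("^\\d+$", p[5]))
      stop(sprintf("malformed SPM file %s at line %d", path, i))
  }
  data.frame(
    src = as.integer(vapply(parts, `[[`, "", 1L)),
    src_strand = vapply(parts, `[[`, "", 2L),
    dst = as.integer(vapply(parts, `[[`, "", 3L)),
    dst_strand = vapply(parts, `[[`, "", 4L),
    length = as.integer(vapply(parts, `[[`, "", 5L))
  )
}
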