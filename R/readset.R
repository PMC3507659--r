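# Read ingestion, strand-aware encoding, and the suffix-/prefix-free
# prefilter over reads plus reverse complements.

#' Read DNA sequences from FASTA files
#'
#' Parses one or more FASTA files (wrapped or unwrapped lines, multiple
#' records per file). Sequences are case-folded to upper case; reads
#' containing any symbol other than A, C, G, T (e.g. ambiguity codes such as
#' N) are dropped and the number of dropped reads is reported via
#' [message()] and the `"dropped"` attribute.
#'
#' @param paths character vector of FASTA file paths, read in order.
#' @return character vector of validated read sequences, in file order, with
#'   attribute `dropped` (number of reads removed for non-ACGT symbols).
#'   Read ids are implicit: position in the returned vector.
#' @export
read_fasta <- function(paths) {
  seqs <- character(0)
  for (path in paths) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    lines <- readLines(path)
    nonblank <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), ";"))
    if (length(nonblank) > 0 && !startsWith(trimws(lines[nonblank[1]]), ">"))
      stop(sprintf("malformed FASTA in %s: sequence before header at line %d",
                   path, nonblank[1]))
    x <- Biostrings::readBStringSet(path)
    seqs <- c(seqs, as.character(x))
  }
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGT]", seqs) | !nzchar(seqs)
  if (any(bad))
    message(sum(bad), " read(s) dropped (ambiguity codes or empty sequence)")
  out <- unname(seqs[!bad])
  attr(out, "dropped") <- sum(bad)
  out
}

#' Encode a read set with virtual reverse complements
#'
#' Builds the strand-indexed read set over which all downstream stages
#' operate: strand indices `1..m` are the forward reads, `m+i` is the
#' reverse complement of read `i`. Reads shorter than `l_min` cannot take
#' part in any suffix-prefix match of length at least `l_min` and are
#' removed at this stage. Per-read sentinels are virtual: they are realized
#' by the comparison rules (every sentinel sorts after T, and sentinels sort
#' among themselves by strand index), never stored.
#'
#' @param reads character vector of sequences over A, C, G, T (e.g. from
#'   [read_fasta()]), or an existing `encoded_reads` object (re-encoded with
#'   the new `l_min`).
#' @param l_min minimum read/overlap length; reads shorter than this are
#'   excluded.
#' @param read_id optional integer ids carried along (default: positions in
#'   `reads`).
#' @return an object of class `encoded_reads`: list with elements `seq`
#'   (forward sequences), `read_id`, `m` (read count), `n` (total forward
#'   bases), `lengths`, `l_min`.
#' @export
encode_reads <- function(reads, l_min = 45L, read_id = NULL) {
  if (inherits(reads, "encoded_reads")) {
    read_id <- read_id %||% reads$read_id
    reads <- reads$seq
  }
  reads <- as.character(reads)
  if (l_min < 1) stop("l_min must be >= 1")
  if (length(reads) > 0 && any(grepl("[^ACGT]", reads)))
    stop("reads must contain only A, C, G, T (see read_fasta)")
  read_id <- read_id %||% seq_along(reads)
  keep <- nchar(reads) >= l_min
  E <- structure(list(
    seq = unname(reads[keep]),
    read_id = as.integer(read_id[keep]),
    m = sum(keep),
    n = sum(nchar(reads[keep])),
    lengths = unname(as.integer(nchar(reads[keep]))),
    l_min = as.integer(l_min)
  ), class = "encoded_reads")
  E
}

#' @export
print.encoded_reads <- function(x, ...) {
  cat(sprintf("encoded_reads: m = %d reads, n = %d bases (l_min = %d)\n",
              x$m, x$n, x$l_min))
  invisible(x)
}

#' Access one strand of an encoded read set
#'
#' @param E an `encoded_reads` object.
#' @param strand strand index in `1..2m`: `i <= m` is read `i`, `m + i` its
#'   reverse complement.
#' @return the strand sequence as a character scalar.
#' @export
strand_seq <- function(E, strand) {
  stopifnot(inherits(E, "encoded_reads"))
  if (any(strand < 1 | strand > 2 * E$m)) stop("strand index out of range")
  out <- character(length(strand))
  f <- strand <= E$m
  out[f] <- E$seq[strand[f]]
  out[!f] <- revcomp_dna(E$seq[strand[!f] - E$m])
  out
}

#' Base access on either strand
#'
#' `strand_base(E, m + i, p)` equals the Watson-Crick complement of base
#' `|r_i| - p + 1` of read `i` (1-based).
#'
#' @inheritParams strand_seq
#' @param pos 1-based position within the strand.
#' @return single characters.
#' @export
strand_base <- function(E, strand, pos) {
  substring(strand_seq(E, strand), pos, pos)
}

#' Lexicographically sort all strands, with lcp values
#'
#' Sorts the `2m` strands (or the `m` forward strands when
#' `forward_only = TRUE`) under the sentinel-extended order: `A < C < G < T <
#' $_1 < ... < $_2m`. Consequently, when one strand is a proper prefix of
#' another the longer strand sorts first, and identical strands are ordered
#' by strand index. The length of the longest common prefix of consecutive
#' sorted strands is returned as a byproduct.
#'
#' @inheritParams strand_seq
#' @param forward_only sort only forward strands (unit-testing aid).
#' @return list with `order` (strand indices in sorted order) and `lcp`
#'   (length `2m - 1`, lcp of consecutive sorted strands).
#' @export
lex_sort_with_lcp <- function(E, forward_only = FALSE) {
  stopifnot(inherits(E, "encoded_reads"))
  if (E$m == 0) stop("empty read set")
  .cpp_sort_strands(E$seq, !forward_only)
}

#' Compute a suffix- and prefix-free read set
#'
#' Scans lexicographically consecutive strand pairs of the sorted `2m`
#' strands. Where the lcp equals the length of one strand of the pair, that
#' strand is a prefix of the other and its read is marked (a mark on the
#' reverse-complement strand `m + i` marks forward read `i`, which is then a
#' suffix of some read). Where the two strands are identical, the read that
#' is larger under the input order is marked; no mark is placed when the two
#' strands belong to the same read (a reverse-complement palindrome would
#' otherwise delete itself). All marked reads are removed; the result is
#' suffix- and prefix-free.
#'
#' @inheritParams strand_seq
#' @return list with `kept` (a new `encoded_reads` over the surviving reads,
#'   original `read_id`s preserved) and `report` (class `prefilter_report`:
#'   kept/removed counts by category and the kept ids).
#' @export
prefilter <- function(E) {
  stopifnot(inherits(E, "encoded_reads"))
  m <- E$m
  if (m == 0) {
    report <- structure(list(keptCount = 0L, removedDuplicates = 0L,
                             removedPrefixContained = 0L,
                             removedSuffixContained = 0L,
                             keptIds = integer(0), inputCount = 0L),
                        class = "prefilter_report")
    return(list(kept = E, report = report))
  }
  srt <- .cpp_sort_strands(E$seq, TRUE)
  o <- srt$order
  l <- srt$lcp
  n2 <- length(o)
  lens2 <- c(E$lengths, E$lengths)
  sl <- lens2[o]                       # strand lengths in sorted order
  pred_len <- c(NA_integer_, sl[-n2])
  prev_l <- c(NA_integer_, l)          # lcp with the sorted predecessor
  # a strand whose lcp with its predecessor equals its own length is a
  # proper prefix of that (longer) predecessor; identical strands form runs
  # through which the containment status propagates (every copy of a
  # contained string is contained)
  ident <- !is.na(pred_len) & prev_l == sl & pred_len == sl
  cont_first <- !is.na(pred_len) & prev_l == sl & pred_len > sl
  rid <- cumsum(!ident)
  cont <- as.logical(stats::ave(cont_first, rid, FUN = any))

  reads_sorted <- ifelse(o > m, o - m, o)
  cont_strand <- o[cont]
  suf_marked <- cont_strand[cont_strand > m] - m    # read is a suffix
  prefix_marked <- cont_strand[cont_strand <= m]    # read is a prefix
  # identical runs: keep the read smallest under the input order; a run
  # formed by the two strands of a single read (reverse-complement
  # palindrome) marks nothing
  dup_marked <- integer(0)
  sizes <- tabulate(rid)
  multi <- sizes[rid] >= 2L
  if (any(multi)) {
    dup_marked <- unlist(lapply(split(reads_sorted[multi], rid[multi]),
                                function(r) {
                                  u <- unique(r)
                                  if (length(u) > 1) u[-which.min(u)]
                                  else integer(0)
                                }), use.names = FALSE)
  }

  status <- integer(m)  # 0 kept, 1 dup, 2 prefix, 3 suffix (priority order)
  status[suf_marked] <- 3L
  status[prefix_marked] <- 2L
  status[dup_marked] <- 1L

  keep <- status == 0L
  kept <- encode_reads(E$seq[keep], l_min = E$l_min,
                       read_id = E$read_id[keep])
  report <- structure(list(
    keptCount = sum(keep),
    removedDuplicates = sum(status == 1L),
    removedPrefixContained = sum(status == 2L),
    removedSuffixContained = sum(status == 3L),
    keptIds = E$read_id[keep],
    inputCount = m
  ), class = "prefilter_report")
  list(kept = kept, report = report)
}

#' @export
print.prefilter_report <- function(x, ...) {
  cat(sprintf(paste0("prefilter: %d/%d reads kept (%d duplicates, ",
                     "%d prefix-contained, %d suffix-contained removed)\n"),
              x$keptCount, x$inputCount, x$removedDuplicates,
              x$removedPrefixContained, x$removedSuffixContained))
  invisible(x)
}

#' Serialize / restore an encoded read set
#'
#' Plain-text sidecar with a versioned header; one `id TAB sequence` line
#' per read.
#'
#' @inheritParams strand_seq
#' @param path file path.
#' @return `read_encoded_reads` returns an `encoded_reads` object.
#' @export
write_encoded_reads <- function(E, path) {
  stopifnot(inherits(E, "encoded_reads"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sgasm-reads\tv1\tm=%d\tl_min=%d", E$m, E$l_min), con)
  if (E$m > 0)
    writeLines(paste(E$read_id, E$seq, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_encoded_reads
#' @export
read_encoded_reads <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#sgasm-reads\tv1"))
    stop("not an sgasm encoded-reads file (missing v1 header): ", path)
  l_min <- as.integer(sub(".*l_min=(\\d+).*", "\\1", lines[1]))
  body <- lines[-1]
  if (length(body) == 0) return(encode_reads(character(0), l_min = l_min))
  parts <- strsplit(body, "\t", fixed = TRUE)
  encode_reads(vapply(parts, `[[`, "", 2L), l_min = l_min,
               read_id = as.integer(vapply(parts, `[[`, "", 1L)))
}
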