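# Brute-force oracles: direct all-pairs string comparison over the strand
# set, definitional transitivity, containment and prefilter containment.
# These are intentionally independent of the indexed pipeline and are only
# meant for small inputs (m up to a few hundred).

strand_space <- function(reads, mode = c("both", "forward")) {
  mode <- match.arg(mode)
  if (mode == "both") c(reads, revcomp_dna(reads)) else reads
}

#' Brute-force suffix-prefix matches
#'
#' Direct enumeration over all strand pairs: an SPM `<x, y, l>` exists when
#' the length-`l` suffix of strand `x` equals the length-`l` prefix of
#' strand `y`, with `l_min <= l < |x|`. Self-overlaps (both strands of one
#' read) are excluded; with `nonredundant = TRUE` (and `mode = "both"`) the
#' mirror of each SPM is removed via [is_nonredundant()].
#'
#' @param reads character vector of read sequences (ids = positions).
#' @param l_min minimum overlap length.
#' @param mode `"both"` (reads plus reverse complements) or `"forward"`.
#' @param nonredundant apply the non-redundancy conditions.
#' @return data.frame with `src`, `dst` (strand indices), `length`.
#' @export
brute_force_spms <- function(reads, l_min, mode = c("both", "forward"),
                             nonredundant = TRUE) {
  mode <- match.arg(mode)
  strands <- strand_space(reads, mode)
  m <- length(reads)
  lens <- nchar(strands)
  rows <- list()
  if (length(strands) >= 2 && max(lens) > l_min) {
    for (l in l_min:(max(lens) - 1L)) {
      srcs <- which(lens >= l + 1L)
      dsts <- which(lens >= l)
      if (!length(srcs) || !length(dsts)) next
      suf <- substring(strands[srcs], lens[srcs] - l + 1L, lens[srcs])
      pre <- substring(strands[dsts], 1L, l)
      grp <- split(dsts, pre)
      key <- match(suf, names(grp))
      sel <- which(!is.na(key))
      if (!length(sel)) next
      hits <- grp[key[sel]]
      src <- rep(srcs[sel], lengths(hits))
      dst <- unlist(hits, use.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(src = src, dst = dst, length = l)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(src = integer(0), dst = integer(0), length = integer(0))
  readof <- function(s) ifelse(s > m & mode == "both", s - m, s)
  out <- out[readof(out$src) != readof(out$dst), , drop = FALSE]
  if (nonredundant && mode == "both")
    out <- out[is_nonredundant(out$src, out$dst, m), , drop = FALSE]
  out <- out[order(out$src, out$dst, -out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Brute-force transitivity classification
#'
#' Definitional check over the full SPM set of the strand space restricted
#' to non-contained reads: `<x, t, l''>` is transitive iff there is a strand
#' `s` with SPMs `<x, s, l>` and `<s, t, l'>` such that
#' `l + l' == |s| + l''`; irreducible otherwise.
#'
#' @inheritParams brute_force_spms
#' @return data.frame as [brute_force_spms()] (non-redundant set) plus a
#'   `status` column; attribute `contained` gives the contained-read flags
#'   used.
#' @export
brute_force_classify <- function(reads, l_min, mode = c("both", "forward")) {
  mode <- match.arg(mode)
  m <- length(reads)
  contained <- brute_force_contained(reads, mode = mode)
  keep <- which(!contained)
  sub <- reads[keep]
  raw <- brute_force_spms(sub, l_min, mode = mode, nonredundant = FALSE)
  ms <- length(sub)
  lens <- nchar(strand_space(sub, mode))
  z <- nrow(raw)
  status <- rep("irreducible", z)
  if (z > 0) {
    have <- new.env(parent = emptyenv(), size = max(29L, 2L * z))
    for (i in seq_len(z))
      assign(paste(raw$src[i], raw$dst[i], raw$length[i]), TRUE, envir = have)
    by_src <- split(seq_len(z), raw$src)
    for (i in seq_len(z)) {
      outs <- by_src[[as.character(raw$src[i])]]
      for (j in outs) {
        if (j == i) next
        s <- raw$dst[j]
        lp <- lens[s] + raw$length[i] - raw$length[j]   # required l'
        if (lp <= raw$length[i]) next                   # chain needs l' > l''
        if (exists(paste(s, raw$dst[i], lp), envir = have)) {
          status[i] <- "transitive"
          break
        }
      }
    }
  }
  raw$status <- status
  sel <- if (mode == "both") is_nonredundant(raw$src, raw$dst, ms)
  else rep(TRUE, z)
  out <- raw[sel, , drop = FALSE]
  # map strand indices back to the original read positions
  remap <- function(s) {
    out <- integer(length(s))
    f <- s <= ms
    out[f] <- keep[s[f]]
    out[!f] <- keep[s[!f] - ms] + m
    out
  }
  out$src <- remap(out$src)
  out$dst <- remap(out$dst)
  out <- out[order(out$src, out$dst, -out$length), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contained") <- contained
  out
}

#' Brute-force internally-contained reads
#'
#' A read is internally contained if it occurs in some other read or a
#' read's reverse complement with non-empty flanks on both sides.
#'
#' @inheritParams brute_force_spms
#' @return logical vector over the reads.
#' @export
brute_force_contained <- function(reads, mode = c("both", "forward")) {
  mode <- match.arg(mode)
  strands <- strand_space(reads, mode)
  m <- length(reads)
  vapply(seq_len(m), function(i) {
    pat <- reads[i]
    np <- nchar(pat)
    for (j in seq_along(strands)) {
      if (j == i || (mode == "both" && j == i + m)) next
      if (nchar(strands[j]) < np + 2L) next
      hits <- gregexpr(pat, strands[j], fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      if (any(hits >= 2L & hits + np - 1L <= nchar(strands[j]) - 1L))
        return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Brute-force prefilter oracle
#'
#' Which reads must be removed to obtain a suffix- and prefix-free set: a
#' read that is a proper prefix or proper suffix of another read or of a
#' read's reverse complement, and all but the first (in input order) of each
#' class of reads identical up to reverse complement.
#'
#' @param reads character vector of read sequences.
#' @return logical vector: `TRUE` where the read is removed.
#' @export
brute_force_prefilter_removed <- function(reads) {
  m <- length(reads)
  if (m == 0) return(logical(0))
  rc <- revcomp_dna(reads)
  strands <- c(reads, rc)
  removed <- logical(m)
  for (i in seq_len(m)) {
    for (j in seq_along(strands)) {
      if (j == i || j == i + m) next
      if (nchar(strands[j]) <= nchar(reads[i])) next
      if (startsWith(strands[j], reads[i]) || endsWith(strands[j], reads[i])) {
        removed[i] <- TRUE
        break
      }
    }
  }
  canon <- pmin(reads, rc)
  first_of_class <- !duplicated(canon)
  removed | !first_of_class
}
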