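# Assembly string graph: two vertices per read (r.B = begin, r.E = end),
# two complementary directed edges per irreducible non-redundant SPM, and
# contig extraction along maximal unbranched walks.

#' Build the assembly string graph
#'
#' For each SPM `<x, y, l>` (over oriented strands) the graph receives two
#' directed edges. Writing `out(s)` for the vertex `r.E` when strand `s` is
#' read `r` forward and `r.B` when `s` is the reverse complement of `r`, the
#' edges are `out(x) -> out(y)` with label length `|read(y)| - l` (the
#' extension of the destination read beyond the overlap) and the complement
#' `out(flip(y)) -> out(flip(x))` with label length `|read(x)| - l`, where
#' `flip` switches the strand. This reproduces the three per-case edge rules
#' for forward/forward, forward/reverse and reverse/forward SPMs. The edges
#' are laid out in a flat array of size `2 * rho` grouped by source vertex
#' (outdegree counting, partial sums, fill).
#'
#' @param spms SPM data.frame (`src`, `dst`, `src_strand`, `dst_strand`,
#'   `length`), normally the irreducible subset of [spm_overlap()] output.
#'   SPMs must not reference internally contained reads.
#' @param E the `encoded_reads` the SPM read ids refer to.
#' @param contained optional named logical (as the `contained` attribute of
#'   [spm_overlap()]); edges touching contained reads raise an error.
#' @return object of class `string_graph`: vertex count `2m` (vertex
#'   `2i - 1` is `r_i.B`, vertex `2i` is `r_i.E`), parallel edge vectors
#'   `from`, `to`, `label_len`, `spm` (row index into `spms`), complement
#'   pairing `comp`, and per-vertex offsets `out_start` (edges of vertex `v`
#'   occupy `out_start[v] + 1 .. out_start[v + 1]`).
#' @export
build_string_graph <- function(spms, E, contained = NULL) {
  stopifnot(inherits(E, "encoded_reads"))
  m <- E$m
  src_idx <- match(spms$src, E$read_id)
  dst_idx <- match(spms$dst, E$read_id)
  if (anyNA(src_idx) || anyNA(dst_idx))
    stop("SPM references a read id not present in the read set")
  if (!is.null(contained)) {
    bad <- contained[as.character(spms$src)] | contained[as.character(spms$dst)]
    if (any(bad)) stop("SPM references an internally contained read")
  }
  rho <- nrow(spms)
  x <- src_idx + m * (spms$src_strand == "-")   # strand indices
  y <- dst_idx + m * (spms$dst_strand == "-")
  out_end <- function(s) ifelse(s <= m, 2L * s, 2L * (s - m) - 1L)
  flip <- function(s) ifelse(s <= m, s + m, s - m)
  readlen <- function(s) E$lengths[ifelse(s <= m, s, s - m)]
  l <- spms$length
  if (rho > 0 && any(l < 1 | l >= readlen(x) | l >= readlen(y)))
    stop("SPM length out of range for its reads")
  from <- as.integer(c(out_end(x), out_end(flip(y))))
  to <- as.integer(c(out_end(y), out_end(flip(x))))
  label_len <- as.integer(c(readlen(y) - l, readlen(x) - l))
  spm_ref <- c(seq_len(rho), seq_len(rho))
  which_edge <- rep(1:2, each = rho)

  ord <- order(from, spm_ref, which_edge)
  pos <- integer(2 * rho)
  pos[ord] <- seq_len(2 * rho)
  comp_orig <- c(rho + seq_len(rho), seq_len(rho))  # the other edge of the SPM
  G <- structure(list(
    m = m,
    read_id = E$read_id,
    lengths = E$lengths,
    vertex_count = 2L * m,
    from = from[ord],
    to = to[ord],
    label_len = label_len[ord],
    spm = spm_ref[ord],
    comp = pos[comp_orig][ord],
    out_start = c(0L, cumsum(tabulate(from[ord], nbins = 2L * m))),
    spms = spms
  ), class = "string_graph")
  G
}

#' @export
print.string_graph <- function(x, ...) {
  cat(sprintf("string_graph: %d vertices (2 per read), %d edges (2 per SPM, rho = %d)\n",
              x$vertex_count, length(x$from), length(x$from) %/% 2L))
  invisible(x)
}

#' Complement edge
#'
#' Every SPM contributes two edges whose spelled walks are reverse
#' complements of each other; `complement_edge` maps each edge index to its
#' partner. The mapping is an involution and preserves the SPM reference.
#'
#' @param G a `string_graph`.
#' @param edge edge index (1-based).
#' @return the complement edge index.
#' @export
complement_edge <- function(G, edge) {
  stopifnot(inherits(G, "string_graph"))
  if (any(edge < 1 | edge > length(G$comp))) stop("edge index out of range")
  G$comp[edge]
}

#' Extract contigs from the string graph
#'
#' Walks maximal unbranched paths: an edge starts a contig when its source
#' vertex does not have outdegree 1 and indegree 1; the walk is extended
#' while the current vertex has outdegree 1 and indegree 1. Each traversed
#' edge is marked visited together with its complement, so every
#' double-stranded contig is reported once. Cycles of unbranched edges are
#' collected afterwards from the lowest remaining edge index. Reads with no
#' incident edges (and not internally contained) are output as single-read
#' contigs. Contig sequences are spelled from the first oriented read (out
#' of `r.E`: `r` forward; out of `r.B`: the reverse complement of `r`)
#' followed by the edge labels (the last `label_len` characters of each
#' oriented destination read).
#'
#' @param G a `string_graph`.
#' @param E the `encoded_reads` the graph was built over.
#' @param min_length minimum contig length in bases (default `l_min + 1`).
#' @param exclude named logical over read ids (e.g. contained flags):
#'   excluded reads are not reported as single-read contigs.
#' @return object of class `contig_set`: list with `sequence` (character
#'   vector) and `layout` (list of data.frames `read_id`, `strand`,
#'   `start`), ordered deterministically.
#' @export
extract_contigs <- function(G, E, min_length = NULL, exclude = NULL) {
  stopifnot(inherits(G, "string_graph"), inherits(E, "encoded_reads"))
  min_length <- min_length %||% (E$l_min + 1L)
  m <- E$m
  nE <- length(G$from)
  outdeg <- tabulate(G$from, nbins = 2L * m)
  indeg <- tabulate(G$to, nbins = 2L * m)
  through <- outdeg == 1L & indeg == 1L
  rc_seq <- revcomp_dna(E$seq)
  visited <- logical(nE)
  sequences <- list()
  layouts <- list()
  nc <- 0L

  walk_from <- function(e0) {
    cap <- 16L
    path <- integer(cap)
    np <- 0L
    e <- e0
    repeat {
      np <- np + 1L
      if (np > cap) {
        cap <- cap * 2L
        length(path) <- cap
      }
      path[np] <- e
      visited[e] <<- TRUE
      visited[G$comp[e]] <<- TRUE
      v <- G$to[e]
      if (!through[v]) break
      nxt <- G$out_start[v] + 1L
      if (visited[nxt]) break   # closed a cycle (or met the complement walk)
      e <- nxt
    }
    path[seq_len(np)]
  }
  emit <- function(path) {
    v0 <- G$from[path[1]]
    i0 <- (v0 + 1L) %/% 2L
    seq0 <- if (v0 %% 2L == 0L) E$seq[i0] else rc_seq[i0]
    w <- G$to[path]
    i <- (w + 1L) %/% 2L
    fwd <- w %% 2L == 0L
    os <- ifelse(fwd, E$seq[i], rc_seq[i])
    ll <- G$label_len[path]
    lens <- E$lengths[i]
    pieces <- substring(os, lens - ll + 1L, lens)
    starts <- nchar(seq0) + cumsum(ll) - lens
    nc <<- nc + 1L
    sequences[[nc]] <<- paste(c(seq0, pieces), collapse = "")
    layouts[[nc]] <<- data.frame(
      read_id = G$read_id[c(i0, i)],
      strand = c(if (v0 %% 2L == 0L) "+" else "-", ifelse(fwd, "+", "-")),
      start = c(0L, starts))
  }

  start_edges <- which(!through[G$from])
  for (e in start_edges) if (!visited[e]) emit(walk_from(e))
  for (e in seq_len(nE)) if (!visited[e]) emit(walk_from(e))  # cycles

  # isolated reads
  deg <- outdeg + indeg
  iso <- which(deg[2L * seq_len(m)] + deg[2L * seq_len(m) - 1L] == 0L)
  if (!is.null(exclude))
    iso <- iso[!exclude[as.character(G$read_id[iso])]]
  for (i in iso) {
    nc <- nc + 1L
    sequences[[nc]] <- E$seq[i]
    layouts[[nc]] <- data.frame(read_id = G$read_id[i], strand = "+",
                                start = 0L)
  }

  seqv <- unlist(sequences) %||% character(0)
  keep <- which(nchar(seqv) >= min_length)
  structure(list(sequence = unname(seqv[keep]), layout = layouts[keep]),
            class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  n <- length(x$sequence)
  if (n == 0) {
    cat("contig_set: 0 contigs\n")
    return(invisible(x))
  }
  lens <- nchar(x$sequence)
  cat(sprintf("contig_set: %d contig(s), total %d bp, longest %d bp, N50 %d bp\n",
              n, sum(lens), max(lens), n50(lens)))
  invisible(x)
}

#' N50 of a length distribution
#'
#' Length `x` such that contigs of length at least `x` cover at least half
#' of the total assembled bases.
#'
#' @param lengths integer vector of contig lengths.
#' @return the N50 value.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) return(0L)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}

#' Write contigs to FASTA
#'
#' Headers `contig_<n> length=<L> reads=<count>`, 70-column wrapping.
#'
#' @param contigs a `contig_set`.
#' @param path output file path.
#' @export
write_contigs_fasta <- function(contigs, path) {
  stopifnot(inherits(contigs, "contig_set"))
  if (length(contigs$sequence) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(contigs$sequence)
  names(x) <- sprintf("contig_%d length=%d reads=%d",
                      seq_along(contigs$sequence), nchar(contigs$sequence),
                      vapply(contigs$layout, nrow, 0L))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Write a GraphViz dump of a string graph
#'
#' A `digraph` rendering for inspecting small graphs (vertices `<id>.B` /
#' `<id>.E`, edges annotated with their label length). Intended for desk
#' debugging, not for large assemblies.
#'
#' @param G a `string_graph`.
#' @param path output `.dot` file path.
#' @export
write_graph_dot <- function(G, path) {
  stopifnot(inherits(G, "string_graph"))
  vname <- function(v) sprintf("\"%d.%s\"", G$read_id[(v + 1L) %/% 2L],
                               ifelse(v %% 2L == 0L, "E", "B"))
  lines <- c("digraph stringgraph {",
             sprintf("  %s -> %s [label=%d];", vname(G$from), vname(G$to),
                     G$label_len),
             "}")
  writeLines(lines, path)
  invisible(path)
}
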