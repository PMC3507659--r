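# Bottom-up traversal of the lcp-interval tree of a sorted bucket.
#
# An lcp-interval of lcp-value l over the sorted suffix array H with lcp
# table L is a maximal interval [e..f] (e < f) with L[q] >= l for
# e+1 <= q <= f, equality for at least one q, and smaller boundary values
# (or array ends) on both sides. Nesting of these intervals forms a tree
# whose leaves are the singletons [e']. The traversal delivers every leaf
# edge, every branch edge and every completed interval in bottom-up order
# (children complete before their parent's branch edge is reported).

#' Traverse the lcp-interval tree of one sorted bucket
#'
#' Runs the stack-based bottom-up traversal (push on rising lcp, pop and
#' complete on falling lcp, extended to deliver leaf edges) and replays the
#' event stream through the supplied callbacks. Every singleton is delivered
#' exactly once as a leaf edge of the deepest interval containing it;
#' `firstedge` is `TRUE` exactly on the first edge out of each interval;
#' every interval is delivered exactly once, after all its edges, with its
#' right boundary defined. For a single-entry bucket a pseudo-root
#' (`lcp = k`, `lb = rb = 0`) carries the leaf.
#'
#' @param E an `encoded_reads` object.
#' @param strand,offset the bucket entries in sorted order (see
#'   [sort_bucket()]).
#' @param L the bucket's lcp table (length `beta - 1`, all values `>= k`).
#' @param k initial-mer size of the bucket.
#' @param callbacks optional list with functions `process_leafedge(firstedge,
#'   itv, leaf)`, `process_branchedge(firstedge, itv, child)`,
#'   `process_lcpinterval(itv)`. `itv`/`child` are lists with `lcp`, `lb`,
#'   `rb` (`NA` while undefined); `leaf` is a list with `strand`, `offset`.
#' @param forward_only strand space restricted to forward strands.
#' @return (invisibly) the event log as a data.frame with columns `type`
#'   (`"leafedge"`, `"branchedge"`, `"lcpinterval"`), `firstedge`, `lcp`,
#'   `lb`, `rb`, `leaf_strand`, `leaf_offset`, `child_lcp`, `child_lb`,
#'   `child_rb` (`NA` where not applicable).
#' @export
traverse_bucket <- function(E, strand, offset, L, k, callbacks = NULL,
                            forward_only = FALSE) {
  stopifnot(inherits(E, "encoded_reads"))
  log <- .cpp_traverse_bucket(E$seq, !forward_only, as.integer(strand),
                              as.integer(offset), as.integer(L), as.integer(k))
  log$type <- c("leafedge", "branchedge", "lcpinterval")[log$type]
  log$firstedge <- log$firstedge == 1L
  for (col in c("rb", "leaf_strand", "leaf_offset", "child_lcp", "child_lb",
                "child_rb"))
    log[[col]][log[[col]] < 0] <- NA_integer_
  if (!is.null(callbacks)) {
    for (i in seq_len(nrow(log))) {
      itv <- list(lcp = log$lcp[i], lb = log$lb[i], rb = log$rb[i])
      switch(log$type[i],
        leafedge = callbacks$process_leafedge(
          log$firstedge[i], itv,
          list(strand = log$leaf_strand[i], offset = log$leaf_offset[i])),
        branchedge = callbacks$process_branchedge(
          log$firstedge[i], itv,
          list(lcp = log$child_lcp[i], lb = log$child_lb[i],
               rb = log$child_rb[i])),
        lcpinterval = callbacks$process_lcpinterval(itv))
    }
  }
  invisible(log)
}

#' Enumerate lcp-intervals by definition (oracle)
#'
#' Direct O(beta^2) enumeration of all lcp-intervals of a bucket lcp table
#' from the interval conditions; used to cross-check the traversal.
#'
#' @param L integer lcp table (length `beta - 1`).
#' @return data.frame with columns `lcp`, `lb`, `rb`, one row per
#'   lcp-interval (`lb < rb`).
#' @export
enumerate_lcp_intervals <- function(L) {
  beta <- length(L) + 1L
  out <- list()
  if (beta >= 2) {
    for (e in 0:(beta - 2)) {
      for (f in (e + 1):(beta - 1)) {
        inner <- L[(e + 1):f]           # L[q] for e+1 <= q <= f (1-based L)
        l <- min(inner)
        ok <- (e == 0 || L[e] < l) &&
          (f == beta - 1 || L[f + 1] < l) &&
          any(inner == l)
        if (ok) out[[length(out) + 1L]] <- c(lcp = l, lb = e, rb = f)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(lcp = integer(0), lb = integer(0), rb = integer(0)))
  as.data.frame(do.call(rbind, out))
}
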