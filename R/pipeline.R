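# One-shot assembly front-end and the oracle-based verification harness.

#' Assemble a read set
#'
#' Runs the full pipeline: encoding (reads shorter than `l_min` dropped),
#' prefilter (suffix-/prefix-free read set over reads plus reverse
#' complements), SPM enumeration with containment removal and transitivity
#' classification, string graph construction from the irreducible
#' non-redundant SPMs, and contig extraction.
#'
#' @param reads character vector of read sequences, an `encoded_reads`
#'   object, or path(s) to FASTA file(s).
#' @param l_min minimum overlap length in bases (default 45).
#' @param parts,mem_limit partitioning controls for the overlap stage.
#' @param min_contig_length minimum reported contig length (default
#'   `l_min + 1`).
#' @param forward_only restrict to forward strands (worked examples).
#' @param cfg optional [kmer_config()].
#' @return object of class `sgasm_assembly`: list with `encoded` (kept
#'   reads), `prefilter_report`, `spms` (all non-redundant SPMs with
#'   status), `contained`, `graph`, `contigs`, `params`.
#' @export
#' @examples
#' reads <- c("TGGACGT", "GGACGTAA", "ACGTAACC")
#' asm <- assemble_reads(reads, l_min = 4, forward_only = TRUE)
#' asm$contigs$sequence
assemble_reads <- function(reads, l_min = 45L, parts = 1L, mem_limit = NULL,
                           min_contig_length = NULL, forward_only = FALSE,
                           cfg = NULL) {
  if (is.character(reads) && length(reads) > 0 && all(file.exists(reads)))
    reads <- read_fasta(reads)
  E0 <- encode_reads(reads, l_min)
  if (E0$m == 0) stop("no reads of length >= l_min")
  pf <- prefilter(E0)
  E <- pf$kept
  if (E$m == 0) stop("no reads left after prefilter")
  spms <- spm_overlap(E, l_min = l_min, cfg = cfg, parts = parts,
                      mem_limit = mem_limit, forward_only = forward_only)
  contained <- attr(spms, "contained")
  irr <- spms[spms$status == "irreducible", , drop = FALSE]
  G <- build_string_graph(irr, E, contained = contained)
  contigs <- extract_contigs(G, E, min_length = min_contig_length,
                             exclude = contained)
  structure(list(
    encoded = E,
    prefilter_report = pf$report,
    spms = spms,
    contained = contained,
    graph = G,
    contigs = contigs,
    params = list(l_min = as.integer(l_min), parts = as.integer(parts),
                  forward_only = forward_only)
  ), class = "sgasm_assembly")
}

#' @export
print.sgasm_assembly <- function(x, ...) {
  lens <- nchar(x$contigs$sequence)
  cat("sgasm assembly\n")
  cat(sprintf("  reads kept:        %d (of %d input)\n",
              x$prefilter_report$keptCount, x$prefilter_report$inputCount))
  cat(sprintf("  contained reads:   %d\n", sum(x$contained)))
  cat(sprintf("  SPMs:              %d non-redundant, %d irreducible\n",
              nrow(x$spms), sum(x$spms$status == "irreducible")))
  cat(sprintf("  string graph:      %d vertices, %d edges\n",
              x$graph$vertex_count, length(x$graph$from)))
  cat(sprintf("  contigs:           %d (total %d bp, N50 %d bp)\n",
              length(lens), sum(lens), n50(lens)))
  invisible(x)
}

#' @export
summary.sgasm_assembly <- function(object, ...) {
  lens <- nchar(object$contigs$sequence)
  out <- list(
    reads_input = object$prefilter_report$inputCount,
    reads_kept = object$prefilter_report$keptCount,
    contained_reads = sum(object$contained),
    spm_total = nrow(object$spms),
    spm_irreducible = sum(object$spms$status == "irreducible"),
    graph_edges = length(object$graph$from),
    contig_count = length(lens),
    total_contig_length = sum(lens),
    longest_contig = if (length(lens)) max(lens) else 0L,
    n50 = n50(lens)
  )
  class(out) <- "summary.sgasm_assembly"
  out
}

#' @export
print.summary.sgasm_assembly <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Cross-check the pipeline against brute-force oracles
#'
#' On a small read set (guarded at `max_reads`), compares: the prefilter's
#' removed-read set against the brute-force containment/duplicate oracle;
#' the pipeline's full non-redundant SPM set and its irreducible subset
#' against the all-pairs and definitional-transitivity oracles; the
#' contained-read flags against the brute-force substring oracle; and
#' validates every emitted SPM by direct string comparison.
#'
#' @param reads character vector of read sequences.
#' @param l_min minimum overlap length.
#' @param forward_only restrict to forward strands.
#' @param parts partition count for the pipeline run.
#' @param max_reads refuse larger inputs (oracles are quadratic).
#' @return list with `pass` (logical scalar) and `checks` (named logical).
#' @export
verify_pipeline <- function(reads, l_min = 45L, forward_only = FALSE,
                            parts = 1L, max_reads = 5000L) {
  if (length(reads) > max_reads)
    stop("input too large for brute-force verification (max_reads = ",
         max_reads, ")")
  mode <- if (forward_only) "forward" else "both"
  E0 <- encode_reads(reads, l_min)
  pf <- prefilter(E0)
  E <- pf$kept
  checks <- c(prefilter_removed = NA, prefilter_free = NA, spm_set = NA,
              irreducible_set = NA, contained = NA, spm_strings = NA)

  oracle_rm <- brute_force_prefilter_removed(E0$seq)
  checks["prefilter_removed"] <-
    setequal(E0$read_id[oracle_rm], setdiff(E0$read_id, pf$report$keptIds))
  checks["prefilter_free"] <- !any(brute_force_prefilter_removed(E$seq))

  if (E$m > 0 && max(E$lengths) >= l_min) {
    pip <- spm_overlap(E, l_min = l_min, parts = parts,
                       forward_only = forward_only)
    ora <- brute_force_classify(E$seq, l_min, mode = mode)
    key <- function(src_strand_idx, dst_strand_idx, len, status = NULL) {
      k <- paste(src_strand_idx, dst_strand_idx, len)
      if (!is.null(status)) k <- paste(k, status)
      sort(k)
    }
    mm <- E$m
    pip_src <- match(pip$src, E$read_id) + mm * (pip$src_strand == "-")
    pip_dst <- match(pip$dst, E$read_id) + mm * (pip$dst_strand == "-")
    checks["spm_set"] <- identical(key(pip_src, pip_dst, pip$length),
                                   key(ora$src, ora$dst, ora$length))
    checks["irreducible_set"] <-
      identical(key(pip_src, pip_dst, pip$length, pip$status),
                key(ora$src, ora$dst, ora$length, ora$status))
    checks["contained"] <-
      identical(unname(attr(pip, "contained")),
                unname(attr(ora, "contained")))
    src_seq <- strand_seq(E, pip_src)
    dst_seq <- strand_seq(E, pip_dst)
    checks["spm_strings"] <- all(
      substring(src_seq, nchar(src_seq) - pip$length + 1L) ==
        substring(dst_seq, 1L, pip$length))
  } else {
    checks[c("spm_set", "irreducible_set", "contained", "spm_strings")] <- TRUE
  }
  list(pass = all(checks), checks = checks)
}
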