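# Shared fixtures and oracle helpers (built in code; no stored data).

trio_reads <- function() c(r = "TGGACGT", s = "GGACGTAA", t = "ACGTAACC")

# sentinel-aware comparison of two strands (a, b are strand indices into
# `strands`): prefix => longer first; identical => lower index first
strand_less <- function(strands, a, b) {
  x <- strands[a]; y <- strands[b]
  if (x == y) return(a < b)
  nx <- nchar(x); ny <- nchar(y)
  mi <- min(nx, ny)
  px <- substr(x, 1, mi); py <- substr(y, 1, mi)
  if (px == py) return(nx > ny)   # sentinel sorts after every base
  px < py
}

# O(n^2) selection sort under the sentinel rule: the naive ordering oracle
naive_strand_order <- function(strands) {
  idx <- seq_along(strands)
  for (i in seq_along(idx)) {
    best <- i
    for (j in seq_along(idx)) {
      if (j > i && strand_less(strands, idx[j], idx[best])) best <- j
    }
    tmp <- idx[i]; idx[i] <- idx[best]; idx[best] <- tmp
  }
  idx
}

lcp_pair <- function(a, b) {
  mi <- min(nchar(a), nchar(b))
  if (mi == 0) return(0L)
  ca <- strsplit(substr(a, 1, mi), "")[[1]]
  cb <- strsplit(substr(b, 1, mi), "")[[1]]
  d <- which(ca != cb)
  if (length(d) == 0) mi else d[1] - 1L
}

# pipeline SPM data.frame -> sorted strand-index keys (optionally + status)
spm_keys <- function(spms, E, status = FALSE) {
  if (nrow(spms) == 0) return(character(0))
  src <- match(spms$src, E$read_id) + E$m * (spms$src_strand == "-")
  dst <- match(spms$dst, E$read_id) + E$m * (spms$dst_strand == "-")
  k <- paste(src, dst, spms$length)
  if (status) k <- paste(k, spms$status)
  sort(k)
}

oracle_keys <- function(ora, status = FALSE) {
  if (nrow(ora) == 0) return(character(0))
  k <- paste(ora$src, ora$dst, ora$length)
  if (status) k <- paste(k, ora$status)
  sort(k)
}

# seeded small read set sampled from a random template (variable lengths)
sim_read_set <- function(seed, n_reads = 60, tpl_len = 1200,
                         read_length = c(30, 120)) {
  tpl <- random_genome(tpl_len, seed = seed)
  simulate_reads(tpl, read_length = read_length, seed = seed + 10000L,
                 n_reads = n_reads)
}

# structural validation of a string graph against its read set
validate_graph <- function(G, E) {
  ne <- length(G$from)
  ok_comp <- all(G$comp[G$comp] == seq_len(ne)) &&
    (ne == 0 || all(G$comp != seq_len(ne))) &&
    identical(G$spm[G$comp], G$spm)
  rc <- revcomp_dna(E$seq)
  oriented <- function(v) ifelse(v %% 2L == 0L, E$seq[(v + 1L) %/% 2L],
                                 rc[(v + 1L) %/% 2L])
  if (ne > 0) {
    src_seq <- oriented(G$from)
    dst_seq <- oriented(G$to)
    l <- nchar(dst_seq) - G$label_len
    ok_overlap <- all(l >= 1) &&
      all(substring(src_seq, nchar(src_seq) - l + 1L) ==
            substring(dst_seq, 1L, l))
  } else ok_overlap <- TRUE
  ok_comp && ok_overlap
}

# brute-force set of SPM-relevant suffixes: whole reads plus proper suffixes
# of length >= l_min whose initial k-mer equals some strand's initial k-mer
relevant_suffixes_oracle <- function(E, k, l_min, forward_only = FALSE) {
  idx <- seq_len(if (forward_only) E$m else 2L * E$m)
  strands <- strand_seq(E, idx)
  init <- unique(substr(strands, 1, k))
  out <- data.frame(strand = idx, offset = 0L)
  for (p in idx) {
    len <- nchar(strands[p])
    qmax <- len - l_min
    if (qmax >= 1) {
      q <- 1:qmax
      kmer <- substring(strands[p], q + 1L, q + k)
      hit <- q[kmer %in% init]
      if (length(hit))
        out <- rbind(out, data.frame(strand = p, offset = hit))
    }
  }
  out[order(out$strand, out$offset), ]
}
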