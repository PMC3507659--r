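# The worked three-read example used throughout:
# r = TGGACGT, s = GGACGTAA, t = ACGTAACC, l_min = 4, k = 4, forward strands.
trio_cfg <- function(E) kmer_config(4, n = E$n, k = 4)

test_that("initial k-mers are collected per strand and deduplicated", {
  E <- encode_reads(trio_reads(), l_min = 4)
  cfg <- trio_cfg(E)
  codes <- collect_initial_kmers(E, cfg, forward_only = TRUE)
  expect_equal(codes, sort(kmer_code(c("TGGA", "GGAC", "ACGT"), 4)))

  # one read yields two codes (forward + reverse complement)
  E1 <- encode_reads("ACGTA", l_min = 4)
  expect_length(collect_initial_kmers(E1, trio_cfg(E1)), 2)

  dd <- dedup_and_count(c(5, 5, 9), kmer_config(4, k = 4, k_prime = 2))
  expect_equal(dd$K, c(5, 9))
  expect_equal(dd$C_init, c(2, 1))
  expect_equal(dd$d, 2L)

  dd1 <- dedup_and_count(rep(7, 5), kmer_config(4, k = 4, k_prime = 2))
  expect_equal(dd1$d, 1L)

  trio <- dedup_and_count(codes, cfg)
  expect_equal(trio$d, 3L)
  expect_equal(trio$C_init, c(1, 1, 1))
})

test_that("candidate suffix enumeration respects offsets and the P/Q filters", {
  # offsets q in 1 .. |r| - l_min
  E <- encode_reads(c("AAAAAA", "GGGGGG"), l_min = 3)
  cfg <- kmer_config(3, n = E$n, k = 3, k_prime = 2, k_dbl_prime = 1)
  cand <- enumerate_candidate_suffixes(E, cfg, forward_only = TRUE)
  expect_true(all(cand$offset >= 1 &
                    cand$offset <= E$lengths[cand$strand] - 3))
  # a read of length l_min has no proper candidates
  E2 <- encode_reads("ACGT", l_min = 4)
  cfg2 <- kmer_config(4, n = E2$n, k = 4)
  expect_equal(nrow(enumerate_candidate_suffixes(E2, cfg2)), 0L)
  # suffixes failing P or Q are filtered out
  E3 <- encode_reads(c("AAATTT", "GGGGGG"), l_min = 3)
  cfg3 <- kmer_config(3, n = E3$n, k = 3, k_prime = 2, k_dbl_prime = 1)
  cand3 <- enumerate_candidate_suffixes(E3, cfg3, forward_only = TRUE)
  expect_equal(cand3$strand, c(2L, 2L, 2L))
  expect_equal(cand3$offset, 1:3)
})

test_that("counting phase counts whole reads plus matching candidates", {
  E <- encode_reads(trio_reads(), l_min = 4)
  cfg <- trio_cfg(E)
  cp <- counting_phase(E, cfg, forward_only = TRUE)
  expect_equal(cp$K, sort(kmer_code(c("ACGT", "GGAC", "TGGA"), 4)))
  # candidates: r@1 (GGACGT...), r@3 (ACGT), s@2 (ACGTAA) all match K
  expect_equal(cp$C[match(kmer_code("ACGT", 4), cp$K)], 3)
  expect_equal(cp$C[match(kmer_code("GGAC", 4), cp$K)], 2)
  expect_equal(cp$C[match(kmer_code("TGGA", 4), cp$K)], 1)
  expect_equal(cp$g, 6)

  # no candidates pass -> C stays at the initial multiplicities
  E2 <- encode_reads(c("AAAA", "CCCC"), l_min = 4)
  cp2 <- counting_phase(E2, kmer_config(4, n = 8, k = 4), forward_only = TRUE)
  expect_equal(cp2$C, c(1, 1))

  # batching invariance: buffer capacity 1 vs huge
  cpa <- counting_phase(E, cfg, buffer_size = 1, forward_only = TRUE)
  cpb <- counting_phase(E, cfg, buffer_size = 1e6, forward_only = TRUE)
  expect_equal(cpa$C, cpb$C)
  expect_equal(cpa$C, cp$C)
})

test_that("partial sums follow the printed recurrence exactly", {
  ps <- compute_partial_sums(c(3, 1, 1))
  expect_equal(ps$pi, c(3, 4, 5, 5))
  expect_equal(ps$g, 5)
  expect_equal(compute_partial_sums(1)$pi, c(1, 1))
  set.seed(2)
  C <- sample(1:9, 12, TRUE)
  ps2 <- compute_partial_sums(C)
  expect_equal(ps2$pi[length(ps2$pi)], sum(C))
  expect_equal(diff(ps2$pi), c(C[-1], 0))
})

test_that("insertion phase fills buckets matching the counting phase", {
  E <- encode_reads(trio_reads(), l_min = 4)
  cfg <- trio_cfg(E)
  S <- insertion_phase(E, cfg, forward_only = TRUE)
  key <- function(code) match(kmer_code(code, 4), sort(kmer_code(
    c("TGGA", "GGAC", "ACGT"), 4)))
  grab <- function(code) {
    b <- S[S$bucket == key(code), c("strand", "offset")]
    b[order(b$strand, b$offset), ]
  }
  expect_equal(grab("ACGT"),
               data.frame(strand = c(1L, 2L, 3L), offset = c(3L, 2L, 0L)),
               ignore_attr = TRUE)
  expect_equal(grab("GGAC"),
               data.frame(strand = c(1L, 2L), offset = c(1L, 0L)),
               ignore_attr = TRUE)
  expect_equal(grab("TGGA"),
               data.frame(strand = 1L, offset = 0L), ignore_attr = TRUE)

  # partition invariance: concatenated S identical up to within-bucket order
  canon <- function(df) df[order(df$bucket, df$strand, df$offset), ]
  for (q in c(2, 3, 7)) {
    Sq <- insertion_phase(E, cfg, parts = q, forward_only = TRUE)
    expect_equal(canon(Sq), canon(S), ignore_attr = TRUE)
  }
})

test_that("the suffix table holds exactly the SPM-relevant suffixes", {
  set.seed(31)
  for (rep in 1:6) {
    reads <- sim_read_set(rep + 700, n_reads = sample(15:60, 1),
                          tpl_len = 600, read_length = c(25, 80))
    E <- prefilter(encode_reads(reads, l_min = 20))$kept
    cfg <- kmer_config(20, n = E$n, k = sample(4:12, 1))
    S <- insertion_phase(E, cfg)
    got <- S[order(S$strand, S$offset), c("strand", "offset")]
    want <- relevant_suffixes_oracle(E, cfg$k, 20)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("partition planning tiles the buckets and honors memory limits", {
  C <- c(5, 1, 1, 1, 8, 2)
  p1 <- plan_partitions(C, parts = 1)
  expect_equal(unname(p1[1, ]), c(1L, 6L))
  pd <- plan_partitions(C, parts = length(C))
  expect_equal(nrow(pd), length(C))         # one bucket range per part
  p2 <- plan_partitions(C, parts = 2)
  expect_equal(unname(p2[1, "lo"]), 1L)
  expect_equal(unname(p2[nrow(p2), "hi"]), 6L)
  expect_true(all(p2[-1, "lo"] == p2[-nrow(p2), "hi"] + 1L))  # contiguous
  # memory limit below a single bucket's requirement
  expect_error(plan_partitions(C, mem_limit = 16), "memory limit")
  pm <- plan_partitions(C, mem_limit = 16 * 8 + 8)
  expect_equal(unname(pm[1, "lo"]), 1L)
  expect_equal(unname(pm[nrow(pm), "hi"]), 6L)
})

test_that("bucket sorting orders full suffixes with lcp table", {
  E <- encode_reads(trio_reads(), l_min = 4)
  # bucket(ACGT) = {t@0, r@3, s@2}
  sb <- sort_bucket(E, strand = c(3L, 1L, 2L), offset = c(0L, 3L, 2L), k = 4,
                    forward_only = TRUE)
  # sorted: ACGTAACC < ACGTAA$ < ACGT$  (sentinels sort after bases)
  expect_equal(sb$order, c(1L, 3L, 2L))
  expect_equal(sb$L, c(6L, 4L))

  # singleton bucket: empty lcp table
  sb1 <- sort_bucket(E, strand = 1L, offset = 0L, k = 4, forward_only = TRUE)
  expect_length(sb1$L, 0)

  # equal remaining strings from different reads: strand-index tie-break,
  # L equals the full suffix length
  E2 <- encode_reads(c("TTACGTA", "AAACGTA"), l_min = 5)
  sb2 <- sort_bucket(E2, strand = c(2L, 1L), offset = c(2L, 2L), k = 4,
                     forward_only = TRUE)
  expect_equal(sb2$order, c(2L, 1L))   # suffixes equal ("ACGTA"): read 1 first
  expect_equal(sb2$L, 5L)
})

test_that("per-bucket lcp tables match direct pairwise comparison", {
  set.seed(41)
  for (rep in 1:5) {
    reads <- sim_read_set(rep + 900, n_reads = 30, tpl_len = 400,
                          read_length = c(25, 60))
    E <- prefilter(encode_reads(reads, l_min = 20))$kept
    cfg <- kmer_config(20, n = E$n, k = 6)
    S <- insertion_phase(E, cfg)
    for (b in unique(S$bucket)) {
      ent <- S[S$bucket == b, ]
      sb <- sort_bucket(E, ent$strand, ent$offset, cfg$k)
      if (length(sb$L) > 0) {
        H <- ent[sb$order, ]
        suf <- substring(strand_seq(E, H$strand), H$offset + 1)
        expect_true(all(sb$L >= cfg$k))
        expect_equal(sb$L, vapply(seq_len(nrow(H) - 1), function(j)
          lcp_pair(suf[j], suf[j + 1]), 0L))
      }
    }
  }
})
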