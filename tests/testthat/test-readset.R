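test_that("read_fasta validates, case-folds and drops ambiguous reads", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "ACNT"), f)
  suppressMessages(reads <- read_fasta(f))
  expect_equal(unname(reads[1]), "ACGT")
  expect_length(reads, 1)
  expect_equal(attr(reads, "dropped"), 1L)

  writeLines(c(">a", "acgt"), f)
  expect_equal(unname(read_fasta(f)[1]), "ACGT")

  writeLines(character(0), f)
  expect_length(read_fasta(f), 0)

  writeLines(c("ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")

  # multi-record, wrapped lines, multiple files
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGTAC", "GTACGT", ">y", "TTTT"), f)
  writeLines(c(">z", "GGGG"), f2)
  expect_equal(as.character(read_fasta(c(f, f2))),
               c("ACGTACGTACGT", "TTTT", "GGGG"))
})

test_that("encode_reads filters by l_min and exposes both strands", {
  E <- encode_reads("ACGTA", l_min = 3)
  expect_equal(E$m, 1L)
  expect_equal(E$n, 5L)
  expect_equal(strand_seq(E, 2), "TACGT")
  expect_equal(strand_base(E, 2, 1:5), c("T", "A", "C", "G", "T"))

  expect_equal(encode_reads("AC", l_min = 3)$m, 0L)
  expect_equal(strand_seq(encode_reads("AAAA", l_min = 1), 2), "TTTT")

  # reverse-complement access invariant on random reads
  set.seed(5)
  reads <- sim_read_set(5, n_reads = 10)
  E <- encode_reads(reads, l_min = 30)
  for (i in seq_len(E$m)) {
    expect_equal(E$lengths[i], nchar(strand_seq(E, E$m + i)))
    p <- sample(E$lengths[i], 3)
    expect_equal(strand_base(E, E$m + i, p),
                 chartr("ACGT", "TGCA",
                        strand_base(E, i, E$lengths[i] - p + 1)))
  }
})

test_that("lexicographic strand sort honors the virtual-sentinel rule", {
  # a proper prefix sorts after the longer string (sentinel > T)
  E <- encode_reads(c("ACGT", "ACG"), l_min = 1)
  srt <- lex_sort_with_lcp(E, forward_only = TRUE)
  expect_equal(srt$order, c(1L, 2L))
  expect_equal(srt$lcp, 3L)

  # a single read still has two strands and one lcp value
  E1 <- encode_reads("ACGTT", l_min = 1)
  srt1 <- lex_sort_with_lcp(E1)
  expect_length(srt1$order, 2)
  expect_length(srt1$lcp, 1)

  # identical reads: lcp equals the read length, tie broken by index
  E2 <- encode_reads(c("ACGT", "ACGT"), l_min = 1)
  srt2 <- lex_sort_with_lcp(E2, forward_only = TRUE)
  expect_equal(srt2$order, c(1L, 2L))
  expect_equal(srt2$lcp, 4L)
})

test_that("lex_sort_with_lcp matches the naive sort + pairwise-lcp oracle", {
  set.seed(11)
  for (rep in 1:8) {
    m <- sample(2:25, 1)
    reads <- vapply(seq_len(m), function(i)
      paste(sample(c("A", "C", "G", "T"), sample(3:12, 1), replace = TRUE),
            collapse = ""), "")
    if (rep %% 2 == 0) reads[1] <- reads[m]          # force duplicates
    if (rep %% 3 == 0) reads[2] <- substr(reads[m], 1, 3)  # force prefixes
    E <- encode_reads(reads, l_min = 1)
    srt <- lex_sort_with_lcp(E)
    strands <- strand_seq(E, seq_len(2 * m))
    expect_equal(srt$order, naive_strand_order(strands))
    sorted <- strands[srt$order]
    expect_equal(srt$lcp,
                 vapply(seq_len(2 * m - 1), function(t)
                   lcp_pair(sorted[t], sorted[t + 1]), 0L))
  }
})

test_that("prefilter removes prefixes, suffixes and duplicates", {
  E <- encode_reads(c("ACGTA", "ACGT", "CGTA", "ACGTA"), l_min = 4)
  res <- prefilter(E)
  expect_equal(res$kept$seq, "ACGTA")
  expect_equal(res$report$keptIds, 1L)     # the first copy survives
  expect_equal(res$report$removedDuplicates, 1L)
  expect_equal(res$report$removedPrefixContained, 1L)
  expect_equal(res$report$removedSuffixContained, 1L)
  with(res$report, expect_equal(
    keptCount + removedDuplicates + removedPrefixContained +
      removedSuffixContained, inputCount))

  # cross-strand identical pair: revcomp(AACGT) == ACGTT; one read removed
  res2 <- prefilter(encode_reads(c("ACGTT", "AACGT"), l_min = 4))
  expect_equal(res2$kept$m, 1L)
  expect_equal(res2$report$keptIds, 1L)

  # reverse-complement palindrome must not delete itself
  res3 <- prefilter(encode_reads("ACGT", l_min = 4))
  expect_equal(res3$kept$seq, "ACGT")
  res4 <- prefilter(encode_reads("AAAA", l_min = 4))
  expect_equal(res4$kept$seq, "AAAA")
})

test_that("prefilter matches the brute-force oracle and is idempotent", {
  set.seed(21)
  for (rep in 1:12) {
    reads <- sim_read_set(rep + 300, n_reads = sample(20:120, 1),
                          tpl_len = 500, read_length = c(20, 60))
    # salt with planted containments
    base <- sample(which(nchar(reads) >= 30), 4)
    reads <- c(reads,
               reads[base[1]],                                   # duplicate
               revcomp_dna(reads[base[2]]),                      # rc duplicate
               substr(reads[base[3]], 1, nchar(reads[base[3]]) - 5),  # prefix
               substring(reads[base[4]], 6))                     # suffix
    E <- encode_reads(reads, l_min = 15)
    res <- prefilter(E)
    oracle_removed <- E$read_id[brute_force_prefilter_removed(E$seq)]
    expect_setequal(setdiff(E$read_id, res$report$keptIds), oracle_removed)
    # kept set is suffix- and prefix-free
    expect_false(any(brute_force_prefilter_removed(res$kept$seq)))
    # idempotent
    res2 <- prefilter(res$kept)
    expect_equal(res2$kept$seq, res$kept$seq)
    expect_equal(res2$report$keptCount, res$report$keptCount)
  }
})

test_that("encoded read sets round-trip through the text sidecar", {
  E <- encode_reads(c("ACGTACGTA", "TTTTACGTT"), l_min = 5)
  f <- withr::local_tempfile()
  write_encoded_reads(E, f)
  E2 <- read_encoded_reads(f)
  expect_equal(E2$seq, E$seq)
  expect_equal(E2$read_id, E$read_id)
  expect_equal(E2$l_min, E$l_min)
  expect_error(read_encoded_reads({
    writeLines("garbage", f); f
  }), "v1 header")
})
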