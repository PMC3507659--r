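test_that("the worked trio yields its SPMs with correct classification", {
  E <- encode_reads(trio_reads(), l_min = 4)
  spms <- spm_overlap(E, l_min = 4, cfg = kmer_config(4, n = E$n, k = 4),
                      forward_only = TRUE)
  got <- spms[order(spms$src, spms$dst), ]
  expect_equal(got$src, c(1L, 1L, 2L))
  expect_equal(got$dst, c(2L, 3L, 3L))
  expect_equal(got$length, c(6L, 4L, 6L))
  expect_equal(got$status, c("irreducible", "transitive", "irreducible"))
  expect_false(any(attr(spms, "contained")))
})

test_that("non-redundancy keeps exactly one SPM of each mirror pair", {
  m <- 5L
  expect_true(is_nonredundant(1L, 2L, m))                  # both forward
  expect_true(is_nonredundant(1L, m + 2L, m))              # 1 precedes 2
  expect_false(is_nonredundant(2L, m + 1L, m))             # its mirror
  expect_false(is_nonredundant(m + 1L, m + 2L, m))         # both reverse
  expect_true(is_nonredundant(m + 3L, 1L, m))              # 1 precedes 3
  expect_false(is_nonredundant(m + 1L, 3L, m))
  # exhaustive mirror exclusivity: exactly one of (x, y) / (flip(y), flip(x))
  flip <- function(s) ifelse(s <= m, s + m, s - m)
  for (x in 1:(2 * m)) for (y in 1:(2 * m)) {
    if (x == y || flip(x) == y) next
    expect_equal(is_nonredundant(x, y, m) +
                   is_nonredundant(flip(y), flip(x), m), 1L)
  }
})

test_that("left-context dictionary decides suffix membership", {
  D <- lc_dict()
  expect_false(lcsearch(D, "TGG"))        # empty dictionary: added
  expect_true(lcsearch(D, "TGG"))         # itself is a suffix of itself
  D2 <- lc_dict()
  expect_false(lcsearch(D2, "GG"))
  expect_true(lcsearch(D2, "TGG"))        # "GG" is a suffix of "TGG"
  D3 <- lc_dict()
  expect_false(lcsearch(D3, "AG"))
  expect_false(lcsearch(D3, "TGG"))       # "AG" is not a suffix; "TGG" added
  expect_true(lcsearch(D3, "ATGG"))
})

test_that("internally contained reads are recognized on both strands", {
  # ACGTA occurs inside TACGTAG with non-empty flanks
  E <- encode_reads(c("TACGTAG", "ACGTA"), l_min = 4)
  flags <- detect_internally_contained(E, l_min = 4,
                                       cfg = kmer_config(4, n = E$n, k = 4))
  expect_equal(unname(flags), c(FALSE, TRUE))

  # the trio has no internal occurrences
  E2 <- encode_reads(trio_reads(), l_min = 4)
  expect_false(any(detect_internally_contained(
    E2, l_min = 4, cfg = kmer_config(4, n = E2$n, k = 4))))

  # containment via the reverse-complement strand
  E3 <- encode_reads(c("TACGTAG", revcomp_dna("ACGTA")), l_min = 4)
  flags3 <- detect_internally_contained(E3, l_min = 4,
                                        cfg = kmer_config(4, n = E3$n, k = 4))
  expect_equal(unname(flags3), c(FALSE, TRUE))

  # agrees with the brute-force substring oracle on random sets
  set.seed(61)
  for (rep in 1:8) {
    reads <- sim_read_set(rep + 1300, n_reads = 40, tpl_len = 500,
                          read_length = c(25, 90))
    E <- prefilter(encode_reads(reads, l_min = 20))$kept
    flags <- detect_internally_contained(E, l_min = 20)
    expect_equal(unname(flags), brute_force_contained(E$seq))
  }
})

test_that("SPM files round-trip and are deterministically sorted", {
  E <- encode_reads(trio_reads(), l_min = 4)
  spms <- spm_overlap(E, l_min = 4, cfg = kmer_config(4, n = E$n, k = 4),
                      forward_only = TRUE)
  irr <- spms[spms$status == "irreducible", ]
  f <- withr::local_tempfile()
  write_spm_file(irr, f)
  expect_equal(readLines(f), c("1\t+\t2\t+\t6", "2\t+\t3\t+\t6"))
  back <- read_spm_file(f)
  expect_equal(back$src, c(1L, 2L))
  expect_equal(back$length, c(6L, 6L))

  write_spm_file(irr[0, ], f)
  expect_length(readLines(f), 0)
  expect_equal(nrow(read_spm_file(f)), 0L)

  writeLines(c("1\t+\t2\t+\t6", "junk line"), f)
  expect_error(read_spm_file(f), "line 2")

  # lossless round trip on random SPM sets
  set.seed(71)
  reads <- sim_read_set(1400, n_reads = 80, tpl_len = 700,
                        read_length = c(40, 90))
  E2 <- prefilter(encode_reads(reads, l_min = 30))$kept
  s2 <- spm_overlap(E2, l_min = 30)
  write_spm_file(s2, f)
  b2 <- read_spm_file(f)
  expect_equal(nrow(b2), nrow(s2))
  expect_equal(sort(paste(b2$src, b2$src_strand, b2$dst, b2$dst_strand,
                          b2$length)),
               sort(paste(s2$src, s2$src_strand, s2$dst, s2$dst_strand,
                          s2$length)))
})

test_that("pipeline SPMs match the brute-force oracles on random sets", {
  set.seed(81)
  for (rep in 1:10) {
    l_min <- c(15L, 25L, 45L)[rep %% 3 + 1]
    reads <- sim_read_set(rep + 1500, n_reads = sample(20:120, 1),
                          tpl_len = sample(400:1500, 1),
                          read_length = c(30, 120))
    for (fo in c(FALSE, TRUE)) {
      E <- prefilter(encode_reads(reads, l_min))$kept
      if (E$m == 0) next
      pip <- spm_overlap(E, l_min = l_min, forward_only = fo)
      ora <- brute_force_classify(E$seq, l_min,
                                  mode = if (fo) "forward" else "both")
      expect_equal(spm_keys(pip, E), oracle_keys(ora))
      expect_equal(spm_keys(pip, E, status = TRUE),
                   oracle_keys(ora, status = TRUE))
      expect_equal(unname(attr(pip, "contained")),
                   unname(attr(ora, "contained")))
    }
  }
})

test_that("every emitted SPM validates by direct string comparison", {
  set.seed(91)
  reads <- sim_read_set(1600, n_reads = 100, tpl_len = 900,
                        read_length = c(35, 110))
  E <- prefilter(encode_reads(reads, l_min = 25))$kept
  spms <- spm_overlap(E, l_min = 25)
  expect_gt(nrow(spms), 0)
  src <- match(spms$src, E$read_id) + E$m * (spms$src_strand == "-")
  dst <- match(spms$dst, E$read_id) + E$m * (spms$dst_strand == "-")
  ss <- strand_seq(E, src)
  ds <- strand_seq(E, dst)
  expect_true(all(spms$length >= 25 & spms$length < nchar(ss)))
  expect_true(all(substring(ss, nchar(ss) - spms$length + 1) ==
                    substring(ds, 1, spms$length)))
})
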