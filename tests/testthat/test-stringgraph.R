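trio_graph <- function() {
  E <- encode_reads(trio_reads(), l_min = 4)
  spms <- spm_overlap(E, l_min = 4, cfg = kmer_config(4, n = E$n, k = 4),
                      forward_only = TRUE)
  irr <- spms[spms$status == "irreducible", ]
  list(E = E, spms = spms, irr = irr,
       G = build_string_graph(irr, E, contained = attr(spms, "contained")))
}

test_that("the worked trio produces the expected graph and contig", {
  tg <- trio_graph()
  G <- tg$G
  expect_equal(G$vertex_count, 6L)
  expect_length(G$from, 4L)                   # 2 * rho, rho = 2
  # vertex 2i-1 = r_i.B, 2i = r_i.E
  # <r,s,6>: r.E -> s.E (label "AA", 2) and s.B -> r.B (label "A", 1)
  # <s,t,6>: s.E -> t.E (label "CC", 2) and t.B -> s.B (2, on the RC strand)
  key <- paste(G$from, G$to, G$label_len)
  expect_setequal(key, c("2 4 2", "3 1 1", "4 6 2", "5 3 2"))
  # complementing is an involution pairing the two edges of each SPM
  expect_equal(G$comp[G$comp], seq_along(G$comp))
  e_rEsE <- which(G$from == 2 & G$to == 4)
  expect_equal(G$from[complement_edge(G, e_rEsE)], 3L)  # s.B -> r.B
  expect_equal(G$spm[complement_edge(G, e_rEsE)], G$spm[e_rEsE])

  ctg <- extract_contigs(G, tg$E, exclude = attr(tg$spms, "contained"))
  expect_length(ctg$sequence, 1L)
  expect_true(ctg$sequence %in% c("TGGACGTAACC", revcomp_dna("TGGACGTAACC")))
  # layout (0-based starts): r at 0, s at 1, t at 3
  lay <- ctg$layout[[1]]
  if (ctg$sequence == "TGGACGTAACC") {
    expect_equal(lay$read_id, c(1L, 2L, 3L))
    expect_equal(lay$start, c(0L, 1L, 3L))
  }
})

test_that("degenerate graphs behave", {
  E <- encode_reads(c("ACGTACGTA", "TTTTTTTTT"), l_min = 5)
  empty <- data.frame(src = integer(0), dst = integer(0),
                      src_strand = character(0), dst_strand = character(0),
                      length = integer(0))
  G <- build_string_graph(empty, E)
  expect_equal(G$vertex_count, 4L)
  expect_length(G$from, 0L)
  # with no SPMs the reads themselves come back as contigs
  ctg <- extract_contigs(G, E, min_length = 1)
  expect_setequal(ctg$sequence, E$seq)
  # short contigs are dropped by min_length
  expect_length(extract_contigs(G, E, min_length = 10)$sequence, 0L)
  # unknown read ids are rejected
  bad <- data.frame(src = 9L, dst = 1L, src_strand = "+", dst_strand = "+",
                    length = 5L)
  expect_error(build_string_graph(bad, E), "not present")
})

test_that("edge count is 2*rho and every edge revalidates by string comparison", {
  set.seed(101)
  for (rep in 1:5) {
    reads <- sim_read_set(rep + 1700, n_reads = 80,
                          tpl_len = sample(500:1200, 1),
                          read_length = c(40, 100))
    E <- prefilter(encode_reads(reads, l_min = 30))$kept
    spms <- spm_overlap(E, l_min = 30)
    irr <- spms[spms$status == "irreducible", ]
    G <- build_string_graph(irr, E, contained = attr(spms, "contained"))
    expect_length(G$from, 2L * nrow(irr))
    expect_true(validate_graph(G, E))
  }
})

test_that("contig layouts re-spell the contig sequence", {
  tpl <- random_genome(4000, seed = 4100)
  reads <- tile_reads(tpl, 100, 50)
  set.seed(111)
  flip <- runif(length(reads)) < 0.5
  reads[flip] <- revcomp_dna(reads[flip])
  asm <- assemble_reads(reads, l_min = 45)
  for (i in seq_along(asm$contigs$sequence)) {
    lay <- asm$contigs$layout[[i]]
    ctg <- asm$contigs$sequence[i]
    for (j in seq_len(nrow(lay))) {
      r <- asm$encoded$seq[match(lay$read_id[j], asm$encoded$read_id)]
      if (lay$strand[j] == "-") r <- revcomp_dna(r)
      expect_equal(substring(ctg, lay$start[j] + 1, lay$start[j] + nchar(r)),
                   r)
    }
    # consecutive reads overlap by their SPM length (>= l_min)
    if (nrow(lay) > 1) {
      ov <- head(lay$start, -1) + 100L - lay$start[-1]
      expect_true(all(ov >= 45L))
    }
  }
})

test_that("a repeat boundary starts a new contig containing the branch read", {
  # two templates sharing a 60-mer: the branching vertex splits the walks
  set.seed(121)
  core <- random_genome(60, seed = 4200)
  left1 <- random_genome(150, seed = 4201)
  left2 <- random_genome(150, seed = 4202)
  right <- random_genome(150, seed = 4203)
  t1 <- paste0(left1, core, right)
  t2 <- paste0(left2, core)
  reads <- c(tile_reads(t1, 100, 40), tile_reads(t2, 100, 40))
  asm <- suppressWarnings(assemble_reads(unique(reads), l_min = 45))
  expect_gt(length(asm$contigs$sequence), 1L)
})

test_that("flipping every read strand yields the same contigs up to RC", {
  reads <- sim_read_set(1800, n_reads = 150, tpl_len = 2500,
                        read_length = c(80, 100))
  asm1 <- assemble_reads(reads, l_min = 45)
  asm2 <- assemble_reads(revcomp_dna(reads), l_min = 45)
  canon <- function(x) sort(pmin(x, revcomp_dna(x)))
  expect_equal(canon(asm1$contigs$sequence), canon(asm2$contigs$sequence))
})

test_that("contig FASTA output round-trips", {
  tg <- trio_graph()
  ctg <- extract_contigs(tg$G, tg$E)
  f <- withr::local_tempfile(fileext = ".fa")
  write_contigs_fasta(ctg, f)
  back <- read_fasta(f)
  expect_equal(as.character(back), ctg$sequence)
  expect_match(readLines(f)[1], "^>contig_1 length=11 reads=3$")
  write_contigs_fasta(extract_contigs(tg$G, tg$E, min_length = 100), f)
  expect_length(readLines(f), 0L)
})
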