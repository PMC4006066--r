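test_that("generated transcripts contain the motif exactly once, reproducibly", {
  tr1 <- make_motif_transcript(flank5_len = 6, flank3_len = 6, seed = 3)
  tr2 <- make_motif_transcript(flank5_len = 6, flank3_len = 6, seed = 3)
  expect_identical(tr1$seq, tr2$seq)
  expect_identical(nchar(tr1$seq), 30L)
  expect_length(match_motif(builtin_descriptor("hsl"), tr1$seq), 1)

  tr3 <- make_motif_transcript(flank5_len = 6, flank3_len = 6, seed = 4)
  expect_false(identical(tr1$seq, tr3$seq))
})

test_that("flankless transcripts are bulge + stem-loop with the match at 3..18", {
  tr <- make_motif_transcript(flank5_len = 0, flank3_len = 0, seed = 5)
  expect_identical(nchar(tr$seq), 18L)
  expect_identical(tr$motif$bulge_positions, c(1L, 2L))
  expect_identical(c(tr$motif$start, tr$motif$end), c(3L, 18L))
})

test_that("make_splint regenerates the worked example ncRNA", {
  m <- worked_motif()
  des <- splint_design(arm5_len = 6, arm3_len = 6, gap = 2, gap_seq = "AA")
  sp <- make_splint(WORKED_TX, m, des)
  expect_identical(sp$seq, WORKED_NC)
  expect_identical(sp$truth$mJ5, 2L)
  expect_identical(sp$truth$mJ3, 0L)
  expect_identical(sp$truth$nJ, 2L)

  des0 <- splint_design(arm5_len = 6, arm3_len = 6, gap = 0)
  expect_identical(make_splint(WORKED_TX, m, des0)$truth$nJ, 0L)

  desX <- splint_design(arm5_len = 6, arm3_len = 6, gap = 2,
                        mismatch_rate = 1.0, seed = 8)
  spX <- make_splint(WORKED_TX, m, desX)
  expect_null(spX$truth)
  # every designed arm position is now non-complementary to its target
  ptX <- designed_structure(WORKED_TX, m, spX$seq, desX)
  ip <- inter_pairs(ptX)
  tx_chars <- strsplit(WORKED_TX, "")[[1]]
  nc_chars <- strsplit(spX$seq, "")[[1]]
  ok <- mapply(function(i, j) {
    sxrna:::bases_pair(tx_chars[i], nc_chars[j], allow_wobble = FALSE)
  }, ip$mpos, ip$npos)
  expect_false(any(ok))

  expect_error(make_splint(WORKED_TX, m, splint_design(20, 6)), "5' flank")
  expect_error(make_splint(WORKED_TX, m, splint_design(6, 20)), "3' flank")
})

test_that("the designed structure of the worked example is the worked dot-bracket", {
  m <- worked_motif()
  des <- splint_design(6, 6, gap = 2, gap_seq = "AA")
  sp <- make_splint(WORKED_TX, m, des)
  pt <- designed_structure(WORKED_TX, m, sp$seq, des)
  expect_identical(render_dotbracket(pt), WORKED_DB)
})

test_that("designed structures recover the design parameters exactly", {
  fx <- make_fixture_set(n = 200, seed = 2024, arm_range = 4:10,
                         gap_range = 0:6)
  ok <- 0L
  for (d in fx$designs) {
    pt <- designed_structure(d$transcript$seq, d$transcript$motif,
                             d$splint$seq, d$design)
    ann <- annotate_junction(pt, d$transcript$motif)
    tr <- d$splint$truth
    hit <- identical(ann$mJ5, tr$mJ5) && identical(ann$mJ3, tr$mJ3) &&
      identical(ann$nJ, tr$nJ) &&
      identical(ann$h5_pairs, tr$h5_pairs) &&
      identical(ann$h3_pairs, tr$h3_pairs) &&
      isTRUE(ann$bulge_unpaired)
    ok <- ok + hit
  }
  expect_identical(ok, 200L)
})

test_that("negative controls come as ablators plus dinucleotide-shuffled decoys", {
  m <- worked_motif()
  neg <- make_negatives(WORKED_TX, m, n = 2, seed = 6)
  expect_length(neg$seqs, 2)
  expect_identical(neg$truth$expected_class, c("repressor", "none"))
  # ablator 1 is the reverse complement of loop + 3' stem
  expect_identical(neg$seqs[[1]],
                   reverse_complement(substr(WORKED_TX, 15, 24)))
  # decoy preserves length and dinucleotide counts
  expect_identical(nchar(neg$seqs[[2]]), nchar(neg$seqs[[1]]))
  expect_identical(dinuc_counts(neg$seqs[[2]]), dinuc_counts(neg$seqs[[1]]))
})

test_that("dinucleotide shuffling is seeded and count-preserving", {
  set.seed(77)
  for (rep in 1:30) {
    x <- random_rna(sample(10:40, 1))
    y <- dinucleotide_shuffle(x, seed = rep)
    expect_identical(dinuc_counts(y), dinuc_counts(x))
    expect_identical(substr(y, 1, 1), substr(x, 1, 1))
    expect_identical(substr(y, nchar(y), nchar(y)), substr(x, nchar(x), nchar(x)))
  }
  expect_identical(dinucleotide_shuffle("ACGUACGUACGU", 5),
                   dinucleotide_shuffle("ACGUACGUACGU", 5))
})

test_that("fixture sets write valid FASTA pairs and a truth table", {
  dir <- withr::local_tempdir()
  fx <- make_fixture_set(n = 3, seed = 9, out_dir = dir)
  tx <- read_rna_fasta(file.path(dir, "transcripts.fa"), "transcript")
  nc <- read_rna_fasta(file.path(dir, "ncrnas.fa"), "smallrna")
  expect_length(tx, 3)
  expect_length(nc, 9)   # splint + ablator + decoy per design
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_identical(nrow(truth), 3L)
  expect_true(all(truth$expected_class == "inducer"))
})
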