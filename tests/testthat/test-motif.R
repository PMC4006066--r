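# Sliding-window oracle for the fixed-geometry HSL descriptor: at every
# start, check AA, then a 6-bp stem around a 4-nt loop with WC/G.U
# complementarity. Independent of the element-recursion matcher.
hsl_oracle_starts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  pairs_ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  hits <- integer(0)
  n <- length(ch)
  for (s in seq_len(max(0, n - 17))) {
    if (ch[s] != "A" || ch[s + 1] != "A") next
    stem5 <- s + 2:7; stem3 <- s + 12:17
    if (max(stem3) > n) next
    if (all(mapply(pairs_ok, ch[stem5], ch[rev(stem3)]))) {
      hits <- c(hits, s + 2L)   # span starts at the stem
    }
  }
  hits
}

test_that("built-in descriptors have the published geometry", {
  hsl <- builtin_descriptor("hsl")
  expect_s3_class(hsl, "motif_descriptor")
  expect_identical(hsl$anchors5, 1L)
  # 6-bp stem + 4-nt loop: a 16-base stem-loop
  expect_identical(hsl$elements[[2]]$min_len, 6L)
  expect_identical(hsl$elements[[3]]$min_len, 4L)
  ire <- builtin_descriptor("ire")
  expect_identical(ire$elements[[2]]$iupac, "CAGUGH")
  expect_error(builtin_descriptor("xyz"), "available")
})

test_that("the worked HSL transcript matches once with the expected sub-spans", {
  m <- match_motif(builtin_descriptor("hsl"), WORKED_TX, "tx")
  expect_length(m, 1)
  m <- m[[1]]
  expect_identical(m$bulge_positions, c(7L, 8L))
  expect_identical(m$stem5, c(9L, 14L))
  expect_identical(m$loop, c(15L, 18L))
  expect_identical(m$stem3, c(19L, 24L))
  expect_identical(c(m$start, m$end), c(9L, 24L))
  expect_identical(m$end - m$start + 1L, 16L)
  expect_true(validate_motif_match(m, builtin_descriptor("hsl"), WORKED_TX))
})

test_that("no-stem sequences yield no matches; tandem motifs yield two", {
  expect_length(match_motif(builtin_descriptor("hsl"), strrep("A", 60)), 0)
  core <- substr(WORKED_TX, 7, 24)  # AA + 16-nt stem-loop
  tandem <- paste0("CAC", core, "CAC", core, "CAC")
  m <- match_motif(builtin_descriptor("hsl"), tandem)
  expect_length(m, 2)
  expect_lt(m[[1]]$start, m[[2]]$start)
})

test_that("matches shift but do not change under flanking sequence", {
  m0 <- match_motif(builtin_descriptor("hsl"), WORKED_TX)
  prefix <- "CCCACCCACCCA"
  m1 <- match_motif(builtin_descriptor("hsl"), paste0(prefix, WORKED_TX))
  expect_length(m1, length(m0))
  expect_identical(m1[[1]]$start, m0[[1]]$start + nchar(prefix))
  expect_identical(m1[[1]]$bulge_positions,
                   m0[[1]]$bulge_positions + nchar(prefix))
})

test_that("matcher agrees with a brute-force HSL oracle on random transcripts", {
  set.seed(42)
  for (rep in 1:40) {
    seq <- random_rna(sample(30:200, 1))
    got <- match_motif(builtin_descriptor("hsl"), seq)
    got_starts <- vapply(got, function(m) m$start, integer(1))
    expect_identical(got_starts, hsl_oracle_starts(seq))
    for (m in got) {
      expect_true(validate_motif_match(m, builtin_descriptor("hsl"), seq))
    }
  }
  # and on a transcript guaranteed to contain one
  tr <- make_motif_transcript(flank5_len = 15, flank3_len = 15, seed = 9)
  expect_identical(hsl_oracle_starts(tr$seq), tr$motif$start)
})

test_that("IRE descriptor matches a canonical IRE stem-loop", {
  stem5 <- "GGGAC"
  seq <- paste0("UU", stem5, "CAGUGC", reverse_complement(stem5), "UU")
  m <- match_motif(builtin_descriptor("ire"), seq)
  expect_length(m, 1)
  expect_identical(m[[1]]$end - m[[1]]$start + 1L, 16L)
  expect_identical(m[[1]]$loop, c(8L, 13L))
  # H excludes G at the last loop position
  seqG <- sub("CAGUGC", "CAGUGG", seq)
  expect_length(match_motif(builtin_descriptor("ire"), seqG), 0)
})

test_that("descriptors round-trip through YAML config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "name: my_hsl",
    "anchors5: [1]",
    "elements:",
    "  - {kind: seq, iupac: AA}",
    "  - {kind: stem_open, tag: stem, min_len: 6, max_len: 6}",
    "  - {kind: seq, iupac: NNNN}",
    "  - {kind: stem_close, tag: stem}"), f)
  d <- read_descriptor(f)
  expect_identical(d$name, "my_hsl")
  m <- match_motif(d, WORKED_TX)
  expect_length(m, 1)
  expect_identical(m[[1]]$stem5, c(9L, 14L))
})

test_that("descriptor validation rejects malformed element lists", {
  expect_error(motif_descriptor("bad", list(seq_element("AA"))), "stem")
  expect_error(
    motif_descriptor("bad", list(stem_close("s"), stem_open("s", 6))),
    "precede")
  expect_error(
    motif_descriptor("bad", list(stem_open("s", 6), stem_close("t"))),
    "tag")
})
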