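worked_pt <- function() parse_dotbracket(WORKED_DB, 30, 14)

test_that("motif intactness counts stem pairs and trans-paired loop bases", {
  m <- worked_motif()
  mi <- motif_intact(worked_pt(), m)
  expect_true(mi$intact)
  expect_identical(mi$stem_present, 6L)

  all_dots <- parse_dotbracket(paste0(strrep(".", 30), "&", strrep(".", 14)),
                               30, 14)
  mi0 <- motif_intact(all_dots, m)
  expect_false(mi0$intact)
  expect_match(mi0$diagnostics, "0/6 stem pairs")

  # loop paired to the ncRNA: fails by default, passes when the flag is off
  partner <- worked_pt()$partner
  partner[c(15, 37)] <- c(37L, 15L)   # loop base 15 onto ncRNA-local 7
  pt_loop <- pair_table(partner, 30, 14)
  expect_false(motif_intact(pt_loop, m)$intact)
  th_relaxed <- thresholds(require_loop_unpaired_trans = FALSE)
  expect_true(motif_intact(pt_loop, m, th_relaxed)$intact)
})

test_that("splinting requires intermolecular pairs on both sides within reach", {
  m <- worked_motif()
  expect_true(splints_base(worked_pt(), m))

  # strip the 3' flank pairs -> one-sided binding is not splinting
  partner <- worked_pt()$partner
  for (i in 25:30) { partner[partner[i]] <- NA; partner[i] <- NA }
  expect_false(splints_base(pair_table(partner, 30, 14), m))

  # pairs beyond max_reach do not count
  expect_false(splints_base(worked_pt(), m, thresholds(max_reach = 2)))
  expect_error(annotate_junction(worked_pt(), m, thresholds(max_reach = 2)),
               "splint")
})

test_that("the worked structure annotates exactly as designed", {
  ann <- annotate_junction(worked_pt(), worked_motif())
  expect_identical(ann$purple5, 9L)
  expect_identical(ann$purple3, 24L)
  expect_identical(ann$blue5, 6L)
  expect_identical(ann$blue3, 25L)
  expect_identical(ann$orange5, 1L)
  expect_identical(ann$orange3, 30L)
  expect_identical(ann$green5, 9L)   # ncRNA-local
  expect_identical(ann$green3, 6L)
  expect_identical(ann$mJ5, 2L)
  expect_identical(ann$mJ3, 0L)
  expect_identical(ann$nJ, 2L)
  expect_identical(ann$h5_pairs, 6L)
  expect_identical(ann$h3_pairs, 6L)
  expect_identical(ann$flank5_paired_frac, 1)
  expect_identical(ann$flank3_paired_frac, 1)
  expect_equal(ann$ncrna_paired_frac, 12 / 14)
  expect_true(ann$bulge_unpaired)    # positions 7,8 unpaired
  expect_true(ann$arm_order_ok)
})

test_that("removing one outer flank pair moves orange but not the junctions", {
  partner <- worked_pt()$partner
  partner[c(1, partner[1])] <- NA    # delete pair (1,44)
  ann <- annotate_junction(pair_table(partner, 30, 14), worked_motif())
  expect_identical(ann$orange5, 2L)
  expect_identical(ann$h5_pairs, 5L)
  expect_identical(ann$mJ5, 2L)
  expect_identical(ann$mJ3, 0L)
  expect_identical(ann$nJ, 2L)
})

test_that("a single-pair flank helix is a degenerate but valid case", {
  partner <- worked_pt()$partner
  for (i in 1:5) { partner[partner[i]] <- NA; partner[i] <- NA }
  ann <- annotate_junction(pair_table(partner, 30, 14), worked_motif())
  expect_identical(ann$blue5, 6L)
  expect_identical(ann$orange5, 6L)
  expect_identical(ann$h5_span, 1L)
  expect_identical(ann$h5_pairs, 1L)
  expect_identical(ann$mJ5, 2L)
})

test_that("anchor finding agrees with the brute-force extremal oracle", {
  set.seed(303)
  m <- worked_motif()
  for (rep in 1:1000) {
    pt <- random_splint_pt(m)
    ann <- annotate_junction(pt, m)
    orc <- oracle_anchors(pt, m)
    for (f in names(orc)) expect_identical(ann[[f]], orc[[f]], info = f)
  }
})

test_that("classification matches the worked inducer and threshold arithmetic", {
  m <- worked_motif()
  res <- score_and_classify(worked_pt(), m)
  expect_identical(res$classification, "inducer")
  expect_true(res$pass)
  expect_length(res$fail_reasons, 0)

  res2 <- score_and_classify(worked_pt(), m, thresholds(max_nJ = 1))
  expect_identical(res2$classification, "none")
  expect_false(res2$pass)
  expect_identical(res2$fail_reasons, "nJ 2 > 1")
})

test_that("ablated motifs classify as repressors only with positive evidence", {
  m <- worked_motif()
  tx <- WORKED_TX
  abl <- make_negatives(tx, m, n = 1)$seqs[[1]]   # revcomp of loop+stem3
  # designed ablation: ncRNA hybridized across loop+stem3, no motif stem
  len_n <- nchar(abl)
  partner <- rep(NA_integer_, 30 + len_n)
  for (k in seq_len(len_n)) {
    i <- m$loop[1] + k - 1L
    p <- 30L + len_n - k + 1L
    partner[i] <- p; partner[p] <- i
  }
  pt <- pair_table(partner, 30, len_n)
  res <- score_and_classify(pt, m)
  expect_identical(res$classification, "repressor")
  expect_gte(res$ablation_pairs, 3)

  # motif absent with no trans pairs on it: none, not repressor
  empty <- pair_table(rep(NA_integer_, 44), 30, 14)
  res0 <- score_and_classify(empty, m)
  expect_identical(res0$classification, "none")
  expect_match(res0$fail_reasons, "motif-absent")
})

test_that("junction bases are unpaired to the other strand by construction", {
  set.seed(404)
  m <- worked_motif()
  for (rep in 1:200) {
    pt <- random_splint_pt(m)
    res <- score_and_classify(pt, m)
    if (res$classification != "inducer") next
    ann <- res$annotation
    mj <- c(if (ann$mJ5 > 0) seq.int(ann$blue5 + 1L, ann$purple5 - 1L),
            if (ann$mJ3 > 0) seq.int(ann$purple3 + 1L, ann$blue3 - 1L))
    for (i in mj) {
      p <- pt$partner[i]
      expect_true(is.na(p) || p <= pt$len_m)
    }
    if (ann$nJ > 0) {
      nj <- seq.int(min(ann$green5, ann$green3) + 1L,
                    max(ann$green5, ann$green3) - 1L)
      for (i in nj) {
        p <- pt$partner[pt$len_m + i]
        expect_true(is.na(p) || p > pt$len_m)
      }
    }
  }
})

test_that("relaxing any single threshold never breaks a passing candidate", {
  set.seed(505)
  m <- worked_motif()
  relax <- list(
    function(th) { th$max_mJ5 <- th$max_mJ5 + 3L; th },
    function(th) { th$max_mJ3 <- th$max_mJ3 + 3L; th },
    function(th) { th$max_nJ <- th$max_nJ + 3L; th },
    function(th) { th$min_helix_pairs <- th$min_helix_pairs - 2L; th },
    function(th) { th$min_flank_paired_frac <- th$min_flank_paired_frac - 0.2; th },
    function(th) { th$min_ncrna_paired_frac <- th$min_ncrna_paired_frac - 0.2; th },
    function(th) { th$min_stem_frac <- th$min_stem_frac - 0.5; th },
    function(th) { th$require_loop_unpaired_trans <- FALSE; th },
    function(th) { th$max_reach <- th$max_reach + 10L; th }
  )
  n_inducers <- 0L
  for (rep in 1:150) {
    pt <- random_splint_pt(m)
    base <- score_and_classify(pt, m)
    if (base$classification == "inducer") n_inducers <- n_inducers + 1L
    for (f in relax) {
      th2 <- f(thresholds())
      got <- score_and_classify(pt, m, th2)
      if (base$classification == "inducer") {
        expect_identical(got$classification, "inducer")
      }
    }
  }
  expect_gt(n_inducers, 0)   # the property was exercised
})
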