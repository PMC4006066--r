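# Seeded synthetic fixtures: transcripts with an embedded motif, designed
# splint ncRNAs (guaranteed positives with known junction geometry),
# ablator and dinucleotide-shuffled negative controls, plus ground truth.

RNA_BASES <- c("A", "C", "G", "U")
WC_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

#' Reverse complement of an RNA sequence
#'
#' Strict Watson-Crick (A-U, G-C); N maps to N.
#'
#' @param x RNA string.
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(x) {
  chars <- strsplit(normalize_rna(x), "")[[1]]
  paste(rev(unname(WC_COMPLEMENT[chars])), collapse = "")
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Longest antiparallel complementarity run between x and y:
# max t such that x[i+s] pairs y[j-s] for s = 0..t-1. Strict Watson-Crick
# by default: wobble-heavy runs carry too little pair weight to compete
# with designed helices, and counting them starves rejection sampling.
max_comp_run <- function(x, y, allow_wobble = FALSE) {
  a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    for (j in seq_len(nb)) {
      if (bases_pair(a[i], b[j], allow_wobble = allow_wobble)) {
        cur[j] <- if (j < nb) prev[j + 1L] + 1L else 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

sample_bases <- function(n, alphabet = RNA_BASES) {
  if (n == 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Fixture sequence-design policy: both flanks are drawn from the purine
# alphabet {G, A}. Purines cannot pair purines (neither Watson-Crick nor
# wobble), so the two flanks can form no cis helix with each other or
# with themselves, and each designed trans helix (whose arm is the
# pyrimidine-rich reverse complement of its flank) has a unique
# antiparallel register up to ties that the deterministic traceback
# resolves toward the design. The flank base adjacent to the bulge is
# fixed to A and the first 3'-flank base to G, which blocks the two
# boundary pair-swaps that would otherwise tie with the design (an
# adenosine of the bulge stealing the innermost 3'-arm U, or a 5'-flank G
# stealing the innermost 3'-arm partner). Loop and ncRNA-gap positions
# draw from {A, C}, which pairs with neither the purine flanks nor the AA
# bulge. Purine-run flanks around the stem-loop and a pyrimidine-rich
# small RNA mirror the natural histone stem-loop context.
FIXTURE_LOOP_ALPHABET <- c("A", "C")
FLANK5_ALPHABET <- c("G", "A")
FLANK3_ALPHABET <- c("G", "A")

# One concrete random instance of a descriptor. The 5' stem arm is drawn
# from purines with a G at its base (so its strand cannot pair the purine
# flanks or the bulge, and the bottom stem pair is a strong G:C);
# degenerate loop positions draw from the {A, C} loop alphabet with the
# base abutting the 3' stem fixed to A, so the loop cannot tie with the
# top stem pair.
instantiate_descriptor <- function(descriptor) {
  parts <- character(length(descriptor$elements))
  n_el <- length(descriptor$elements)
  for (i in seq_len(n_el)) {
    e <- descriptor$elements[[i]]
    parts[i] <- switch(e$kind,
      seq = {
        len <- e$min_len
        codes <- if (nchar(e$iupac) == 1L) rep(e$iupac, len)
                 else strsplit(e$iupac, "")[[1]][seq_len(len)]
        drawn <- vapply(codes, function(cd) {
          allowed <- setdiff(IUPAC_SETS[[cd]], "N")
          pref <- intersect(allowed, FIXTURE_LOOP_ALPHABET)
          if (length(pref)) sample(pref, 1L) else sample(allowed, 1L)
        }, character(1))
        if (i == descriptor$close_idx - 1L &&
            "A" %in% IUPAC_SETS[[codes[len]]]) {
          drawn[len] <- "A"
        }
        paste(drawn, collapse = "")
      },
      stem_open = {
        len <- e$min_len
        s <- sample(c("G", "A"), len, replace = TRUE)
        s[1L] <- "G"
        paste(s, collapse = "")
      },
      stem_close = reverse_complement(parts[descriptor$open_idx])
    )
  }
  paste(parts, collapse = "")
}

#' Generate a transcript with exactly one embedded motif
#'
#' Flanks are drawn from the purine alphabet \{G, A\} (purines cannot pair
#' purines, so the flanks are inert toward themselves, each other and the
#' purine 5' stem arm; see the design-policy notes in the package source),
#' degenerate loop positions from \{A, C\}. Rejection sampling verifies
#' that no antiparallel Watson-Crick complementarity run of 4 or more
#' bases exists between the two flanks, between either flank and the
#' motif instance, or within a flank; that the stem is not periodic
#' (periodic stems admit equal-weight shifted registers in the cofold);
#' and that the assembled transcript matches the descriptor exactly once
#' under [match_motif()].
#'
#' @param descriptor a [motif_descriptor()] (default built-in HSL).
#' @param flank5_len,flank3_len flank lengths (bases).
#' @param seed RNG seed; the same seed reproduces the same transcript.
#' @param id transcript id.
#' @param max_tries rejection-sampling cap; exceeding it is an error
#'   suggesting a different seed or longer flanks.
#' @return list with `id`, `seq` and `motif` (the `motif_match`).
#' @export
make_motif_transcript <- function(descriptor = builtin_descriptor("hsl"),
                                  flank5_len = 8L, flank3_len = 8L,
                                  seed = 1L, id = sprintf("tx_s%d", seed),
                                  max_tries = 500L) {
  stopifnot(flank5_len >= 0, flank3_len >= 0)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      core <- instantiate_descriptor(descriptor)
      f5 <- sample_bases(flank5_len, FLANK5_ALPHABET)
      if (flank5_len > 0) substr(f5, flank5_len, flank5_len) <- "A"
      f3 <- sample_bases(flank3_len, FLANK3_ALPHABET)
      if (flank3_len > 0) substr(f3, 1, 1) <- "G"
      if (flank5_len > 0 && flank3_len > 0 &&
          max_comp_run(f5, f3) >= 4L) next
      if (flank5_len > 0 &&
          (max_comp_run(f5, core) >= 4L || max_comp_run(f5, f5) >= 4L)) next
      if (flank3_len > 0 &&
          (max_comp_run(f3, core) >= 4L || max_comp_run(f3, f3) >= 4L)) next
      tseq <- paste0(f5, core, f3)
      matches <- match_motif(descriptor, tseq, id)
      if (length(matches) != 1L) next
      m <- matches[[1]]
      # reject stems that overlap themselves under small shifts: a
      # periodic stem admits equal-weight shifted registers
      s5 <- strsplit(substr(tseq, m$stem5[1], m$stem5[2]), "")[[1]]
      slen <- length(s5)
      periodic <- FALSE
      for (sh in 1:3) {
        ov <- slen - sh
        if (ov >= 3 && all(s5[seq_len(ov)] == s5[seq_len(ov) + sh])) {
          periodic <- TRUE
          break
        }
      }
      if (periodic) next
      return(list(id = id, seq = tseq, motif = m))
    }
    stop("could not generate a uniquely matching transcript in ", max_tries,
         " tries; use a different seed or longer flanks", call. = FALSE)
  })
}

#' Splint design parameters
#'
#' @param arm5_len,arm3_len lengths of the designed trans helices pairing
#'   the mRNA 5' flank (immediately 5' of the bulge) and 3' flank
#'   (immediately 3' of the motif).
#' @param gap designed ncRNA-side junction length (unpaired ncRNA bases
#'   between the arms; equals the truth `nJ`).
#' @param bulge designed mRNA bulge string (the bases between the 5' trans
#'   helix and the stem; equals the truth `mJ5`). Informational — the
#'   transcript's own bulge is used.
#' @param mismatch_rate per-arm-position probability of replacing the base
#'   with a non-complementary one; any rate > 0 voids the design truth.
#' @param seed RNG seed for gap bases and mismatches.
#' @param gap_seq optional explicit gap bases (overrides random draw).
#' @return a `splint_design` list.
#' @export
splint_design <- function(arm5_len, arm3_len, gap = 2L, bulge = "AA",
                          mismatch_rate = 0, seed = 1L, gap_seq = NULL) {
  stopifnot(arm5_len >= 1, arm3_len >= 1, gap >= 0,
            mismatch_rate >= 0, mismatch_rate <= 1)
  if (!is.null(gap_seq) && nchar(gap_seq) != gap) {
    stop("gap_seq length != gap", call. = FALSE)
  }
  structure(list(arm5_len = as.integer(arm5_len),
                 arm3_len = as.integer(arm3_len),
                 gap = as.integer(gap), bulge = bulge,
                 mismatch_rate = mismatch_rate, seed = as.integer(seed),
                 gap_seq = gap_seq),
            class = "splint_design")
}

#' Design a splint ncRNA for a motif-bearing transcript
#'
#' The ncRNA is, 5' to 3': the reverse complement of the `arm3_len`
#' transcript bases immediately 3' of the motif, then `gap` bases that
#' cannot pair with the mRNA bulge, then the reverse complement of the
#' `arm5_len` bases immediately 5' of the bulge. Pairing the arms to
#' their design targets together with the motif stem yields a valid
#' nested joint structure (see [designed_structure()]) whose annotation
#' is exactly: `mJ5` = bulge length, `mJ3` = 0, `nJ` = gap,
#' `h5_pairs` = `arm5_len`, `h3_pairs` = `arm3_len`.
#'
#' @param tseq transcript sequence.
#' @param motif its `motif_match`.
#' @param design a [splint_design()].
#' @param id ncRNA id.
#' @return list with `id`, `seq` and `truth` (a list of designed
#'   annotation values, or `NULL` when `mismatch_rate > 0`).
#' @export
make_splint <- function(tseq, motif, design, id = "splint") {
  stopifnot(inherits(design, "splint_design"))
  tseq <- normalize_rna(tseq)
  b0 <- if (length(motif$bulge_positions)) min(motif$bulge_positions)
        else motif$start
  if (b0 - design$arm5_len < 1L) {
    stop("5' flank too short for arm5_len = ", design$arm5_len, call. = FALSE)
  }
  if (motif$end + design$arm3_len > nchar(tseq)) {
    stop("3' flank too short for arm3_len = ", design$arm3_len, call. = FALSE)
  }
  bulge_chars <- strsplit(tseq, "")[[1]][motif$bulge_positions]
  with_seed(design$seed, {
    arm3 <- reverse_complement(
      substr(tseq, motif$end + 1L, motif$end + design$arm3_len))
    arm5 <- reverse_complement(
      substr(tseq, b0 - design$arm5_len, b0 - 1L))
    gap_seq <- design$gap_seq
    if (is.null(gap_seq)) {
      # gap bases may pair neither the bulge nor either flank, which the
      # cofold could otherwise reach without disturbing the designed helices
      tchars <- strsplit(tseq, "")[[1]]
      context <- unique(c(bulge_chars,
                          tchars[seq_len(b0 - 1L)],
                          if (motif$end < nchar(tseq))
                            tchars[(motif$end + 1L):nchar(tseq)]))
      # restrict further to the inert loop alphabet: G would reach the
      # stem3/loop pyrimidines in motif-open alternative structures
      ok <- FIXTURE_LOOP_ALPHABET[vapply(FIXTURE_LOOP_ALPHABET, function(bb) {
        !any(bases_pair(rep(bb, length(context)), context))
      }, logical(1))]
      if (!length(ok)) ok <- "A"
      gap_seq <- paste(sample(ok, design$gap, replace = TRUE), collapse = "")
    }
    seqs <- paste0(arm3, gap_seq, arm5)
    if (design$mismatch_rate > 0) {
      chars <- strsplit(seqs, "")[[1]]
      arm_idx <- c(seq_len(design$arm3_len),
                   design$arm3_len + design$gap + seq_len(design$arm5_len))
      hit <- arm_idx[stats::runif(length(arm_idx)) < design$mismatch_rate]
      for (i in hit) {
        target <- WC_COMPLEMENT[[chars[i]]]  # the base it was built to pair
        chars[i] <- sample(
          RNA_BASES[!vapply(RNA_BASES, bases_pair, logical(1), b = target)],
          1L)
      }
      seqs <- paste(chars, collapse = "")
    }
    truth <- if (design$mismatch_rate == 0) {
      list(mJ5 = motif$stem5[1] - b0, mJ3 = 0L, nJ = design$gap,
           h5_pairs = design$arm5_len, h3_pairs = design$arm3_len,
           bulge_unpaired = TRUE)
    } else NULL
    list(id = id, seq = seqs, truth = truth)
  })
}

#' Pair table of a designed splint structure
#'
#' Builds the structure the design intends — motif stem plus the two trans
#' helices at their design targets — directly, without folding. Used for
#' parameter-recovery tests of [annotate_junction()].
#'
#' @inheritParams make_splint
#' @param ncrna_seq the splint sequence from [make_splint()].
#' @return a [pair_table()].
#' @export
designed_structure <- function(tseq, motif, ncrna_seq, design) {
  len_m <- nchar(tseq); len_n <- nchar(ncrna_seq)
  b0 <- if (length(motif$bulge_positions)) min(motif$bulge_positions)
        else motif$start
  partner <- rep(NA_integer_, len_m + len_n)
  slen <- motif$stem5[2] - motif$stem5[1] + 1L
  for (k in seq_len(slen)) {
    i <- motif$stem5[1] + k - 1L; j <- motif$stem3[2] - k + 1L
    partner[i] <- j; partner[j] <- i
  }
  for (j in seq_len(design$arm3_len)) {
    i <- motif$end + j; p <- len_m + design$arm3_len + 1L - j
    partner[i] <- p; partner[p] <- i
  }
  for (j in seq_len(design$arm5_len)) {
    i <- b0 - j; p <- len_m + design$arm3_len + design$gap + j
    partner[i] <- p; partner[p] <- i
  }
  pair_table(partner, len_m, len_n)
}

#' Dinucleotide-preserving shuffle
#'
#' Altschul-Erickson shuffle: returns a sequence with identical
#' dinucleotide (and hence mononucleotide) counts, identical first and
#' last base, in random order otherwise.
#'
#' @param x RNA string.
#' @param seed RNG seed.
#' @return shuffled string.
#' @export
dinucleotide_shuffle <- function(x, seed = 1L) {
  chars <- strsplit(normalize_rna(x), "")[[1]]
  n <- length(chars)
  if (n <= 3L) return(x)
  with_seed(seed, {
    from <- chars[-n]; to <- chars[-1L]
    verts <- unique(chars)
    last <- chars[n]
    out_edges <- split(to, factor(from, levels = verts))
    repeat {
      last_edge <- vapply(verts, function(v) {
        es <- out_edges[[v]]
        if (v == last || length(es) == 0L) NA_character_
        else es[sample.int(length(es), 1L)]
      }, character(1))
      reaches <- vapply(verts, function(v) {
        if (v == last || is.na(last_edge[[v]])) return(TRUE)
        seen <- character(0); cur <- v
        while (!is.na(last_edge[[cur]]) && !(cur %in% seen) && cur != last) {
          seen <- c(seen, cur); cur <- last_edge[[cur]]
        }
        cur == last
      }, logical(1))
      if (all(reaches)) break
    }
    arranged <- lapply(stats::setNames(verts, verts), function(v) {
      es <- out_edges[[v]]
      le <- last_edge[[v]]
      if (is.na(le)) return(sample(es, length(es)))
      drop1 <- match(le, es)
      rest <- es[-drop1]
      c(sample(rest, length(rest)), le)
    })
    used <- stats::setNames(integer(length(verts)), verts)
    walk <- character(n); walk[1L] <- chars[1L]
    cur <- chars[1L]
    for (i in 2:n) {
      used[[cur]] <- used[[cur]] + 1L
      nxt <- arranged[[cur]][used[[cur]]]
      walk[i] <- nxt
      cur <- nxt
    }
    paste(walk, collapse = "")
  })
}

#' Negative-control ncRNAs for a motif
#'
#' Half the controls are *ablators* — reverse complements of the motif
#' loop + 3' stem (longer variants extend into the 5' stem) that
#' hybridize onto the conserved motif itself and are expected to classify
#' as repressors. The other half are dinucleotide-shuffled decoys of the
#' first ablator, expected to classify as none.
#'
#' @param tseq transcript sequence.
#' @param motif its `motif_match`.
#' @param n number of controls (ablators first, then decoys; `n = 2`
#'   gives one of each).
#' @param seed RNG seed.
#' @return list with `seqs` (named character vector) and `truth`
#'   (data frame of `ncrna_id`, `expected_class`).
#' @export
make_negatives <- function(tseq, motif, n = 2L, seed = 1L) {
  stopifnot(n >= 1)
  tseq <- normalize_rna(tseq)
  n_abl <- ceiling(n / 2); n_dec <- n - n_abl
  abl <- vapply(seq_len(n_abl), function(k) {
    from <- max(motif$stem5[1], motif$loop[1] - (k - 1L))
    reverse_complement(substr(tseq, from, motif$stem3[2]))
  }, character(1))
  names(abl) <- sprintf("ablator_%d", seq_len(n_abl))
  dec <- character(0)
  if (n_dec > 0) {
    dec <- vapply(seq_len(n_dec), function(k) {
      dinucleotide_shuffle(abl[[1L]], seed = seed + k)
    }, character(1))
    names(dec) <- sprintf("decoy_%d", seq_len(n_dec))
  }
  seqs <- c(abl, dec)
  list(seqs = seqs,
       truth = data.frame(
         ncrna_id = names(seqs),
         expected_class = c(rep("repressor", n_abl), rep("none", n_dec)),
         stringsAsFactors = FALSE))
}

#' Generate a full fixture set with ground truth
#'
#' `n` seeded designs: each gets a motif transcript (flanks sized to its
#' arms), a mismatch-free splint, one ablator and one dinucleotide-
#' shuffled decoy of the ablator (see [make_negatives()]). Truth rows
#' mirror the designed junction geometry. Optionally writes paired FASTA
#' files and a truth TSV.
#'
#' @param n number of designs.
#' @param seed master seed; all per-design seeds derive from it.
#' @param descriptor a [motif_descriptor()].
#' @param arm_range,gap_range integer ranges the designs draw from.
#' @param out_dir if non-`NULL`, write `transcripts.fa`, `ncrnas.fa` and
#'   `truth.tsv` there.
#' @return list with `transcripts`, `splints`, `decoys`, `ablators`
#'   (named character vectors), `designs` (list of per-design metadata)
#'   and `truth` (data frame).
#' @export
make_fixture_set <- function(n = 20L, seed = 1L,
                             descriptor = builtin_descriptor("hsl"),
                             arm_range = 4:10, gap_range = 0:6,
                             out_dir = NULL) {
  stopifnot(n >= 1)
  params <- with_seed(seed, {
    data.frame(
      arm5 = sample(arm_range, n, replace = TRUE),
      arm3 = sample(arm_range, n, replace = TRUE),
      gap = sample(gap_range, n, replace = TRUE),
      sub_seed = sample.int(1e7, n)
    )
  })
  transcripts <- character(0); splints <- character(0)
  decoys <- character(0); ablators <- character(0)
  designs <- vector("list", n)
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    p <- params[k, ]
    tid <- sprintf("tx%04d", k)
    tr <- make_motif_transcript(descriptor,
                                flank5_len = p$arm5,
                                flank3_len = p$arm3,
                                seed = p$sub_seed, id = tid)
    des <- splint_design(p$arm5, p$arm3, gap = p$gap, seed = p$sub_seed + 1L)
    sp <- make_splint(tr$seq, tr$motif, des, id = sprintf("splint%04d", k))
    neg <- make_negatives(tr$seq, tr$motif, n = 2L, seed = p$sub_seed + 2L)
    transcripts[[tid]] <- tr$seq
    splints[[sp$id]] <- sp$seq
    ablators[[sprintf("abl%04d", k)]] <- neg$seqs[[1L]]
    decoys[[sprintf("decoy%04d", k)]] <- neg$seqs[[2L]]
    designs[[k]] <- list(transcript = tr, splint = sp, design = des)
    truth[[k]] <- data.frame(
      transcript_id = tid, ncrna_id = sp$id,
      motif_start = tr$motif$start, motif_end = tr$motif$end,
      mJ5 = sp$truth$mJ5, mJ3 = sp$truth$mJ3, nJ = sp$truth$nJ,
      h5_pairs = sp$truth$h5_pairs, h3_pairs = sp$truth$h3_pairs,
      expected_class = "inducer", stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  out <- list(transcripts = transcripts, splints = splints,
              decoys = decoys, ablators = ablators,
              designs = designs, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_rna_fasta(transcripts, file.path(out_dir, "transcripts.fa"))
    write_rna_fasta(c(splints, ablators, decoys),
                    file.path(out_dir, "ncrnas.fa"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
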