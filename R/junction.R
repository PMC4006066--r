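# Trans three-way junction detection on a joint structure.
#
# Given the pair table of a cofold and the location of a stem-loop motif
# on the mRNA strand, decide whether (1) the motif stem is present as
# intramolecular pairs, (2) the ncRNA splints both flanks at the motif
# base, then annotate the anchor positions and segments from which the
# junction is scored:
#
#   purple5/purple3  bottom bases of the motif stem
#   blue5/blue3      first mRNA base paired to the ncRNA 5'/3' of the
#                    motif (nearest the motif base)
#   orange5/orange3  last such bases (farthest from the motif base)
#   green5/green3    ncRNA-local partners of blue5/blue3
#
# Segments between purple and blue anchors are the mRNA-side junction
# regions (mJ5, mJ3, in unpaired bases); the segment between the green
# anchors is the ncRNA-side junction (nJ); segments between blue and
# orange anchors are the extents of the two trans helices.

#' Detection thresholds
#'
#' Defaults are package policy, motivated by published geometries of cis
#' three-way junctions (small unpaired junction segments) and by general
#' hybridization quality (well-paired flank helices and ncRNA). All are
#' configurable.
#'
#' @param max_mJ5,max_mJ3,max_nJ maximum unpaired bases in each junction
#'   segment (default 8).
#' @param min_helix_pairs minimum intermolecular pairs per flank helix
#'   (default 4).
#' @param min_flank_paired_frac minimum fraction of mRNA bases paired
#'   within each flank helix extent (default 0.6).
#' @param min_ncrna_paired_frac minimum fraction of ncRNA bases
#'   intermolecularly paired (default 0.5).
#' @param min_stem_frac fraction of motif stem pairs that must be present
#'   for the motif to count as intact (default 1.0).
#' @param require_loop_unpaired_trans if `TRUE` (default) the motif loop
#'   may not pair with the ncRNA.
#' @param min_ablation_pairs minimum intermolecular pairs landing on the
#'   motif for a repressor verdict (default 3).
#' @param max_reach how far (in mRNA bases) from the motif base the
#'   splinting pairs may lie; defaults to 25, the default cofold window
#'   flank.
#' @return a `thresholds` object.
#' @export
thresholds <- function(max_mJ5 = 8L, max_mJ3 = 8L, max_nJ = 8L,
                       min_helix_pairs = 4L,
                       min_flank_paired_frac = 0.6,
                       min_ncrna_paired_frac = 0.5,
                       min_stem_frac = 1.0,
                       require_loop_unpaired_trans = TRUE,
                       min_ablation_pairs = 3L,
                       max_reach = 25L) {
  th <- list(max_mJ5 = as.integer(max_mJ5), max_mJ3 = as.integer(max_mJ3),
             max_nJ = as.integer(max_nJ),
             min_helix_pairs = as.integer(min_helix_pairs),
             min_flank_paired_frac = min_flank_paired_frac,
             min_ncrna_paired_frac = min_ncrna_paired_frac,
             min_stem_frac = min_stem_frac,
             require_loop_unpaired_trans = isTRUE(require_loop_unpaired_trans),
             min_ablation_pairs = as.integer(min_ablation_pairs),
             max_reach = as.integer(max_reach))
  nums <- unlist(th[c("max_mJ5", "max_mJ3", "max_nJ", "min_helix_pairs",
                      "min_ablation_pairs", "max_reach")])
  if (any(nums < 0)) stop("thresholds must be non-negative", call. = FALSE)
  fr <- unlist(th[c("min_flank_paired_frac", "min_ncrna_paired_frac",
                    "min_stem_frac")])
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]", call. = FALSE)
  structure(th, class = "sxrna_thresholds")
}

check_motif_in_pt <- function(pt, motif) {
  if (motif$start < 1L || motif$end > pt$len_m) {
    stop("motif span [", motif$start, ",", motif$end,
         "] outside the mRNA strand (len ", pt$len_m, ")", call. = FALSE)
  }
}

#' Is the motif stem present in a joint structure?
#'
#' The motif is intact when at least `min_stem_frac` of the stem pairs
#' implied by the match (stem5 position k with stem3 position
#' end - k + 1) are present as intramolecular pairs, and — when
#' `require_loop_unpaired_trans` — no loop position pairs with the ncRNA.
#'
#' @param pt a [pair_table()].
#' @param motif a `motif_match` in the mRNA-strand coordinates of `pt`.
#' @param th a [thresholds()] object.
#' @return list with `intact` flag, `stem_present`/`stem_total` counts and
#'   `loop_trans_paired` count (diagnostics).
#' @export
motif_intact <- function(pt, motif, th = thresholds()) {
  check_motif_in_pt(pt, motif)
  L <- motif$stem5[2] - motif$stem5[1] + 1L
  i <- motif$stem5[1] + seq_len(L) - 1L
  j <- motif$stem3[2] - seq_len(L) + 1L
  present <- sum(!is.na(pt$partner[i]) & pt$partner[i] == j)
  loop_pos <- if (motif$loop[2] >= motif$loop[1])
    seq.int(motif$loop[1], motif$loop[2]) else integer(0)
  lp <- pt$partner[loop_pos]
  loop_trans <- sum(!is.na(lp) & lp > pt$len_m)
  intact <- (present / L) >= th$min_stem_frac &&
    (!th$require_loop_unpaired_trans || loop_trans == 0L)
  list(intact = intact, stem_present = present, stem_total = L,
       loop_trans_paired = loop_trans,
       diagnostics = sprintf("%d/%d stem pairs, %d loop positions trans-paired",
                             present, L, loop_trans))
}

#' Does the ncRNA splint both flanks of the motif base?
#'
#' True when there is an intermolecular pair within `max_reach` mRNA bases
#' 5' of the bottom 5' stem base and another within `max_reach` bases 3'
#' of the bottom 3' stem base.
#'
#' @inheritParams motif_intact
#' @return logical flag.
#' @export
splints_base <- function(pt, motif, th = thresholds()) {
  check_motif_in_pt(pt, motif)
  ip <- inter_pairs(pt)
  purple5 <- motif$stem5[1]; purple3 <- motif$stem3[2]
  any(ip$mpos >= purple5 - th$max_reach & ip$mpos < purple5) &&
    any(ip$mpos > purple3 & ip$mpos <= purple3 + th$max_reach)
}

#' Annotate the anchors and segments of a trans three-way junction
#'
#' Precondition: [motif_intact()] and [splints_base()] both hold (checked;
#' violation is an error, never a silent `NULL`). Anchors follow the
#' extremal-pair definitions: blue anchors are the intermolecularly paired
#' mRNA positions nearest the motif base on each side, orange the
#' farthest; green anchors are the ncRNA-local partners of the blue
#' anchors.
#'
#' @inheritParams motif_intact
#' @return a `junction_annotation` list: anchors (`purple5`, `purple3`,
#'   `blue5`, `blue3`, `orange5`, `orange3`, `green5`, `green3`), segment
#'   lengths (`mJ5`, `mJ3`, `nJ`), helix measures (`h5_pairs`, `h3_pairs`,
#'   `h5_span`, `h3_span`), paired fractions (`flank5_paired_frac`,
#'   `flank3_paired_frac`, `ncrna_paired_frac`), the `bulge_unpaired` flag
#'   and the antiparallel `arm_order_ok` flag.
#' @export
annotate_junction <- function(pt, motif, th = thresholds()) {
  mi <- motif_intact(pt, motif, th)
  if (!mi$intact) {
    stop("annotate_junction precondition violated: motif not intact (",
         mi$diagnostics, ")", call. = FALSE)
  }
  if (!splints_base(pt, motif, th)) {
    stop("annotate_junction precondition violated: ncRNA does not splint ",
         "the motif base", call. = FALSE)
  }
  ip <- inter_pairs(pt)
  purple5 <- motif$stem5[1]; purple3 <- motif$stem3[2]
  side5 <- ip[ip$mpos < purple5, , drop = FALSE]
  side3 <- ip[ip$mpos > purple3, , drop = FALSE]
  blue5 <- max(side5$mpos); orange5 <- min(side5$mpos)
  blue3 <- min(side3$mpos); orange3 <- max(side3$mpos)
  green5 <- side5$npos[side5$mpos == blue5]
  green3 <- side3$npos[side3$mpos == blue3]
  h5 <- side5[side5$mpos >= orange5 & side5$mpos <= blue5, , drop = FALSE]
  h3 <- side3[side3$mpos >= blue3 & side3$mpos <= orange3, , drop = FALSE]
  h5_span <- blue5 - orange5 + 1L
  h3_span <- orange3 - blue3 + 1L
  bulge <- motif$bulge_positions
  bulge <- bulge[bulge >= 1L & bulge <= pt$len_m]  # clamped windows may cut it
  ann <- list(
    purple5 = purple5, purple3 = purple3,
    blue5 = blue5, blue3 = blue3,
    orange5 = orange5, orange3 = orange3,
    green5 = green5, green3 = green3,
    mJ5 = purple5 - blue5 - 1L,
    mJ3 = blue3 - purple3 - 1L,
    nJ = abs(green5 - green3) - 1L,
    h5_pairs = nrow(h5), h3_pairs = nrow(h3),
    h5_span = h5_span, h3_span = h3_span,
    flank5_paired_frac = nrow(h5) / h5_span,
    flank3_paired_frac = nrow(h3) / h3_span,
    ncrna_paired_frac = nrow(ip) / pt$len_n,
    bulge_unpaired = all(is.na(pt$partner[bulge])),
    # antiparallel splinting: the 5' flank helix must engage the ncRNA arm
    # distal (3') of the one engaged by the 3' flank helix, not interleave
    arm_order_ok = min(h5$npos) > max(h3$npos)
  )
  structure(ann, class = "junction_annotation")
}

#' @export
print.junction_annotation <- function(x, ...) {
  cat(sprintf("3WJ anchors: purple [%d,%d] blue [%d,%d] orange [%d,%d] green [%d,%d]\n",
              x$purple5, x$purple3, x$blue5, x$blue3, x$orange5, x$orange3,
              x$green5, x$green3))
  cat(sprintf("junctions mJ5=%d mJ3=%d nJ=%d; helices %d/%d pairs, flank fracs %.2f/%.2f, ncRNA frac %.2f\n",
              x$mJ5, x$mJ3, x$nJ, x$h5_pairs, x$h3_pairs,
              x$flank5_paired_frac, x$flank3_paired_frac, x$ncrna_paired_frac))
  invisible(x)
}

#' Score a joint structure and classify the interaction
#'
#' A candidate is an *inducer* when the motif is intact, the ncRNA splints
#' the motif base, the splint is antiparallel (5' flank helix on the ncRNA
#' 3' arm and vice versa), and every threshold is met. It is a
#' *repressor* when the motif is NOT intact and at least
#' `min_ablation_pairs` intermolecular pairs land on motif (stem or loop)
#' positions — positive evidence of ablation, not mere motif absence.
#' Otherwise the classification is `"none"`, with every failed condition
#' recorded in `fail_reasons`.
#'
#' @inheritParams motif_intact
#' @return list with `classification` (`"inducer"`, `"repressor"` or
#'   `"none"`), `pass` flag, `annotation` (a [annotate_junction()] result,
#'   or `NULL` when the junction preconditions fail), `ablation_pairs`
#'   count and `fail_reasons` character vector.
#' @export
score_and_classify <- function(pt, motif, th = thresholds()) {
  mi <- motif_intact(pt, motif, th)
  ip <- inter_pairs(pt)
  motif_pos <- c(seq.int(motif$stem5[1], motif$stem5[2]),
                 if (motif$loop[2] >= motif$loop[1])
                   seq.int(motif$loop[1], motif$loop[2]) else integer(0),
                 seq.int(motif$stem3[1], motif$stem3[2]))
  ablation <- sum(ip$mpos %in% motif_pos)
  fails <- character(0)
  ann <- NULL

  if (!mi$intact) {
    if (ablation >= th$min_ablation_pairs) {
      return(list(classification = "repressor", pass = FALSE,
                  annotation = NULL, ablation_pairs = ablation,
                  fail_reasons = sprintf("motif-absent (%s)", mi$diagnostics)))
    }
    return(list(classification = "none", pass = FALSE, annotation = NULL,
                ablation_pairs = ablation,
                fail_reasons = sprintf("motif-absent (%s)", mi$diagnostics)))
  }
  if (!splints_base(pt, motif, th)) {
    return(list(classification = "none", pass = FALSE, annotation = NULL,
                ablation_pairs = ablation, fail_reasons = "no-splint"))
  }
  ann <- annotate_junction(pt, motif, th)
  chk <- function(bad, fmt, ...) if (bad) fails <<- c(fails, sprintf(fmt, ...))
  chk(ann$mJ5 > th$max_mJ5, "mJ5 %d > %d", ann$mJ5, th$max_mJ5)
  chk(ann$mJ3 > th$max_mJ3, "mJ3 %d > %d", ann$mJ3, th$max_mJ3)
  chk(ann$nJ > th$max_nJ, "nJ %d > %d", ann$nJ, th$max_nJ)
  chk(ann$h5_pairs < th$min_helix_pairs, "h5_pairs %d < %d",
      ann$h5_pairs, th$min_helix_pairs)
  chk(ann$h3_pairs < th$min_helix_pairs, "h3_pairs %d < %d",
      ann$h3_pairs, th$min_helix_pairs)
  chk(ann$flank5_paired_frac < th$min_flank_paired_frac,
      "flank5_frac %.3f < %.2f", ann$flank5_paired_frac,
      th$min_flank_paired_frac)
  chk(ann$flank3_paired_frac < th$min_flank_paired_frac,
      "flank3_frac %.3f < %.2f", ann$flank3_paired_frac,
      th$min_flank_paired_frac)
  chk(ann$ncrna_paired_frac < th$min_ncrna_paired_frac,
      "ncrna_frac %.3f < %.2f", ann$ncrna_paired_frac,
      th$min_ncrna_paired_frac)
  chk(!ann$arm_order_ok, "arm-order")

  if (length(fails) == 0L) {
    list(classification = "inducer", pass = TRUE, annotation = ann,
         ablation_pairs = ablation, fail_reasons = character(0))
  } else {
    list(classification = "none", pass = FALSE, annotation = ann,
         ablation_pairs = ablation, fail_reasons = fails)
  }
}
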