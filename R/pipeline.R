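# Orchestration: motif search -> window extraction -> cofold vs. each
# ncRNA -> junction detection -> one report row per
# (transcript, motif, ncRNA, mode) combination.

#' Scan configuration
#'
#' @param window_flank bases of mRNA context taken on each side of the
#'   motif for windowed cofolding (default 25).
#' @param mode `"window"`, `"whole"` (full-message cofold) or `"both"`.
#' @param thresholds a [thresholds()] object.
#' @param backend `"reference"` or `"external"` (see [cofold()]).
#' @param descriptor a [motif_descriptor()] (default the built-in HSL).
#' @param max_whole_len transcripts longer than this are skipped in
#'   whole-message mode with a warning; cubic folding cost makes very long
#'   messages impractical (default 5000).
#' @param hits_only drop `classification == "none"` rows from the result.
#' @return a `scan_config` object.
#' @export
scan_config <- function(window_flank = 25L,
                        mode = c("window", "whole", "both"),
                        thresholds = sxrna::thresholds(),
                        backend = c("reference", "external"),
                        descriptor = builtin_descriptor("hsl"),
                        max_whole_len = 5000L,
                        hits_only = FALSE) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  window_flank <- as.integer(window_flank)
  if (window_flank < 0) stop("window_flank must be >= 0", call. = FALSE)
  structure(list(window_flank = window_flank, mode = mode,
                 thresholds = thresholds, backend = backend,
                 descriptor = descriptor,
                 max_whole_len = as.integer(max_whole_len),
                 hits_only = isTRUE(hits_only)),
            class = "scan_config")
}

#' Extract the cofold window around a motif
#'
#' The window spans `flank` bases on each side of the motif, silently
#' clamped at the transcript ends (the `clamped` flag records it).
#'
#' @param sequence transcript sequence.
#' @param motif a `motif_match` on that transcript.
#' @param flank bases of context on each side.
#' @return list with `seq` (the window), `start`/`end` (transcript
#'   coordinates of the window), `offset` (`start - 1`; add it to a
#'   window-local position to recover the transcript position) and
#'   `clamped`.
#' @export
extract_window <- function(sequence, motif, flank = 25L) {
  flank <- as.integer(flank)
  len <- nchar(sequence)
  if (motif$start < 1L || motif$end > len) {
    stop("motif [", motif$start, ",", motif$end,
         "] out of bounds for transcript of length ", len, call. = FALSE)
  }
  ws <- max(1L, motif$start - flank)
  we <- min(len, motif$end + flank)
  list(seq = substr(sequence, ws, we),
       start = ws, end = we, offset = ws - 1L,
       clamped = (motif$start - flank < 1L) || (motif$end + flank > len))
}

shift_motif <- function(motif, offset) {
  m <- motif
  m$start <- motif$start - offset
  m$end <- motif$end - offset
  m$stem5 <- motif$stem5 - offset
  m$loop <- motif$loop - offset
  m$stem3 <- motif$stem3 - offset
  m$bulge_positions <- motif$bulge_positions - offset
  m
}

empty_candidates <- function() {
  data.frame(
    transcript_id = character(0), ncrna_id = character(0),
    descriptor = character(0), mode = character(0),
    motif_start = integer(0), motif_end = integer(0),
    classification = character(0), pass = logical(0),
    mJ5 = integer(0), mJ3 = integer(0), nJ = integer(0),
    h5_pairs = integer(0), h3_pairs = integer(0),
    flank5_frac = numeric(0), flank3_frac = numeric(0),
    ncrna_frac = numeric(0), bulge_unpaired = logical(0),
    backend_score = numeric(0), fail_reasons = character(0),
    purple5 = integer(0), purple3 = integer(0),
    blue5 = integer(0), blue3 = integer(0),
    orange5 = integer(0), orange3 = integer(0),
    green5 = integer(0), green3 = integer(0),
    window_start = integer(0), window_end = integer(0),
    stringsAsFactors = FALSE
  )
}

candidate_row <- function(tid, nid, motif, mode, res, score, win) {
  ann <- res$annotation
  g <- function(f, default) if (is.null(ann)) default else ann[[f]]
  data.frame(
    transcript_id = tid, ncrna_id = nid,
    descriptor = motif$descriptor_name, mode = mode,
    motif_start = motif$start, motif_end = motif$end,
    classification = res$classification, pass = res$pass,
    mJ5 = g("mJ5", NA_integer_), mJ3 = g("mJ3", NA_integer_),
    nJ = g("nJ", NA_integer_),
    h5_pairs = g("h5_pairs", NA_integer_),
    h3_pairs = g("h3_pairs", NA_integer_),
    flank5_frac = g("flank5_paired_frac", NA_real_),
    flank3_frac = g("flank3_paired_frac", NA_real_),
    ncrna_frac = g("ncrna_paired_frac", NA_real_),
    bulge_unpaired = g("bulge_unpaired", NA),
    backend_score = score,
    fail_reasons = paste(res$fail_reasons, collapse = ";"),
    purple5 = g("purple5", NA_integer_), purple3 = g("purple3", NA_integer_),
    blue5 = g("blue5", NA_integer_), blue3 = g("blue3", NA_integer_),
    orange5 = g("orange5", NA_integer_), orange3 = g("orange3", NA_integer_),
    green5 = g("green5", NA_integer_), green3 = g("green3", NA_integer_),
    window_start = win$start, window_end = win$end,
    stringsAsFactors = FALSE
  )
}

#' Scan transcripts against a set of small RNAs
#'
#' For every transcript, motif match, ncRNA and requested mode: extract
#' the cofold input (motif window or whole message), cofold, map the
#' structure back to transcript coordinates, run junction detection and
#' classification, and emit one candidate row. Anchor coordinates in the
#' result are transcript coordinates (window bookkeeping is lossless).
#' Output order is deterministic: transcript id, motif start, ncRNA id,
#' mode.
#'
#' @param transcripts named character vector of transcript sequences (as
#'   from [read_rna_fasta()]).
#' @param smallrnas named character vector of small RNA sequences.
#' @param config a [scan_config()].
#' @param verbose log progress per transcript.
#' @return data frame of candidates; the report columns of
#'   [write_report()] plus anchor coordinates (`purple5` ... `green3`,
#'   `NA` when no junction was annotated) and the window span.
#' @export
scan_sxrna <- function(transcripts, smallrnas, config = scan_config(),
                       verbose = FALSE) {
  stopifnot(inherits(config, "scan_config"))
  if (length(transcripts) == 0) return(empty_candidates())
  if (is.null(names(transcripts)) || is.null(names(smallrnas)) &&
      length(smallrnas) > 0) {
    stop("transcripts and smallrnas must be named", call. = FALSE)
  }
  transcripts <- stats::setNames(normalize_rna(transcripts), names(transcripts))
  if (length(smallrnas)) {
    smallrnas <- stats::setNames(normalize_rna(smallrnas), names(smallrnas))
  }
  modes <- switch(config$mode, both = c("window", "whole"), config$mode)
  th <- config$thresholds
  rows <- list()
  any_motif <- FALSE

  for (tid in sort(names(transcripts))) {
    tseq <- transcripts[[tid]]
    matches <- match_motif(config$descriptor, tseq, tid)
    if (verbose) {
      message("scan: ", tid, " (", nchar(tseq), " nt): ",
              length(matches), " motif match(es)")
    }
    if (length(matches) == 0) next
    any_motif <- TRUE
    for (motif in matches) {
      for (mode in modes) {
        if (mode == "whole" && nchar(tseq) > config$max_whole_len) {
          warning("skipping whole-message fold of ", tid, " (",
                  nchar(tseq), " nt > max_whole_len)", call. = FALSE)
          next
        }
        win <- if (mode == "window") {
          extract_window(tseq, motif, config$window_flank)
        } else {
          list(seq = tseq, start = 1L, end = nchar(tseq), offset = 0L,
               clamped = FALSE)
        }
        local_motif <- shift_motif(motif, win$offset)
        for (nid in sort(names(smallrnas))) {
          js <- tryCatch(
            cofold(win$seq, smallrnas[[nid]], backend = config$backend),
            error = function(e) {
              stop("cofold failed for transcript ", tid, " x ncRNA ", nid,
                   ": ", conditionMessage(e), call. = FALSE)
            })
          pt <- as_pair_table(js)
          res <- score_and_classify(pt, local_motif, th)
          row <- candidate_row(tid, nid, motif, mode, res, js$score, win)
          # anchors back to transcript coordinates
          for (f in c("purple5", "purple3", "blue5", "blue3",
                      "orange5", "orange3")) {
            row[[f]] <- row[[f]] + win$offset
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  if (!any_motif) warning("no motif matches in any transcript", call. = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else empty_candidates()
  if (nrow(out)) {
    out <- out[order(out$transcript_id, out$motif_start, out$ncrna_id,
                     out$mode, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    if (config$hits_only) {
      out <- out[out$classification != "none", , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}
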