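# Structured stem-loop pattern matching.
#
# A descriptor is an ordered list of pattern elements: sequence elements
# (IUPAC codes, variable length), a stem opening and its closing element
# whose matched region must be reverse-complementary to the opening under
# the pairing rule (Watson-Crick, optionally G.U wobble, up to
# max_mismatch mispairs). Element indices listed in anchors5 mark
# must-stay-unpaired bulge positions (the adenosines at the 5' base of the
# histone stem-loop); their matched positions are reported per match but
# excluded from the motif span.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U", T = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("G", "C"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U", "N")
)

iupac_matches <- function(base, code) {
  allowed <- IUPAC_SETS[[code]]
  if (is.null(allowed)) stop("unknown IUPAC code: ", code, call. = FALSE)
  base %in% allowed
}

# N never pairs, even against N.
bases_pair <- function(a, b, allow_wobble = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  if (!allow_wobble) return(wc)
  wc | (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' Pattern elements for motif descriptors
#'
#' `seq_element()` matches a run of bases against IUPAC codes: either a
#' fixed-length pattern (`nchar(iupac) == min_len == max_len`) or a
#' single code repeated for any length in `[min_len, max_len]`.
#' `stem_open()`/`stem_close()` delimit a helix: the closing region must be
#' reverse-complementary to the opening region under Watson-Crick pairing
#' (plus G.U when `allow_wobble`), with at most `max_mismatch` mispairs.
#'
#' @param iupac IUPAC string.
#' @param min_len,max_len length bounds (bases).
#' @param tag string linking a `stem_close` to its `stem_open`.
#' @param allow_wobble allow G.U pairs in the stem.
#' @param max_mismatch tolerated mispaired stem positions.
#' @return a pattern element list.
#' @export
seq_element <- function(iupac, min_len = nchar(iupac), max_len = nchar(iupac)) {
  stopifnot(is.character(iupac), length(iupac) == 1L, nzchar(iupac))
  iupac <- toupper(iupac)
  if (min_len > max_len) stop("min_len > max_len", call. = FALSE)
  if (nchar(iupac) > 1 && (min_len != nchar(iupac) || max_len != nchar(iupac))) {
    stop("multi-code seq_element must have fixed length nchar(iupac)",
         call. = FALSE)
  }
  structure(list(kind = "seq", iupac = iupac,
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "sxrna_element")
}

#' @rdname seq_element
#' @export
stem_open <- function(tag, min_len, max_len = min_len,
                      allow_wobble = TRUE, max_mismatch = 0L) {
  if (min_len > max_len) stop("min_len > max_len", call. = FALSE)
  if (min_len < 1) stop("stem length must be >= 1", call. = FALSE)
  structure(list(kind = "stem_open", tag = tag,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 allow_wobble = isTRUE(allow_wobble),
                 max_mismatch = as.integer(max_mismatch)),
            class = "sxrna_element")
}

#' @rdname seq_element
#' @export
stem_close <- function(tag) {
  structure(list(kind = "stem_close", tag = tag), class = "sxrna_element")
}

#' Build a motif descriptor
#'
#' @param name descriptor name (reported per match).
#' @param elements ordered list of pattern elements (see [seq_element()]).
#'   Exactly one `stem_open`/`stem_close` pair is supported; the elements
#'   between them form the loop.
#' @param anchors5 integer indices of elements whose matched positions are
#'   required-unpaired bulges 5' of the stem (reported as
#'   `bulge_positions`, excluded from the motif span).
#' @return a `motif_descriptor` object.
#' @export
motif_descriptor <- function(name, elements, anchors5 = integer(0)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  kinds <- vapply(elements, function(e) e$kind, character(1))
  opens <- which(kinds == "stem_open")
  closes <- which(kinds == "stem_close")
  if (length(opens) != 1L || length(closes) != 1L) {
    stop("descriptor must contain exactly one stem_open/stem_close pair",
         call. = FALSE)
  }
  if (closes <= opens) stop("stem_close precedes stem_open", call. = FALSE)
  if (!identical(elements[[opens]]$tag, elements[[closes]]$tag)) {
    stop("stem_close tag does not reference the stem_open tag", call. = FALSE)
  }
  anchors5 <- as.integer(anchors5)
  if (any(anchors5 < 1 | anchors5 > length(elements)) ||
      any(kinds[anchors5] != "seq")) {
    stop("anchors5 must index seq elements", call. = FALSE)
  }
  if (any(anchors5 >= opens)) {
    stop("anchors5 elements must precede the stem", call. = FALSE)
  }
  structure(list(name = name, elements = elements, anchors5 = anchors5,
                 open_idx = opens, close_idx = closes),
            class = "motif_descriptor")
}

#' @export
print.motif_descriptor <- function(x, ...) {
  cat("Motif descriptor '", x$name, "' (", length(x$elements),
      " elements)\n", sep = "")
  for (i in seq_along(x$elements)) {
    e <- x$elements[[i]]
    lab <- switch(e$kind,
      seq = sprintf("seq %s [%d,%d]%s", e$iupac, e$min_len, e$max_len,
                    if (i %in% x$anchors5) " (5' bulge anchor)" else ""),
      stem_open = sprintf("stem_open '%s' [%d,%d] wobble=%s mismatch<=%d",
                          e$tag, e$min_len, e$max_len, e$allow_wobble,
                          e$max_mismatch),
      stem_close = sprintf("stem_close '%s'", e$tag))
    cat(sprintf("  %d. %s\n", i, lab))
  }
  invisible(x)
}

#' Built-in motif descriptors
#'
#' `"hsl"`: the histone stem-loop — an AA bulge (required-unpaired anchor)
#' followed by a 16-base stem-loop of a 6-bp stem (G.U allowed, no
#' mismatches) around a 4-nt loop. The conserved 16-base stem-loop length
#' is fixed; primary-sequence consensus letters are deliberately left to
#' user configuration rather than hard-coded.
#' `"ire"`: the iron-response element — a 5-bp upper stem around the
#' canonical CAGUGH loop.
#'
#' @param name `"hsl"` or `"ire"`.
#' @return a [motif_descriptor()].
#' @export
builtin_descriptor <- function(name) {
  switch(tolower(name),
    hsl = motif_descriptor("hsl", list(
      seq_element("AA", 2, 2),
      stem_open("stem", 6, 6, allow_wobble = TRUE, max_mismatch = 0L),
      seq_element("NNNN", 4, 4),
      stem_close("stem")
    ), anchors5 = 1L),
    ire = motif_descriptor("ire", list(
      stem_open("stem", 5, 5, allow_wobble = TRUE, max_mismatch = 0L),
      seq_element("CAGUGH", 6, 6),
      stem_close("stem")
    )),
    stop("unknown descriptor '", name, "'; available: hsl, ire",
         call. = FALSE)
  )
}

#' Read a motif descriptor from a YAML config file
#'
#' The config mirrors the descriptor fields:
#' ```yaml
#' name: my_hsl
#' anchors5: [1]
#' elements:
#'   - {kind: seq, iupac: AA}
#'   - {kind: stem_open, tag: stem, min_len: 6, max_len: 6,
#'      allow_wobble: true, max_mismatch: 0}
#'   - {kind: seq, iupac: NNNN}
#'   - {kind: stem_close, tag: stem}
#' ```
#'
#' @param path path to the YAML file.
#' @return a [motif_descriptor()].
#' @export
read_descriptor <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name) || is.null(cfg$elements)) {
    stop("descriptor config needs 'name' and 'elements'", call. = FALSE)
  }
  elements <- lapply(cfg$elements, function(e) {
    switch(e$kind,
      seq = seq_element(e$iupac,
                        e$min_len %||% nchar(e$iupac),
                        e$max_len %||% nchar(e$iupac)),
      stem_open = stem_open(e$tag, e$min_len, e$max_len %||% e$min_len,
                            e$allow_wobble %||% TRUE,
                            e$max_mismatch %||% 0L),
      stem_close = stem_close(e$tag),
      stop("unknown element kind: ", e$kind, call. = FALSE))
  })
  motif_descriptor(cfg$name, elements, as.integer(cfg$anchors5 %||% integer(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_motif_match <- function(transcript_id, descriptor, positions) {
  # positions: list of [start, end] per element (1-based inclusive)
  open_sp <- positions[[descriptor$open_idx]]
  close_sp <- positions[[descriptor$close_idx]]
  non_anchor <- setdiff(seq_along(positions), descriptor$anchors5)
  span_start <- min(vapply(positions[non_anchor], `[`, integer(1), 1L))
  span_end <- max(vapply(positions[non_anchor], `[`, integer(1), 2L))
  bulge <- unlist(lapply(descriptor$anchors5, function(i) {
    seq.int(positions[[i]][1], positions[[i]][2])
  }))
  structure(list(
    transcript_id = transcript_id,
    start = span_start, end = span_end,
    stem5 = open_sp,
    loop = c(open_sp[2] + 1L, close_sp[1] - 1L),
    stem3 = close_sp,
    bulge_positions = as.integer(bulge %||% integer(0)),
    descriptor_name = descriptor$name
  ), class = "motif_match")
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf(
    "Motif '%s' on %s: span [%d,%d] stem5 [%d,%d] loop [%d,%d] stem3 [%d,%d]",
    x$descriptor_name, x$transcript_id, x$start, x$end,
    x$stem5[1], x$stem5[2], x$loop[1], x$loop[2], x$stem3[1], x$stem3[2]))
  if (length(x$bulge_positions)) {
    cat(" bulge {", paste(x$bulge_positions, collapse = ","), "}", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Find all matches of a motif descriptor in a transcript
#'
#' Every start position and admissible element-length assignment is tried;
#' overlapping matches are all reported. The stem regions must be
#' reverse-complementary under the descriptor's pairing rule. Matches are
#' returned ordered by motif span start, then span length.
#'
#' @param descriptor a [motif_descriptor()].
#' @param sequence normalized RNA sequence (single string).
#' @param transcript_id id recorded in each match.
#' @return list of `motif_match` objects (empty list when there is no match).
#' @export
match_motif <- function(descriptor, sequence, transcript_id = "seq") {
  stopifnot(inherits(descriptor, "motif_descriptor"))
  chars <- strsplit(normalize_rna(sequence), "")[[1]]
  n <- length(chars)
  elements <- descriptor$elements
  matches <- list()

  seq_ok <- function(e, from, len) {
    if (len == 0L) return(TRUE)
    if (from + len - 1L > n) return(FALSE)
    codes <- if (nchar(e$iupac) == 1L) rep(e$iupac, len)
             else strsplit(e$iupac, "")[[1]][seq_len(len)]
    all(mapply(iupac_matches, chars[from:(from + len - 1L)], codes))
  }

  stem_ok <- function(open_sp, close_sp, e_open) {
    len <- open_sp[2] - open_sp[1] + 1L
    a <- chars[open_sp[1]:(open_sp[1] + len - 1L)]
    b <- chars[close_sp[2]:(close_sp[2] - len + 1L)]   # reversed
    mism <- sum(!bases_pair(a, b, e_open$allow_wobble))
    mism <= e_open$max_mismatch
  }

  recurse <- function(idx, pos, spans) {
    if (idx > length(elements)) {
      matches[[length(matches) + 1L]] <<-
        new_motif_match(transcript_id, descriptor, spans)
      return(invisible(NULL))
    }
    e <- elements[[idx]]
    if (e$kind == "stem_close") {
      open_sp <- spans[[descriptor$open_idx]]
      len <- open_sp[2] - open_sp[1] + 1L
      if (pos + len - 1L > n) return(invisible(NULL))
      close_sp <- c(pos, pos + len - 1L)
      if (stem_ok(open_sp, close_sp, elements[[descriptor$open_idx]])) {
        spans[[idx]] <- close_sp
        recurse(idx + 1L, pos + len, spans)
      }
      return(invisible(NULL))
    }
    for (len in e$min_len:e$max_len) {
      if (pos + len - 1L > n) break
      ok <- if (e$kind == "seq") seq_ok(e, pos, len) else TRUE
      if (ok) {
        spans[[idx]] <- c(pos, pos + len - 1L)
        recurse(idx + 1L, pos + len, spans)
      }
    }
    invisible(NULL)
  }

  min_total <- sum(vapply(elements, function(e) {
    if (e$kind == "stem_close") elements[[descriptor$open_idx]]$min_len
    else e$min_len
  }, numeric(1)))
  starts <- if (n >= min_total) seq_len(n - min_total + 1L) else integer(0)
  for (s in starts) recurse(1L, s, vector("list", length(elements)))

  if (length(matches)) {
    key_start <- vapply(matches, function(m) m$start, integer(1))
    key_len <- vapply(matches, function(m) m$end - m$start + 1L, integer(1))
    matches <- matches[order(key_start, key_len)]
  }
  matches
}

#' Re-check the internal invariants of a motif match
#'
#' Used in validation and property tests: sub-spans must tile the span,
#' stems must have equal length and be reverse-complementary under the
#' descriptor's pairing rule.
#'
#' @param match a `motif_match`.
#' @param descriptor the descriptor it came from.
#' @param sequence the transcript sequence.
#' @return `TRUE`, or an error describing the violated invariant.
#' @export
validate_motif_match <- function(match, descriptor, sequence) {
  chars <- strsplit(normalize_rna(sequence), "")[[1]]
  with(match, {
    stopifnot(
      stem5[2] + 1L == loop[1], loop[2] + 1L == stem3[1],
      stem5[2] - stem5[1] == stem3[2] - stem3[1],
      start <= stem5[1], end >= stem3[2]
    )
  })
  len <- match$stem5[2] - match$stem5[1] + 1L
  a <- chars[match$stem5[1]:match$stem5[2]]
  b <- chars[match$stem3[2]:match$stem3[1]]
  e_open <- descriptor$elements[[descriptor$open_idx]]
  mism <- sum(!bases_pair(a, b, e_open$allow_wobble))
  if (mism > e_open$max_mismatch) {
    stop("stem mismatch count ", mism, " exceeds max_mismatch")
  }
  TRUE
}
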