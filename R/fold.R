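# Joint secondary structure of an mRNA segment and one ncRNA.
#
# The two strands are concatenated; combined positions 1..len_m are the
# mRNA side, len_m+1..len_m+len_n the ncRNA side. Dot-bracket strings use
# the RNAcofold convention of a single "&" between the strands (the "&"
# occupies no position). A pair table maps each combined position to its
# partner (NA = unpaired).

#' Construct a pair table
#'
#' @param partner integer vector over combined positions; `NA` for
#'   unpaired, otherwise the 1-based combined partner position. Must be an
#'   involution with no self-pairing.
#' @param len_m,len_n strand lengths; `length(partner) == len_m + len_n`.
#' @return a `pair_table` object.
#' @export
pair_table <- function(partner, len_m, len_n) {
  partner <- as.integer(partner)
  len_m <- as.integer(len_m); len_n <- as.integer(len_n)
  L <- len_m + len_n
  if (length(partner) != L) {
    stop("partner vector length ", length(partner), " != len_m + len_n = ",
         L, call. = FALSE)
  }
  paired <- which(!is.na(partner))
  if (any(partner[paired] < 1 | partner[paired] > L)) {
    stop("partner position out of range", call. = FALSE)
  }
  if (any(partner[paired] == paired)) {
    stop("position paired with itself", call. = FALSE)
  }
  if (!identical(partner[partner[paired]], paired)) {
    stop("partner map is not an involution", call. = FALSE)
  }
  structure(list(partner = partner, len_m = len_m, len_n = len_n),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("Pair table: %d + %d nt, %d pairs (%d intermolecular)\n",
              x$len_m, x$len_n, sum(!is.na(x$partner)) / 2L,
              nrow(inter_pairs(x))))
  invisible(x)
}

#' Strand membership of combined positions
#'
#' @param pt a [pair_table()].
#' @param i combined positions.
#' @return `"m"` or `"n"` per position.
#' @export
strand_of <- function(pt, i) ifelse(i <= pt$len_m, "m", "n")

#' Convert a combined position to a strand-local one
#'
#' @param pt a [pair_table()].
#' @param i combined positions.
#' @return integer vector of strand-local positions (mRNA positions are
#'   unchanged; ncRNA positions are shifted by `len_m`).
#' @export
to_local <- function(pt, i) ifelse(i <= pt$len_m, i, i - pt$len_m)

#' Intermolecular pairs of a pair table
#'
#' @param pt a [pair_table()].
#' @return data frame with columns `mpos` (mRNA position) and `npos`
#'   (ncRNA-local position), one row per intermolecular pair.
#' @export
inter_pairs <- function(pt) {
  i <- which(!is.na(pt$partner))
  i <- i[i <= pt$len_m & pt$partner[i] > pt$len_m]
  data.frame(mpos = i, npos = pt$partner[i] - pt$len_m)
}

#' Parse a two-strand dot-bracket string
#'
#' Stack-based matching of `(` with `)` across the combined sequence; the
#' single `&` separates the strands and consumes no position. Only one
#' bracket family is supported, so crossing (pseudoknotted) pairings are
#' not representable.
#'
#' @param db dot-bracket string over `(`, `)`, `.` with one `&`.
#' @param len_m,len_n expected strand lengths.
#' @return a [pair_table()].
#' @export
parse_dotbracket <- function(db, len_m, len_n) {
  stopifnot(is.character(db), length(db) == 1L)
  chars <- strsplit(db, "")[[1]]
  if (sum(chars == "&") != 1L) {
    stop("dot-bracket must contain exactly one '&'", call. = FALSE)
  }
  chars <- chars[chars != "&"]
  amp_at <- regexpr("&", db, fixed = TRUE)[1]
  if (amp_at - 1L != len_m) {
    stop("'&' at position ", amp_at, " but len_m = ", len_m, call. = FALSE)
  }
  L <- len_m + len_n
  if (length(chars) != L) {
    stop("dot-bracket length ", length(chars),
         " != len_m + len_n = ", L, call. = FALSE)
  }
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad)) {
    stop("invalid dot-bracket character '", chars[bad[1]], "' at position ",
         bad[1], call. = FALSE)
  }
  partner <- rep(NA_integer_, L)
  stack <- integer(0)
  for (i in seq_len(L)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) {
        stop("unbalanced ')' at position ", i, call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i
      partner[i] <- j
    }
  }
  if (length(stack)) {
    stop("unbalanced '(' at position ", stack[length(stack)], call. = FALSE)
  }
  pair_table(partner, len_m, len_n)
}

#' Render a pair table as a dot-bracket string
#'
#' Inverse of [parse_dotbracket()]. Errors if the pairing is crossing
#' (not nested), since a single bracket family cannot express it.
#'
#' @param pt a [pair_table()].
#' @return dot-bracket string with `&` between the strands.
#' @export
render_dotbracket <- function(pt) {
  partner <- pt$partner
  L <- length(partner)
  out <- rep(".", L)
  opens <- which(!is.na(partner) & partner > seq_len(L))
  for (i in opens) {
    j <- partner[i]
    inside <- partner[(i + 1L):(j - 1L)]
    inside <- inside[!is.na(inside)]
    if (length(inside) && any(inside < i | inside > j)) {
      stop("crossing pairs cannot be rendered in dot-bracket", call. = FALSE)
    }
    out[i] <- "("
    out[j] <- ")"
  }
  paste0(paste(out[seq_len(pt$len_m)], collapse = ""), "&",
         paste(out[pt$len_m + seq_len(pt$len_n)], collapse = ""))
}

new_joint_structure <- function(seq_m, seq_n, dotbracket, score) {
  structure(list(seq_m = seq_m, seq_n = seq_n,
                 dotbracket = dotbracket, score = score),
            class = "joint_structure")
}

#' @export
print.joint_structure <- function(x, ...) {
  cat(x$seq_m, "&", x$seq_n, "\n", sep = "")
  cat(x$dotbracket, sprintf(" (score %.2f)\n", x$score), sep = "")
  invisible(x)
}

#' Pair table of a joint structure
#'
#' @param x a `joint_structure`.
#' @return a [pair_table()].
#' @export
as_pair_table <- function(x) {
  stopifnot(inherits(x, "joint_structure"))
  parse_dotbracket(x$dotbracket, nchar(x$seq_m), nchar(x$seq_n))
}

#' Cofold an mRNA segment with one ncRNA
#'
#' The reference backend maximizes total base-pair weight (G:C = 3,
#' A:U = 2, G:U = 1) by dynamic programming over the concatenated
#' sequence. Intermolecular pairs are permitted; intramolecular hairpin
#' loops must span at least 3 unpaired bases, with no such constraint
#' across the strand break; N never pairs. Tie-breaking among co-optimal
#' structures is deterministic: each position pairs with the smallest
#' partner achieving the optimum and is left unpaired only when no pairing
#' does, so output is bit-reproducible and co-optimal helices stay flush
#' against enclosing stems. The score is the total pair weight
#' (dimensionless).
#'
#' The external backend shells out to ViennaRNA's `RNAcofold` and reports
#' its minimum free energy (kcal/mol) as the score; it errors if the
#' executable is not on the PATH (no silent fallback).
#'
#' @param seq_m,seq_n non-empty RNA sequences (normalized internally).
#' @param backend `"reference"` or `"external"`.
#' @return a `joint_structure` with fields `seq_m`, `seq_n`, `dotbracket`
#'   (with `&` separator) and `score`.
#' @examples
#' cofold("GGGG", "CCCC")$dotbracket   # "((((&))))"
#' @export
cofold <- function(seq_m, seq_n, backend = c("reference", "external")) {
  backend <- match.arg(backend)
  seq_m <- normalize_rna(seq_m); seq_n <- normalize_rna(seq_n)
  if (!nzchar(seq_m) || !nzchar(seq_n)) {
    stop("cofold requires non-empty sequences", call. = FALSE)
  }
  if (backend == "reference") {
    res <- .cofold_dp(paste0(seq_m, seq_n), nchar(seq_m))
    partner <- res$partner
    partner[partner == 0L] <- NA_integer_
    pt <- pair_table(partner, nchar(seq_m), nchar(seq_n))
    new_joint_structure(seq_m, seq_n, render_dotbracket(pt),
                        as.numeric(res$score))
  } else {
    cofold_external(seq_m, seq_n)
  }
}

cofold_external <- function(seq_m, seq_n) {
  exe <- Sys.which("RNAcofold")
  if (!nzchar(exe)) {
    stop("external backend unavailable: RNAcofold not found on PATH",
         call. = FALSE)
  }
  out <- system2(exe, c("--noPS"), input = paste0(seq_m, "&", seq_n),
                 stdout = TRUE, stderr = FALSE)
  if (length(out) < 2) {
    stop("external backend failed: unexpected RNAcofold output", call. = FALSE)
  }
  m <- regmatches(out[2], regexec("^([().&]+)\\s+\\(\\s*(-?[0-9.]+)\\)", out[2]))[[1]]
  if (length(m) != 3) {
    stop("external backend failed: cannot parse '", out[2], "'", call. = FALSE)
  }
  new_joint_structure(seq_m, seq_n, m[2], as.numeric(m[3]))
}
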