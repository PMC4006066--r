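#' @useDynLib sxrna, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Columns of the candidate report, in output order.
REPORT_COLUMNS <- c(
  "transcript_id", "ncrna_id", "descriptor", "mode",
  "motif_start", "motif_end", "classification", "pass",
  "mJ5", "mJ3", "nJ", "h5_pairs", "h3_pairs",
  "flank5_frac", "flank3_frac", "ncrna_frac",
  "bulge_unpaired", "backend_score", "fail_reasons"
)

#' Normalize an RNA sequence
#'
#' Uppercases and converts T to U. The result must contain only A, C, G, U
#' or N; any other character is an error. Normalization is idempotent.
#'
#' @param x character vector of sequences.
#' @return character vector of normalized sequences.
#' @examples
#' normalize_rna("acgt")   # "ACGU"
#' @export
normalize_rna <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(gsub("[ACGUN]", "", out[bad]), "")))
    stop("sequence contains non-RNA characters: ",
         paste(chars, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read transcript or small RNA sequences from FASTA
#'
#' Records are normalized to the RNA alphabet (T to U, uppercase). Record
#' order is preserved. Duplicate ids are rejected. DNA-alphabet input
#' (e.g. RefSeq transcript dumps) and miRBase-style U-alphabet input are
#' both accepted.
#'
#' @param path path to a FASTA file.
#' @param kind `"transcript"` (N allowed, zero-length allowed) or
#'   `"smallrna"` (length >= 1 required).
#' @return named character vector of normalized sequences; names are the
#'   FASTA ids (first whitespace-delimited token of each header). An empty
#'   file yields an empty vector.
#' @export
read_rna_fasta <- function(path, kind = c("transcript", "smallrna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("empty record id in ", path, call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- normalize_rna(as.character(set))
  if (kind == "smallrna" && any(nchar(seqs) < 1)) {
    stop("zero-length small RNA record in ", path, call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (names are record ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Write a candidate report as TSV
#'
#' One row per candidate with the fixed column set used throughout the
#' package. Rows are sorted by transcript id, motif start, ncRNA id and
#' mode so reruns are byte-identical.
#'
#' @param candidates data frame of candidates as returned by [scan_sxrna()].
#' @param path output path.
#' @param hits_only drop rows with classification `"none"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(candidates, path, hits_only = FALSE) {
  df <- as.data.frame(candidates, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REPORT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("candidate table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, REPORT_COLUMNS, drop = FALSE]
  if (hits_only && nrow(df)) df <- df[df$classification != "none", , drop = FALSE]
  if (nrow(df)) {
    ord <- order(df$transcript_id, df$motif_start, df$ncrna_id, df$mode,
                 method = "radix")
    df <- df[ord, , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Export motif matches as GFF3
#'
#' Each match becomes a `stem_loop` feature with `five_prime_stem`, `loop`
#' and `three_prime_stem` children linked by `Parent`. Coordinates are
#' 1-based inclusive per the GFF3 standard (the package convention, so no
#' conversion is involved).
#'
#' @param matches list of motif matches from [match_motif()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_gff3 <- function(matches, path) {
  if (length(matches) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rows <- lapply(seq_along(matches), function(k) {
    m <- matches[[k]]
    id <- sprintf("stem_loop_%s_%d", m$transcript_id, m$start)
    data.frame(
      seqid = m$transcript_id,
      start = c(m$start, m$stem5[1], m$loop[1], m$stem3[1]),
      end   = c(m$end, m$stem5[2], m$loop[2], m$stem3[2]),
      type  = c("stem_loop", "five_prime_stem", "loop", "three_prime_stem"),
      ID    = c(id, paste0(id, c(".stem5", ".loop", ".stem3"))),
      Parent = c(NA, id, id, id),
      descriptor = m$descriptor_name,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqid,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = "+",
    type = tab$type,
    ID = tab$ID,
    Parent = ifelse(is.na(tab$Parent), "", tab$Parent),
    descriptor = tab$descriptor
  )
  S4Vectors::mcols(gr)$Parent[!nzchar(S4Vectors::mcols(gr)$Parent)] <- NA_character_
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
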