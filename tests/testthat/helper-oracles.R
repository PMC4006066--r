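# Independent oracles used across the suite.

# The canonical worked example: 30-nt transcript with one HSL
# (bulge at 7,8; stem5 9..14; loop 15..18; stem3 19..24, 1-based) and its
# designed 14-nt splint; joint dot-bracket of the designed structure.
WORKED_TX <- "GAGAGAAAGGCUCUUUUCAGAGCCCACACC"
WORKED_NC <- "GGUGUGAAUCUCUC"
WORKED_DB <- "((((((..((((((....))))))((((((&))))))..))))))"

worked_motif <- function() {
  m <- match_motif(builtin_descriptor("hsl"), WORKED_TX, "tx")
  stopifnot(length(m) == 1L)
  m[[1]]
}

# --- folding oracle -------------------------------------------------------
# Exhaustive maximum over all valid nested structures of the concatenated
# sequence, by memoized interval enumeration. Written independently of the
# package's C++ dynamic program (R closure, explicit hash-map memo).
oracle_pair_weight <- function(a, b) {
  key <- paste0(a, b)
  w <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)
  unname(ifelse(is.na(w[key]), 0, w[key]))
}

oracle_cofold_score <- function(seq_m, seq_n) {
  chars <- strsplit(paste0(seq_m, seq_n), "")[[1]]
  len_m <- nchar(seq_m)
  L <- length(chars)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  admissible <- function(i, j) {
    w <- oracle_pair_weight(chars[i], chars[j])
    if (w == 0) return(0)
    if (((i <= len_m) == (j <= len_m)) && (j - i - 1) < 3) return(0)
    w
  }
  best <- function(i, j) {
    if (i >= j) return(0)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- best(i + 1, j)
    for (k in (i + 1):j) {
      w <- admissible(i, k)
      if (w > 0) {
        res <- max(res, w + best(i + 1, k - 1) + best(k + 1, j))
      }
    }
    memo[[key]] <- res
    res
  }
  best(1, L)
}

# Validity + achieved score of a joint_structure under the reference rules.
check_structure_valid <- function(js) {
  pt <- as_pair_table(js)
  chars <- strsplit(paste0(js$seq_m, js$seq_n), "")[[1]]
  len_m <- nchar(js$seq_m)
  total <- 0
  paired <- which(!is.na(pt$partner) & pt$partner > seq_along(pt$partner))
  for (i in paired) {
    j <- pt$partner[i]
    w <- oracle_pair_weight(chars[i], chars[j])
    if (w == 0) stop("non-complementary pair (", i, ",", j, ")")
    if (((i <= len_m) == (j <= len_m)) && (j - i - 1) < 3) {
      stop("hairpin loop < 3 at (", i, ",", j, ")")
    }
    total <- total + w
  }
  total
}

# --- anchor oracle --------------------------------------------------------
# Brute-force anchors by the stated extremal definitions: enumerate all
# intermolecular pairs, take extrema on each side of the motif base.
oracle_anchors <- function(pt, motif) {
  purple5 <- motif$stem5[1]; purple3 <- motif$stem3[2]
  m <- integer(0); nn <- integer(0)
  for (i in seq_len(pt$len_m)) {
    p <- pt$partner[i]
    if (!is.na(p) && p > pt$len_m) {
      m <- c(m, i); nn <- c(nn, p - pt$len_m)
    }
  }
  s5 <- m[m < purple5]; s3 <- m[m > purple3]
  blue5 <- max(s5); orange5 <- min(s5)
  blue3 <- min(s3); orange3 <- max(s3)
  green5 <- nn[m == blue5]; green3 <- nn[m == blue3]
  list(purple5 = purple5, purple3 = purple3,
       blue5 = blue5, blue3 = blue3, orange5 = orange5, orange3 = orange3,
       green5 = green5, green3 = green3,
       mJ5 = purple5 - blue5 - 1L, mJ3 = blue3 - purple3 - 1L,
       nJ = abs(green5 - green3) - 1L,
       h5_pairs = sum(m >= orange5 & m <= blue5),
       h3_pairs = sum(m >= blue3 & m <= orange3))
}

# Random pair table around the worked motif geometry: always includes the
# six stem pairs; random subsets of flank positions pair the ncRNA (5'
# flank onto the ncRNA tail, 3' flank onto the head, orders reversed so
# the table stays a valid antiparallel splint).
random_splint_pt <- function(motif, len_m = 30L, len_n = 14L) {
  partner <- rep(NA_integer_, len_m + len_n)
  slen <- motif$stem5[2] - motif$stem5[1] + 1L
  for (k in seq_len(slen)) {
    i <- motif$stem5[1] + k - 1L; j <- motif$stem3[2] - k + 1L
    partner[i] <- j; partner[j] <- i
  }
  f5 <- seq_len(motif$stem5[1] - 3L)             # leave the bulge out
  f3 <- seq.int(motif$stem3[2] + 1L, len_m)
  a5 <- sort(sample(f5, sample(seq_along(f5), 1)))
  a3 <- sort(sample(f3, sample(seq_along(f3), 1)))
  stopifnot(length(a5) + length(a3) <= len_n)
  # 3' flank pairs the ncRNA head, 5' flank the tail, both antiparallel
  p3 <- rev(seq_len(length(a3)))
  p5 <- len_n - seq_along(a5) + 1L
  for (t in seq_along(a3)) {
    partner[a3[t]] <- len_m + p3[t]; partner[len_m + p3[t]] <- a3[t]
  }
  for (t in seq_along(a5)) {
    partner[a5[t]] <- len_m + p5[t]; partner[len_m + p5[t]] <- a5[t]
  }
  pair_table(partner, len_m, len_n)
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

dinuc_counts <- function(x) {
  ch <- strsplit(x, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}
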