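# Positional base-composition matrices, first-base-by-length preferences,
# and the ping-pong 5'-overlap signature.

# Normalize (seqs, counts) input: seqs may be a character vector or a read
# data.frame carrying sequence + count columns.
seqs_counts <- function(seqs, counts = NULL) {
  if (is.data.frame(seqs)) {
    r <- as_srna_reads(seqs)
    list(seqs = r$sequence, counts = as.numeric(r$count))
  } else {
    s <- norm_dna(seqs)
    if (is.null(counts)) counts <- rep(1, length(s))
    stop_if(length(counts) != length(s),
            "counts must have one entry per sequence")
    list(seqs = s, counts = as.numeric(counts))
  }
}

#' Count-weighted positional base frequencies
#'
#' Base composition at 5'->3' positions 1..k; shorter sequences contribute
#' only to the positions they cover, and positions with no coverage are
#' dropped. Bases are reported in the RNA alphabet (U, A, G, C).
#'
#' @param seqs Character vector of sequences, or a read data.frame
#'   (sequence + count columns).
#' @param counts Optional copy numbers (default 1 per sequence).
#' @param k Number of positions (>= 1).
#' @return Matrix of class `base_matrix` (rows = covered positions, columns
#'   U/A/G/C); each row sums to 1. Attribute `coverage` holds the
#'   count-weighted number of sequences covering each position.
#' @examples
#' positional_base_frequencies(c("TAAA", "TGGG"), k = 2)
#' @export
positional_base_frequencies <- function(seqs, counts = NULL, k) {
  stop_if(k < 1, "k must be >= 1")
  x <- seqs_counts(seqs, counts)
  stop_if(length(x$seqs) == 0L, "no sequences given")
  bases <- c("T", "A", "G", "C")
  freq <- matrix(0, nrow = k, ncol = 4L,
                 dimnames = list(seq_len(k), c("U", "A", "G", "C")))
  coverage <- numeric(k)
  for (p in seq_len(k)) {
    b <- substring(x$seqs, p, p)
    has <- b != ""
    if (!any(has)) next
    w <- tapply(x$counts[has], factor(b[has], levels = bases), sum)
    w[is.na(w)] <- 0
    coverage[p] <- sum(w)
    if (coverage[p] > 0) freq[p, ] <- w / coverage[p]
  }
  keep <- coverage > 0
  structure(freq[keep, , drop = FALSE], coverage = coverage[keep],
            class = c("base_matrix", "matrix"))
}

#' Per-position enrichment of one base over its sequence-wide frequency
#'
#' `enrichment(p) = freq(base at position p) / overall freq(base)`, where
#' the overall frequency is count-weighted across every position of every
#' sequence. Ties in the argmax break to the smallest position.
#'
#' @inheritParams positional_base_frequencies
#' @param base One of "A", "U", "G", "C" (T accepted as U).
#' @return List with `enrichment` (named numeric over covered positions)
#'   and `argmax` (integer position).
#' @examples
#' position_enrichment("GGGGGGGGGA", base = "A", k = 10)$argmax
#' @export
position_enrichment <- function(seqs, counts = NULL, base, k) {
  stop_if(k < 1, "k must be >= 1")
  base <- toupper(base)
  if (base == "T") base <- "U"
  stop_if(!base %in% c("A", "U", "G", "C"), "base must be one of A, U, G, C")
  x <- seqs_counts(seqs, counts)
  dna_base <- if (base == "U") "T" else base
  per_seq <- vapply(strsplit(x$seqs, ""), function(ch) sum(ch == dna_base),
                    numeric(1))
  overall <- sum(per_seq * x$counts) / sum(nchar(x$seqs) * x$counts)
  stop_if(overall == 0, "base %s does not occur in the sequences", base)
  pm <- positional_base_frequencies(x$seqs, x$counts, k)
  enr <- pm[, base] / overall
  argmax <- as.integer(names(enr)[which.max(enr)])  # which.max: first max
  list(enrichment = enr, argmax = argmax)
}

#' First-base preference by read length
#'
#' @inheritParams positional_base_frequencies
#' @return Matrix (rows = observed lengths, columns U/A/G/C) of
#'   count-weighted first-base fractions; each row sums to 1.
#' @export
first_base_by_length <- function(seqs, counts = NULL) {
  x <- seqs_counts(seqs, counts)
  stop_if(length(x$seqs) == 0L, "no sequences given")
  lens <- nchar(x$seqs)
  fb <- factor(substring(x$seqs, 1L, 1L), levels = c("T", "A", "G", "C"))
  tab <- tapply(x$counts, list(lens, fb), sum)
  tab[is.na(tab)] <- 0
  colnames(tab) <- c("U", "A", "G", "C")
  sweep(tab, 1, rowSums(tab), "/")
}

#' Ping-pong 5'-overlap profile and enrichment statistic
#'
#' For every plus-strand read (5' end at `a`) and minus-strand read (5' end
#' at `b`, i.e. `end - 1`) on the same chromosome, the 5'-5' overlap is
#' `o = b - a + 1`; pairs with `1 <= o <= 20` are tallied with weight
#' `count_plus * count_minus`. The enrichment statistic
#' `z10 = (c10 - mean(c_o, o != 10)) / sd(c_o, o != 10)` (sample sd)
#' standardizes the 10-nt bin against the other bins; `z10 = 0` when the sd
#' is 0 (e.g. no pairs at all). Ping-pong amplification leaves an excess of
#' exactly-10-nt overlaps, so large `z10` indicates an active cycle; this
#' package treats `z10 > 1.96` as a detected signature.
#'
#' @param alignments Alignment data.frame (id, chrom, start, end, strand,
#'   count) with 0-based half-open coordinates.
#' @param max_overlap Largest overlap tallied (default 20).
#' @return Object of class `pingpong_profile`: list with `overlap_counts`
#'   (named numeric over 1..max_overlap) and `z10`.
#' @examples
#' aln <- data.frame(id = c("p", "m"), chrom = "chr1",
#'                   start = c(100, 91), end = c(130, 110),
#'                   strand = c("+", "-"), count = 1)
#' ping_pong_profile(aln)$overlap_counts[["10"]]
#' @export
ping_pong_profile <- function(alignments, max_overlap = 20L) {
  counts <- setNames(numeric(max_overlap), seq_len(max_overlap))
  if (!is.null(alignments) && nrow(alignments) > 0L) {
    if (is.null(alignments$count)) alignments$count <- 1L
    fp <- five_prime(alignments$start, alignments$end, alignments$strand)
    for (chr in unique(alignments$chrom)) {
      sel <- alignments$chrom == chr
      plus <- alignments$strand[sel] == "+"
      # aggregate copy weight per distinct 5' position and sweep the
      # minus-strand positions once per offset
      wp <- tapply(alignments$count[sel][plus], fp[sel][plus], sum)
      wm <- tapply(alignments$count[sel][!plus], fp[sel][!plus], sum)
      if (length(wp) == 0L || length(wm) == 0L) next
      ap <- as.numeric(names(wp)); am <- as.numeric(names(wm))
      for (o in seq_len(max_overlap)) {
        j <- match(ap + o - 1, am)
        ok <- !is.na(j)
        if (any(ok)) {
          counts[o] <- counts[o] + sum(as.numeric(wp[ok]) * as.numeric(wm[j[ok]]))
        }
      }
    }
  }
  structure(list(overlap_counts = counts, z10 = pingpong_z(counts)),
            class = "pingpong_profile")
}

# z-score of the 10-nt bin against the mean/sd of the other bins.
pingpong_z <- function(counts, bin = 10L) {
  others <- counts[-bin]
  s <- sd(others)
  if (!is.finite(s) || s == 0) return(0)
  (counts[[bin]] - mean(others)) / s
}

#' @export
print.pingpong_profile <- function(x, ...) {
  cat(sprintf("Ping-pong profile: z10 = %.3f (%s)\n", x$z10,
              if (x$z10 > 1.96) "signature detected" else "no signature"))
  print(x$overlap_counts)
  invisible(x)
}

#' @export
plot.pingpong_profile <- function(x, ...) {
  cols <- ifelse(names(x$overlap_counts) == "10", "firebrick", "grey60")
  barplot(x$overlap_counts, col = cols, border = NA,
          xlab = "5'-5' overlap (nt)", ylab = "weighted pair count",
          main = sprintf("z10 = %.2f", x$z10), ...)
  invisible(x)
}
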