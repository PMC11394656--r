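# Shared fixtures and independent brute-force oracles used to cross-check
# the package's optimized implementations.

make_reads <- function(seqs, counts = 1L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  data.frame(id = ids, sequence = seqs,
             count = rep_len(counts, length(seqs)),
             stringsAsFactors = FALSE)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All-pairs ping-pong oracle: enumerate every (+, -) read pair directly.
naive_ping_pong <- function(aln, max_overlap = 20L) {
  counts <- stats::setNames(numeric(max_overlap), seq_len(max_overlap))
  if (is.null(aln$count)) aln$count <- 1L
  fp <- ifelse(aln$strand == "+", aln$start, aln$end - 1L)
  plus <- which(aln$strand == "+")
  minus <- which(aln$strand == "-")
  for (i in plus) {
    for (j in minus) {
      if (aln$chrom[i] != aln$chrom[j]) next
      o <- fp[j] - fp[i] + 1L
      if (o >= 1L && o <= max_overlap) {
        counts[o] <- counts[o] + aln$count[i] * aln$count[j]
      }
    }
  }
  counts
}

# Per-base genomic category oracle: mark every annotated base, count
# directly, apply the priority rule read by read.
naive_assign_category <- function(aln, annotation, min_overlap_fraction = 0.5,
                                  priority = c("repeat", "gene")) {
  out <- character(nrow(aln))
  ob <- integer(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    bases <- seq(aln$start[i], aln$end[i] - 1L)
    width <- length(bases)
    out[i] <- "other"
    for (cat_ in priority) {
      sub <- annotation[annotation$category == cat_ &
                          annotation$chrom == aln$chrom[i], , drop = FALSE]
      covered <- rep(FALSE, width)
      for (k in seq_len(nrow(sub))) {
        covered <- covered | (bases >= sub$start[k] & bases < sub$end[k])
      }
      n_cov <- sum(covered)
      if (n_cov >= min_overlap_fraction * width && n_cov >= 1L) {
        out[i] <- cat_
        ob[i] <- n_cov
        break
      }
    }
  }
  data.frame(id = aln$id, category = out, overlap_bases = ob,
             stringsAsFactors = FALSE)
}

# All-offset duplex oracle: direct per-position scoring loop.
naive_score_duplex <- function(pirna, mrna, match_weight = 1,
                               wobble_weight = 0.5, mismatch_weight = -1) {
  p <- strsplit(chartr("U", "T", toupper(pirna)), "")[[1]]
  m <- strsplit(chartr("U", "T", toupper(mrna)), "")[[1]]
  L <- length(p)
  w1 <- function(pb, mb) {
    if ((pb == "A" && mb == "T") || (pb == "T" && mb == "A") ||
        (pb == "G" && mb == "C") || (pb == "C" && mb == "G")) {
      match_weight
    } else if ((pb == "G" && mb == "T") || (pb == "T" && mb == "G")) {
      wobble_weight
    } else {
      mismatch_weight
    }
  }
  best <- -Inf; best_s <- NA_integer_
  for (s in 0:(length(m) - L)) {
    sc <- 0
    for (i in seq_len(L)) sc <- sc + w1(p[i], m[s + L - i + 1])
    if (sc > best) { best <- sc; best_s <- s }
  }
  seed <- 0L
  for (i in 2:11) {
    pb <- p[i]; mb <- m[best_s + L - i + 1]
    if ((pb == "A" && mb == "T") || (pb == "T" && mb == "A") ||
        (pb == "G" && mb == "C") || (pb == "C" && mb == "G")) {
      seed <- seed + 1L
    }
  }
  list(best_score = best, site_start = best_s, seed_matches = seed)
}

# Reverse complement for building planted duplex sites in tests.
rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
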