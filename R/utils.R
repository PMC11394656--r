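# Internal helpers shared across modules.

# Normalize an RNA/DNA sequence to DNA alphabet (U -> T), uppercase.
norm_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# Reverse-complement a character vector of DNA sequences.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA string(s) of given lengths (uses the current RNG stream).
random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
}

# 5' genomic coordinate of an alignment (0-based): start on +, end-1 on -.
five_prime <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

check_fraction_map <- function(x, what, tol = 1e-9) {
  stop_if(any(x < 0), "%s contains negative fractions", what)
  stop_if(abs(sum(x) - 1) > tol, "%s must sum to 1 (got %.12f)", what, sum(x))
  invisible(TRUE)
}

check_prob <- function(x, what) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1,
          "%s must be a probability in [0, 1]", what)
  invisible(TRUE)
}

# Validate a small-RNA read table (id, sequence, length, count[, sample]).
as_srna_reads <- function(reads) {
  stop_if(!is.data.frame(reads), "reads must be a data.frame")
  need <- c("id", "sequence")
  stop_if(!all(need %in% names(reads)),
          "reads must have columns %s", paste(need, collapse = ", "))
  reads$sequence <- norm_dna(reads$sequence)
  if (is.null(reads$length)) reads$length <- nchar(reads$sequence)
  stop_if(any(reads$length != nchar(reads$sequence)),
          "read length column disagrees with sequence length")
  if (is.null(reads$count)) reads$count <- 1L
  stop_if(any(reads$count < 1), "read counts must be >= 1")
  bad <- grepl("[^ACGTN]", reads$sequence)
  stop_if(any(bad), "read sequences contain characters outside {A,C,G,U/T,N}")
  stop_if(anyDuplicated(reads$id) > 0L, "read ids must be unique")
  reads
}
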