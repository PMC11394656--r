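# Small-RNA classification, candidate piRNA calling, length and class
# composition profiles.

#' Canonical piRNA length windows
#'
#' Two presets are shipped: `canonical` (27-32 nt, the window the emulated
#' testis libraries exhibit and the package default) and `broad` (24-33 nt,
#' the wider range sometimes used for mammalian testis piRNA).
#'
#' @return Named list of `c(min, max)` integer windows.
#' @export
pirna_windows <- function() {
  list(canonical = c(27L, 32L), broad = c(24L, 33L))
}

#' Classify small-RNA reads into ncRNA classes
#'
#' Reads are matched against the reference sets in priority order rRNA ->
#' tRNA -> snRNA -> snoRNA -> miRNA; a read matches a class if it is
#' identical to, or an exact substring of, any reference sequence of that
#' class (U and T equivalent). Unmatched reads that pass the candidate
#' piRNA rule (length within `pirna_window` and 1U or 10A) are labeled
#' "piRNA"; everything else is "other". The result is deterministic and
#' independent of input order.
#'
#' @param reads Read data.frame (id, sequence, count).
#' @param references Named list `class -> character vector` as from
#'   [load_class_references()].
#' @param pirna_window Integer `c(min, max)` length window for the piRNA
#'   rule (default 27-32 nt).
#' @return Named character vector: read id -> class label.
#' @examples
#' refs <- list(miRNA = "TGAGGTAGTAGGTTGTATAGTT")
#' reads <- data.frame(id = c("a", "b"),
#'                     sequence = c("TGAGGTAGTAGGTTGTATAGTT",
#'                                  strrep("TA", 15)))
#' classify_reads(reads, refs)
#' @export
classify_reads <- function(reads, references,
                           pirna_window = pirna_windows()$canonical) {
  reads <- as_srna_reads(reads)
  if (nrow(reads) == 0L) return(setNames(character(0), character(0)))
  priority <- c("rRNA", "tRNA", "snRNA", "snoRNA", "miRNA")
  present <- priority[priority %in% names(references)]
  stop_if(length(unlist(references[present])) == 0L,
          "references must be non-empty for at least one class")

  # exact-substring matching via a hash of all reference substrings whose
  # lengths occur among the reads, ordered so that match() respects the
  # class priority
  lens <- sort(unique(reads$length))
  tab_seq <- character(0); tab_cls <- character(0)
  for (cls in present) {
    for (ref in norm_dna(references[[cls]])) {
      nl <- nchar(ref)
      for (l in lens[lens <= nl]) {
        tab_seq <- c(tab_seq, substring(ref, 1:(nl - l + 1L), l:nl))
        tab_cls <- c(tab_cls, rep(cls, nl - l + 1L))
      }
    }
  }
  hit <- match(reads$sequence, tab_seq)
  label <- ifelse(is.na(hit), NA_character_, tab_cls[hit])

  unmatched <- is.na(label)
  cand <- is_pirna_candidate(reads$sequence[unmatched],
                             reads$length[unmatched], pirna_window)
  label[unmatched] <- ifelse(cand, "piRNA", "other")
  setNames(label, reads$id)
}

# The 1U/10A candidate rule on already-normalized sequences.
is_pirna_candidate <- function(seqs, lens, window) {
  in_win <- lens >= window[1] & lens <= window[2]
  first_u <- substring(seqs, 1L, 1L) == "T"
  tenth_a <- substring(seqs, 10L, 10L) == "A"
  in_win & (first_u | tenth_a)
}

#' Call candidate piRNAs by the length and 1U/10A rule
#'
#' Retains exactly the reads whose length lies within `window` and whose
#' first base is U (1U) or whose tenth base is A (10A), recording which
#' rule(s) fired. U and T are treated as equivalent.
#'
#' @param reads Read data.frame (id, sequence, count).
#' @param window Integer `c(min, max)` length window; `min` must be >= 10
#'   so that position 10 exists. See [pirna_windows()] for presets.
#' @return data.frame of retained reads with added logical columns
#'   `first_is_U` and `tenth_is_A`.
#' @examples
#' reads <- data.frame(id = "a", sequence = paste0("T", strrep("G", 29)))
#' call_pirna_candidates(reads)
#' @export
call_pirna_candidates <- function(reads, window = pirna_windows()$canonical) {
  stop_if(length(window) != 2L || window[1] > window[2],
          "window must be c(min, max) with min <= max")
  stop_if(window[1] < 10L, "window min must be >= 10 (position 10 must exist)")
  reads <- as_srna_reads(reads)
  keep <- is_pirna_candidate(reads$sequence, reads$length, window)
  out <- reads[keep, , drop = FALSE]
  out$first_is_U <- substring(out$sequence, 1L, 1L) == "T"
  out$tenth_is_A <- substring(out$sequence, 10L, 10L) == "A"
  rownames(out) <- NULL
  out
}

#' Count-weighted read length histogram
#'
#' @param reads Read data.frame (id, sequence, count).
#' @param restrict_class Optional class label; keep only reads labeled with
#'   it (requires `labels`).
#' @param labels Named character vector read id -> class, as from
#'   [classify_reads()].
#' @return Object of class `length_histogram`: list with `counts` (named
#'   numeric over observed lengths) and `modal_length` (smallest length
#'   attaining the maximum).
#' @export
length_histogram <- function(reads, restrict_class = NULL, labels = NULL) {
  reads <- as_srna_reads(reads)
  if (!is.null(restrict_class)) {
    stop_if(is.null(labels), "restrict_class requires labels")
    keep <- names(labels)[labels == restrict_class]
    reads <- reads[reads$id %in% keep, , drop = FALSE]
  }
  stop_if(nrow(reads) == 0L, "no reads selected for the length histogram")
  counts <- tapply(reads$count, reads$length, sum)
  counts <- setNames(as.numeric(counts), names(counts))
  modal <- min(as.integer(names(counts)[counts == max(counts)]))
  structure(list(counts = counts, modal_length = modal),
            class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  cat(sprintf("Length histogram over %s-%s nt, modal length %d nt\n",
              min(names(x$counts)), max(names(x$counts)), x$modal_length))
  print(x$counts)
  invisible(x)
}

#' @export
plot.length_histogram <- function(x, ...) {
  lens <- as.integer(names(x$counts))
  full <- setNames(numeric(diff(range(lens)) + 1L),
                   seq(min(lens), max(lens)))
  full[names(x$counts)] <- x$counts
  barplot(full, xlab = "read length (nt)", ylab = "read copies", ...)
  invisible(x)
}

#' Count-weighted class composition
#'
#' @param labels Named character vector read id -> class.
#' @param reads Read data.frame; every labeled id must be present.
#' @return Object of class `class_composition`: named numeric vector of
#'   percentages summing to 100.
#' @export
class_composition <- function(labels, reads) {
  reads <- as_srna_reads(reads)
  idx <- match(names(labels), reads$id)
  stop_if(anyNA(idx), "labels refer to read ids absent from reads: %s",
          paste(head(names(labels)[is.na(idx)], 3), collapse = ", "))
  w <- reads$count[idx]
  pct <- 100 * tapply(w, as.character(labels), sum) / sum(w)
  structure(setNames(as.numeric(pct), names(pct)),
            class = "class_composition")
}

#' @export
print.class_composition <- function(x, ...) {
  v <- sort(unclass(x), decreasing = TRUE)
  cat("Class composition (% of read copies):\n")
  for (cls in names(v)) cat(sprintf("  %-8s %6.2f%%\n", cls, v[[cls]]))
  invisible(x)
}
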