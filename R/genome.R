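#' Simulate an annotated genome
#'
#' Generates a uniform-random DNA sequence and a set of mutually disjoint
#' `repeat` and `gene` annotation intervals whose total base coverage equals
#' the requested fractions (to rounding at interval granularity). All
#' coordinates are 0-based, half-open (BED convention). Unannotated bases
#' form the implicit `other` category.
#'
#' Interval sizes are near-equal around a category-typical size (repeat
#' ~600 bp, gene ~2000 bp); intervals are laid out in random order with
#' random non-negative gaps, so the exact requested coverage is achieved
#' while placement stays random.
#'
#' @param length Genome length in nt (>= 1000).
#' @param repeat_fraction,gene_fraction Target fractions of bases covered by
#'   repeat and gene intervals; their sum must be <= 0.9.
#' @param seed Integer seed; the same (arguments, seed) give a byte-identical
#'   genome.
#' @param name Sequence name used in FASTA/BED output.
#' @return Object of class `synthetic_genome`: list with `name`, `sequence`
#'   (character string), `length`, and `annotation` (data.frame with columns
#'   chrom, start, end, strand, category).
#' @examples
#' g <- simulate_genome(20000, 0.15, 0.01, seed = 1)
#' table(g$annotation$category)
#' @export
simulate_genome <- function(length, repeat_fraction, gene_fraction,
                            seed = 1L, name = "chrS") {
  stop_if(length < 1000, "genome length must be >= 1000")
  stop_if(repeat_fraction < 0 || gene_fraction < 0,
          "fractions must be non-negative")
  stop_if(repeat_fraction + gene_fraction > 0.9,
          "repeat_fraction + gene_fraction must be <= 0.9")
  length <- as.integer(length)
  set.seed(as.integer(seed))
  sequence <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")

  sizes_for <- function(target, typical) {
    if (target <= 0L) return(integer(0))
    n <- max(1L, as.integer(round(target / typical)))
    base <- target %/% n
    extra <- target %% n
    sz <- rep(base, n)
    if (extra > 0L) sz[seq_len(extra)] <- sz[seq_len(extra)] + 1L
    sz
  }
  rep_sizes <- sizes_for(as.integer(round(length * repeat_fraction)), 600L)
  gene_sizes <- sizes_for(as.integer(round(length * gene_fraction)), 2000L)
  sizes <- c(rep_sizes, gene_sizes)
  cats <- c(rep("repeat", length(rep_sizes)), rep("gene", length(gene_sizes)))
  if (length(sizes) == 0L) {
    anno <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       category = character(0), stringsAsFactors = FALSE)
  } else {
    ord <- sample.int(length(sizes))
    sizes <- sizes[ord]; cats <- cats[ord]
    free <- length - sum(sizes)
    stop_if(free < 0, "annotation does not fit in the genome")
    # random non-negative gaps before each interval (and after the last)
    breaks <- sort(sample.int(free + 1L, length(sizes), replace = TRUE) - 1L)
    starts <- breaks + c(0L, cumsum(sizes)[-length(sizes)])
    anno <- data.frame(chrom = name, start = starts,
                       end = starts + sizes, strand = ".",
                       category = cats, stringsAsFactors = FALSE)
    anno <- anno[order(anno$start), , drop = FALSE]
    rownames(anno) <- NULL
  }
  structure(list(name = name, sequence = sequence, length = length,
                 annotation = anno),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cov <- tapply(x$annotation$end - x$annotation$start,
                x$annotation$category, sum)
  cat(sprintf("Synthetic genome '%s': %d bp, %d annotation intervals\n",
              x$name, x$length, nrow(x$annotation)))
  for (cat_ in names(cov)) {
    cat(sprintf("  %s: %d bp (%.2f%%)\n", cat_, cov[[cat_]],
                100 * cov[[cat_]] / x$length))
  }
  invisible(x)
}

# Interval table for one category, including the implicit "other" complement.
category_intervals <- function(genome, category) {
  anno <- genome$annotation
  if (category != "other") {
    out <- anno[anno$category == category, c("start", "end"), drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  occ <- anno[order(anno$start), , drop = FALSE]
  starts <- integer(0); ends <- integer(0)
  pos <- 0L
  for (i in seq_len(nrow(occ))) {
    if (occ$start[i] > pos) { starts <- c(starts, pos); ends <- c(ends, occ$start[i]) }
    pos <- max(pos, occ$end[i])
  }
  if (pos < genome$length) { starts <- c(starts, pos); ends <- c(ends, genome$length) }
  data.frame(start = starts, end = ends)
}
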