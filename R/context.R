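# Genomic-origin category assignment (repeat / gene / other) for mapped
# piRNAs, and category composition summaries.

#' Assign mapped reads to genomic categories
#'
#' Each read is assigned to the first category in `priority` for which at
#' least `min_overlap_fraction` of its bases fall inside intervals of that
#' category (strand-agnostic; intervals of one category are merged before
#' overlap is measured, so split annotations behave like their union).
#' Reads qualifying for no category are "other" with 0 overlap bases.
#'
#' @param aln Alignment data.frame (id, chrom, start, end, strand, count),
#'   0-based half-open.
#' @param annotation Annotation data.frame (chrom, start, end, category)
#'   with categories among `priority`.
#' @param min_overlap_fraction Required overlapping fraction of the read,
#'   in (0, 1] (default 0.5).
#' @param priority Category order tried first-to-last (default repeat then
#'   gene, reflecting the transposon-silencing reading of repeat-derived
#'   piRNAs).
#' @return data.frame with columns id, category, overlap_bases.
#' @examples
#' aln <- data.frame(id = "r1", chrom = "chr1", start = 100, end = 130,
#'                   strand = "+", count = 1)
#' anno <- data.frame(chrom = "chr1", start = 0, end = 1000,
#'                    category = "repeat")
#' assign_category(aln, anno)
#' @export
assign_category <- function(aln, annotation, min_overlap_fraction = 0.5,
                            priority = c("repeat", "gene")) {
  stop_if(!is.numeric(min_overlap_fraction) ||
            min_overlap_fraction <= 0 || min_overlap_fraction > 1,
          "min_overlap_fraction must lie in (0, 1]")
  n <- nrow(aln)
  category <- rep("other", n)
  overlap <- integer(n)
  width <- aln$end - aln$start
  unassigned <- rep(TRUE, n)
  for (cat_ in priority) {
    sub <- annotation[annotation$category == cat_, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ob <- overlap_bases_by_chrom(aln, sub)
    take <- unassigned & (ob >= min_overlap_fraction * width) & ob >= 1L
    category[take] <- cat_
    overlap[take] <- ob[take]
    unassigned <- unassigned & !take
  }
  data.frame(id = aln$id, category = category, overlap_bases = overlap,
             stringsAsFactors = FALSE)
}

# Total bases of each read overlapping the (merged) intervals, per chrom.
overlap_bases_by_chrom <- function(aln, intervals) {
  out <- integer(nrow(aln))
  for (chr in unique(aln$chrom)) {
    rsel <- which(aln$chrom == chr)
    isel <- intervals$chrom == chr
    if (!any(isel)) next
    rir <- IRanges::IRanges(start = aln$start[rsel] + 1L, end = aln$end[rsel])
    iir <- IRanges::reduce(IRanges::IRanges(start = intervals$start[isel] + 1L,
                                            end = intervals$end[isel]))
    hits <- IRanges::findOverlaps(rir, iir)
    if (length(hits) == 0L) next
    w <- IRanges::width(IRanges::pintersect(
      rir[S4Vectors::queryHits(hits)], iir[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[rsel[as.integer(names(agg))]] <- as.integer(agg)
  }
  out
}

#' Count-weighted category composition of assigned reads
#'
#' @param assignments [assign_category()] output.
#' @param counts Named numeric: read id -> copy number.
#' @return Object of class `category_summary`: named percentage vector over
#'   repeat/gene/other, summing to 100.
#' @export
category_summary <- function(assignments, counts) {
  stop_if(nrow(assignments) == 0L, "no assignments to summarize")
  w <- counts[assignments$id]
  stop_if(anyNA(w), "every assignment id needs a copy number in counts")
  cats <- c("repeat", "gene", "other")
  pct <- setNames(numeric(3), cats)
  got <- 100 * tapply(as.numeric(w), assignments$category, sum) / sum(w)
  pct[names(got)] <- got
  structure(pct, class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat("Genomic origin of mapped piRNAs (% of copies):\n")
  for (cat_ in names(x)) cat(sprintf("  %-7s %6.2f%%\n", cat_, x[[cat_]]))
  invisible(x)
}
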