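# File formats: collapsed FASTA / FASTQ reads, BED6 alignments and
# annotation, TSV matrices and tables. Sequence parsing goes through
# Biostrings; BED6/TSV are plain 6-column tables handled with base R.

#' Read small-RNA reads from a collapsed FASTA file
#'
#' Collapsed FASTA encodes copy number in the identifier as `>id_xCOUNT`;
#' records without the `_x` suffix get count 1.
#'
#' @param path FASTA file.
#' @param sample Optional sample identifier attached to every read.
#' @return data.frame with columns id, sequence, length, count, sample.
#' @export
read_collapsed_fasta <- function(path, sample = NA_character_) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  m <- regmatches(ids, regexec("^(.*)_x(\\d+)$", ids))
  count <- vapply(m, function(g) if (length(g) == 3L) as.integer(g[3]) else 1L,
                  integer(1))
  id <- vapply(seq_along(m), function(i) {
    if (length(m[[i]]) == 3L) m[[i]][2] else ids[i]
  }, character(1))
  as_srna_reads(data.frame(id = id, sequence = as.character(ss),
                           count = count, sample = sample,
                           stringsAsFactors = FALSE))
}

#' Write reads as collapsed FASTA (`>id_xCOUNT`)
#'
#' @param reads Read data.frame (id, sequence, count).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  reads <- as_srna_reads(reads)
  writeLines(paste0(">", reads$id, "_x", reads$count, "\n", reads$sequence),
             path)
  invisible(path)
}

#' Read / write reads as FASTQ
#'
#' FASTQ carries no copy-number convention here: one record per collapsed
#' read, written with a constant placeholder quality.
#'
#' @param path FASTQ file.
#' @param sample Optional sample identifier.
#' @param reads Read data.frame.
#' @return `read_srna_fastq` returns a read data.frame.
#' @export
read_srna_fastq <- function(path, sample = NA_character_) {
  ss <- Biostrings::readBStringSet(path, format = "fastq")
  as_srna_reads(data.frame(id = sub("\\s.*$", "", names(ss)),
                           sequence = as.character(ss),
                           count = 1L, sample = sample,
                           stringsAsFactors = FALSE))
}

#' @rdname read_srna_fastq
#' @export
write_reads_fastq <- function(reads, path) {
  reads <- as_srna_reads(reads)
  qual <- vapply(reads$length, function(n) strrep("I", n), character(1))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", qual), path)
  invisible(path)
}

#' Write a synthetic genome as FASTA
#' @param genome A [simulate_genome()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read / write annotation intervals as BED6
#'
#' The BED name field carries the category (`repeat` / `gene`), score is 0
#' and coordinates are 0-based half-open.
#'
#' @param x Annotation data.frame (chrom, start, end, strand, category) or a
#'   `synthetic_genome`.
#' @param path BED file.
#' @return `read_annotation_bed` returns the annotation data.frame.
#' @export
write_annotation_bed <- function(x, path) {
  if (inherits(x, "synthetic_genome")) x <- x$annotation
  bed <- data.frame(x$chrom, x$start, x$end, x$category, 0L,
                    ifelse(x$strand %in% c("+", "-"), x$strand, "."))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1]], start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]), strand = bed[[6]],
             category = bed[[4]], stringsAsFactors = FALSE)
}

#' Read / write read alignments as BED6
#'
#' The name field is the read id and the score field carries the copy
#' number.
#'
#' @param aln Alignment data.frame (id, chrom, start, end, strand, count).
#' @param path BED file.
#' @return `read_alignments_bed` returns the alignment data.frame.
#' @export
write_alignments_bed <- function(aln, path) {
  bed <- data.frame(aln$chrom, aln$start, aln$end, aln$id, aln$count,
                    aln$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments_bed
#' @export
read_alignments_bed <- function(path) {
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(id = bed[[4]], chrom = bed[[1]], start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]), strand = bed[[6]],
             count = as.integer(bed[[5]]), stringsAsFactors = FALSE)
}

#' Load packaged (or external) ncRNA class reference sequences
#'
#' The bundled reference set is a small synthetic FASTA whose record names
#' are `CLASS_NN` (e.g. `miRNA_03`); it stands in for the curated ncRNA
#' databases a production pipeline would use and exists so that
#' classification is exactly reproducible offline.
#'
#' @param path FASTA of reference sequences; defaults to the packaged
#'   synthetic set.
#' @return Named list `class -> character vector of sequences`.
#' @export
load_class_references <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_ncrna_references.fa",
                        package = "pirnascape")
  }
  ss <- Biostrings::readBStringSet(path)
  cls <- sub("_.*$", "", sub("\\s.*$", "", names(ss)))
  split(norm_dna(as.character(ss)), cls)
}

#' Read / write expression matrices as TSV
#'
#' The matrix TSV is piRNAs x samples with a header row of sample ids; the
#' sidecar design TSV has columns `sample` and `condition`.
#'
#' @param em An [expression_matrix()].
#' @param path Matrix TSV path.
#' @param design_path Design TSV path.
#' @return `read_expression_tsv` returns an `expression_matrix`.
#' @param kind Value kind of the matrix being read: "count" or "tpm".
#' @export
write_expression_tsv <- function(em, path, design_path) {
  write.table(em$values, path, sep = "\t", quote = FALSE, col.names = NA)
  write.table(data.frame(sample = colnames(em$values),
                         condition = as.character(em$condition)),
              design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, design_path, kind = "count") {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                            row.names = 1, check.names = FALSE))
  design <- read.table(design_path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  cond <- setNames(design$condition, design$sample)[colnames(m)]
  expression_matrix(m, cond, kind = kind)
}

#' Write a differential-expression result table as TSV
#' @param results A [de_test()] result.
#' @param path Output TSV (columns id, log2fc, p, status).
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(results, path) {
  write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a simulation truth table as TSV
#' @param truth Truth data.frame from [simulate_library()] or
#'   [simulate_count_matrix()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
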