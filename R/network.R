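# piRNA-mRNA duplex scoring, target prediction, and the bipartite
# regulatory network. The duplex scorer is a deliberately simple antisense
# complementarity score (match / G:U wobble / mismatch weights, no
# thermodynamics or bulges); externally produced target tables can be used
# instead via build_network().

#' Score antisense complementarity of a piRNA against an mRNA
#'
#' Slides the piRNA (antiparallel) along the mRNA; at each offset the score
#' sums `match_weight` for Watson-Crick pairs, `wobble_weight` for G:U
#' pairs, and `mismatch_weight` otherwise, over all piRNA positions. The
#' best-scoring site is returned (ties break to the smallest site start);
#' `seed_matches` counts Watson-Crick pairs at piRNA positions 2-11 of that
#' site.
#'
#' @param pirna_seq piRNA sequence (>= 11 nt).
#' @param mrna_seq mRNA sequence (>= piRNA length).
#' @param match_weight,wobble_weight,mismatch_weight Per-position weights.
#' @return List with `best_score`, `site_start` (0-based on the mRNA) and
#'   `seed_matches`.
#' @examples
#' m <- paste(rep("A", 40), collapse = "")
#' score_duplex(paste(rep("T", 30), collapse = ""), m)$best_score
#' @export
score_duplex <- function(pirna_seq, mrna_seq, match_weight = 1.0,
                         wobble_weight = 0.5, mismatch_weight = -1.0) {
  p <- norm_dna(pirna_seq); m <- norm_dna(mrna_seq)
  L <- nchar(p); M <- nchar(m)
  stop_if(L < 11L, "piRNA must be >= 11 nt")
  stop_if(M < L, "mRNA must be at least as long as the piRNA")
  pc <- strsplit(p, "")[[1]]
  mc <- strsplit(m, "")[[1]]

  pair_w <- function(pb, mb) {
    wc <- (pb == "A" & mb == "T") | (pb == "T" & mb == "A") |
      (pb == "G" & mb == "C") | (pb == "C" & mb == "G")
    wob <- (pb == "G" & mb == "T") | (pb == "T" & mb == "G")
    ifelse(wc, match_weight, ifelse(wob, wobble_weight, mismatch_weight))
  }

  n_off <- M - L + 1L
  scores <- numeric(n_off)
  # antiparallel pairing: piRNA position i faces mRNA position s + L - i + 1
  # (1-based), i.e. the reversed piRNA slides along the mRNA
  rc <- rev(pc)
  for (j in seq_len(L)) {
    scores <- scores + pair_w(rep(rc[j], n_off), mc[seq_len(n_off) + j - 1L])
  }
  best <- which.max(scores)  # first maximum = smallest site_start
  s <- best - 1L
  seed_pos <- 2:11
  mb <- mc[s + L - seed_pos + 1L]
  pb <- pc[seed_pos]
  wc <- (pb == "A" & mb == "T") | (pb == "T" & mb == "A") |
    (pb == "G" & mb == "C") | (pb == "C" & mb == "G")
  list(best_score = scores[best], site_start = s,
       seed_matches = as.integer(sum(wc)))
}

#' Predict mRNA targets for a set of piRNAs
#'
#' Scores every piRNA against every mRNA with [score_duplex()] and retains
#' pairs with `best_score >= min_score` and `seed_matches >=
#' min_seed_matches`.
#'
#' @param pirna_seqs Named character vector of piRNA sequences.
#' @param mrna_seqs Named character vector of mRNA sequences (may be
#'   empty, giving an empty result).
#' @param min_score Minimum duplex score.
#' @param min_seed_matches Minimum Watson-Crick matches at piRNA positions
#'   2-11 (default 9).
#' @param ... Passed to [score_duplex()].
#' @return data.frame with columns pirna, mrna, score, site_start,
#'   seed_matches.
#' @export
predict_targets <- function(pirna_seqs, mrna_seqs, min_score,
                            min_seed_matches = 9L, ...) {
  stop_if(!is.finite(min_score) || !is.finite(min_seed_matches),
          "thresholds must be finite")
  empty <- data.frame(pirna = character(0), mrna = character(0),
                      score = numeric(0), site_start = integer(0),
                      seed_matches = integer(0), stringsAsFactors = FALSE)
  if (length(mrna_seqs) == 0L || length(pirna_seqs) == 0L) return(empty)
  rows <- list()
  for (pi_id in names(pirna_seqs)) {
    for (m_id in names(mrna_seqs)) {
      ds <- score_duplex(pirna_seqs[[pi_id]], mrna_seqs[[m_id]], ...)
      if (ds$best_score >= min_score && ds$seed_matches >= min_seed_matches) {
        rows[[length(rows) + 1L]] <-
          data.frame(pirna = pi_id, mrna = m_id, score = ds$best_score,
                     site_start = ds$site_start,
                     seed_matches = ds$seed_matches,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the bipartite piRNA-mRNA regulatory network
#'
#' Edges are restricted to differentially expressed piRNAs and mRNAs: every
#' edge endpoint must appear with status `up` or `down` in its DE table.
#' Duplicate (piRNA, mRNA) edges collapse to one (keeping the best score),
#' so each mRNA's regulator degree counts distinct piRNA neighbors.
#'
#' @param edges data.frame with columns pirna, mrna and optionally score.
#' @param de_pirna_table,de_mrna_table data.frames with columns id and
#'   status (up/down among DE entries).
#' @return Object of class `regulatory_network`: list with `edges` (pirna,
#'   mrna, score, pirna_status, mrna_status), `pirnas`, `mrnas`, and
#'   `mrna_degree` (data.frame mrna, degree, sorted decreasing).
#' @export
build_network <- function(edges, de_pirna_table, de_mrna_table) {
  de_pi <- de_pirna_table[de_pirna_table$status %in% c("up", "down"), ,
                          drop = FALSE]
  de_m <- de_mrna_table[de_mrna_table$status %in% c("up", "down"), ,
                        drop = FALSE]
  if (nrow(edges) > 0L) {
    bad_pi <- setdiff(edges$pirna, de_pi$id)
    stop_if(length(bad_pi) > 0L,
            "edge references non-DE piRNA: %s", bad_pi[1])
    bad_m <- setdiff(edges$mrna, de_m$id)
    stop_if(length(bad_m) > 0L, "edge references non-DE mRNA: %s", bad_m[1])
    if (is.null(edges$score)) edges$score <- NA_real_
    edges <- edges[order(edges$pirna, edges$mrna, -edges$score), ,
                   drop = FALSE]
    edges <- edges[!duplicated(edges[, c("pirna", "mrna")]), , drop = FALSE]
    edges$pirna_status <- de_pi$status[match(edges$pirna, de_pi$id)]
    edges$mrna_status <- de_m$status[match(edges$mrna, de_m$id)]
    edges <- edges[, c("pirna", "mrna", "score", "pirna_status",
                       "mrna_status")]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(pirna = character(0), mrna = character(0),
                        score = numeric(0), pirna_status = character(0),
                        mrna_status = character(0), stringsAsFactors = FALSE)
  }
  deg <- if (nrow(edges) > 0L) {
    tb <- sort(table(edges$mrna), decreasing = TRUE)
    data.frame(mrna = names(tb), degree = as.integer(tb),
               stringsAsFactors = FALSE)
  } else {
    data.frame(mrna = character(0), degree = integer(0),
               stringsAsFactors = FALSE)
  }
  structure(list(edges = edges,
                 pirnas = sort(unique(edges$pirna)),
                 mrnas = sort(unique(edges$mrna)),
                 mrna_degree = deg),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("piRNA-mRNA regulatory network: %d piRNAs, %d mRNAs, %d edges\n",
              length(x$pirnas), length(x$mrnas), nrow(x$edges)))
  if (nrow(x$mrna_degree) > 0L) {
    top <- x$mrna_degree[1, ]
    cat(sprintf("  most-regulated mRNA: %s (%d distinct piRNAs)\n",
                top$mrna, top$degree))
  }
  invisible(x)
}

#' Export a regulatory network
#'
#' Formats: `tsv` (loss-less: re-importable with [import_network_tsv()]),
#' `sif` (Cytoscape simple interaction format, one `piRNA regulates mRNA`
#' row per edge), and `graphml` (bipartite graph with status and score
#' attributes, written through igraph).
#'
#' @param network A [build_network()] result.
#' @param path Output file.
#' @param format One of "tsv", "sif", "graphml".
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("tsv", "sif",
                                                     "graphml")) {
  stop_if(!inherits(network, "regulatory_network"),
          "network must be a regulatory_network")
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(network$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else if (format == "sif") {
    writeLines(sprintf("%s regulates %s", network$edges$pirna,
                       network$edges$mrna), path)
  } else {
    g <- network_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network_tsv <- function(path) {
  e <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  build_network(e[, c("pirna", "mrna", "score")],
                data.frame(id = e$pirna, status = e$pirna_status),
                data.frame(id = e$mrna, status = e$mrna_status))
}

#' Convert a regulatory network to an igraph bipartite graph
#'
#' @param network A [build_network()] result.
#' @return An igraph graph with vertex attributes `type` (FALSE = piRNA,
#'   TRUE = mRNA) and `status`, and edge attribute `score`.
#' @export
network_to_igraph <- function(network) {
  e <- network$edges
  verts <- data.frame(
    name = c(network$pirnas, network$mrnas),
    type = c(rep(FALSE, length(network$pirnas)),
             rep(TRUE, length(network$mrnas))),
    status = c(e$pirna_status[match(network$pirnas, e$pirna)],
               e$mrna_status[match(network$mrnas, e$mrna)]),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(e[, c("pirna", "mrna", "score")],
                                directed = TRUE, vertices = verts)
}
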