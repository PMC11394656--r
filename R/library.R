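#' Simulate a two-condition small-RNA sequencing library
#'
#' Draws `n_reads` read copies with class counts multinomially distributed
#' according to `config$class_fractions[[condition]]`. piRNA reads are
#' sampled from genomic loci (wholly inside an interval of their origin
#' category), with lengths from `pirna_length_dist`, a U at position 1 with
#' probability `q1U` and an A at position 10 with probability `q10A`. A
#' `pingpong_fraction` of piRNA reads are emitted as antisense secondary
#' partners whose 5' end overlaps their primary's 5' end by exactly 10 nt;
#' because the two reads cover the same duplex, the partner's base biases
#' are tied through complementarity (see the methods vignette). Base biases
#' are realised by rejection-sampling loci, so every genome-derived read's
#' sequence equals the genome substring at its alignment coordinates
#' (reverse-complemented on the minus strand).
#'
#' Non-piRNA classes are drawn from packaged reference class sequences:
#' mature miRNAs as full reference sequences with lengths peaked at
#' `mirna_length_mode`, the structural classes (rRNA, tRNA, snRNA, snoRNA)
#' as reference fragments, and `other` as random sequences with lengths
#' outside the piRNA window. Identical reference-derived sequences are
#' collapsed with summed copy counts.
#'
#' @param config A [generator_config()].
#' @param genome A [simulate_genome()] result.
#' @param condition Condition name; must be present in
#'   `config$class_fractions` (defaults ship "BSB" and "NBS").
#' @param seed Integer seed (defaults to `config$seed`). Identical
#'   (config, genome, condition, seed) give byte-identical output.
#' @param references Class reference list as from [load_class_references()].
#' @return Object of class `synthetic_library`: list with `reads` (id,
#'   sequence, length, count, sample), `alignments` (BED-like: id, chrom,
#'   start, end, strand, count; genome-derived reads only), and `truth`
#'   (id, class, category, role, partner_id).
#' @examples
#' g <- simulate_genome(50000, 0.15, 0.01, seed = 1)
#' lib <- simulate_library(generator_config(n_reads = 2000), g, "BSB", seed = 1)
#' head(lib$truth)
#' @export
simulate_library <- function(config, genome, condition,
                             seed = config$seed,
                             references = load_class_references()) {
  stop_if(!inherits(config, "generator_config"),
          "config must be a generator_config")
  stop_if(!inherits(genome, "synthetic_genome"),
          "genome must be a synthetic_genome")
  fracs <- config$class_fractions[[condition]]
  stop_if(is.null(fracs) || length(fracs) == 0L,
          "class_fractions has no entry for condition '%s'", condition)
  clearance <- 45L  # covers max read length 32 plus the 9-nt pair offset
  stop_if(genome$length < 2L * clearance + 10L,
          "genome too short to sample reads")
  set.seed(as.integer(seed))

  n_class <- stats::rmultinom(1, config$n_reads, fracs)[, 1]

  reads <- list(); truth <- list(); aln <- NULL

  ## ---- piRNA reads -------------------------------------------------------
  n_pi <- n_class[["piRNA"]]
  if (n_pi > 0L) {
    pi_parts <- simulate_pirna_reads(config, genome, n_pi, clearance)
    reads$piRNA <- pi_parts$reads
    truth$piRNA <- pi_parts$truth
    aln <- pi_parts$alignments
  }

  ## ---- reference-derived classes ----------------------------------------
  frag_ranges <- list(rRNA = c(18L, 34L), tRNA = c(16L, 34L),
                      snRNA = c(18L, 30L), snoRNA = c(18L, 30L))
  for (cls in c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA")) {
    n <- if (cls %in% names(n_class)) n_class[[cls]] else 0L
    if (n == 0L) next
    refs <- references[[cls]]
    stop_if(is.null(refs) || length(refs) == 0L,
            "no reference sequences for class %s", cls)
    if (cls == "miRNA") {
      w <- 2^(-2 * abs(nchar(refs) - config$mirna_length_mode))
      seqs <- refs[sample.int(length(refs), n, replace = TRUE, prob = w)]
    } else {
      rng <- frag_ranges[[cls]]
      ridx <- sample.int(length(refs), n, replace = TRUE)
      rl <- nchar(refs)[ridx]
      fl <- pmin(rl, sample(seq(rng[1], rng[2]), n, replace = TRUE))
      st <- floor(runif(n) * (rl - fl + 1))
      seqs <- substring(refs[ridx], st + 1, st + fl)
    }
    tab <- table(seqs)
    ids <- sprintf("%s_%05d", tolower(cls), seq_along(tab))
    reads[[cls]] <- data.frame(id = ids, sequence = names(tab),
                               count = as.integer(tab),
                               stringsAsFactors = FALSE)
    truth[[cls]] <- data.frame(id = ids, class = cls,
                               category = NA_character_, role = "n/a",
                               partner_id = NA_character_,
                               stringsAsFactors = FALSE)
  }

  ## ---- unannotated 'other' reads ----------------------------------------
  n_other <- if ("other" %in% names(n_class)) n_class[["other"]] else 0L
  if (n_other > 0L) {
    # lengths deliberately outside the canonical piRNA window
    ol <- sample(c(15:26, 33:36), n_other, replace = TRUE)
    ids <- sprintf("other_%06d", seq_len(n_other))
    reads$other <- data.frame(id = ids, sequence = random_dna(ol),
                              count = 1L, stringsAsFactors = FALSE)
    truth$other <- data.frame(id = ids, class = "other",
                              category = NA_character_, role = "n/a",
                              partner_id = NA_character_,
                              stringsAsFactors = FALSE)
  }

  reads <- do.call(rbind, unname(reads))
  truth <- do.call(rbind, unname(truth))
  rownames(reads) <- rownames(truth) <- NULL
  reads$length <- nchar(reads$sequence)
  reads$sample <- condition
  reads <- reads[, c("id", "sequence", "length", "count", "sample")]
  structure(list(reads = reads, alignments = aln, truth = truth,
                 condition = condition),
            class = "synthetic_library")
}

#' @export
print.synthetic_library <- function(x, ...) {
  total <- sum(x$reads$count)
  cat(sprintf("Synthetic %s library: %d collapsed reads (%d copies)\n",
              x$condition, nrow(x$reads), total))
  comp <- tapply(x$reads$count[match(x$truth$id, x$reads$id)], x$truth$class,
                 sum)
  comp <- sort(100 * comp / total, decreasing = TRUE)
  cat("  true composition:",
      paste(sprintf("%s %.1f%%", names(comp), comp), collapse = ", "), "\n")
  if (!is.null(x$alignments)) {
    cat(sprintf("  %d genome alignments\n", nrow(x$alignments)))
  }
  invisible(x)
}

# piRNA read generation: locus rejection sampling + ping-pong pairing.
simulate_pirna_reads <- function(config, genome, n_pi, clearance) {
  lens <- as.integer(names(config$pirna_length_dist))
  ldist <- as.numeric(config$pirna_length_dist)

  n_sec <- min(as.integer(round(n_pi * config$pingpong_fraction)),
               n_pi %/% 2L)
  n_pairs <- n_sec
  n_pri <- n_pi - n_sec  # paired primaries first, then standalone

  # eligible anchor positions: wholly inside a category interval with
  # `clearance` bp to spare on both sides. Each interval is a uni-strand
  # cluster: all its primary reads share one strand, so antisense read
  # pairs only arise through ping-pong pairing (see the methods vignette).
  cats <- names(config$origin_fractions)
  elig <- lapply(cats, function(cc) {
    iv <- category_intervals(genome, cc)
    iv$w <- iv$end - iv$start - 2L * clearance
    iv <- iv[iv$w > 0L, , drop = FALSE]
    if (nrow(iv) > 0L) {
      iv$strand <- sample(c("+", "-"), nrow(iv), replace = TRUE)
    }
    iv
  })
  names(elig) <- cats
  cat_draw <- sample(cats, n_pri, replace = TRUE,
                     prob = as.numeric(config$origin_fractions))
  for (cc in unique(cat_draw)) {
    stop_if(nrow(elig[[cc]]) == 0L,
            "genome has no interval large enough to host '%s' reads", cc)
  }

  draw_locus <- function(idx) {
    a <- integer(length(idx))
    s <- character(length(idx))
    for (cc in unique(cat_draw[idx])) {
      sel <- cat_draw[idx] == cc
      iv <- elig[[cc]]
      j <- sample.int(nrow(iv), sum(sel), replace = TRUE, prob = iv$w)
      a[sel] <- iv$start[j] + clearance +
        as.integer(floor(runif(sum(sel)) * iv$w[j]))
      s[sel] <- iv$strand[j]
    }
    list(anchor = a, strand = s)
  }

  want1U <- runif(n_pri) < config$q1U   # primary pos 1 / secondary pos 10
  want10A <- runif(n_pri) < config$q10A # primary pos 10 / secondary pos 1
  base_at <- function(pos) substring(genome$sequence, pos + 1, pos + 1)

  anchor <- integer(n_pri)
  strand <- character(n_pri)
  todo <- seq_len(n_pri)
  iter <- 0L
  while (length(todo) > 0L) {
    loc <- draw_locus(todo)
    anchor[todo] <- loc$anchor
    strand[todo] <- loc$strand
    p1 <- anchor[todo]
    p2 <- ifelse(strand[todo] == "+", p1 + 9L, p1 - 9L)
    b1ok <- (base_at(p1) == ifelse(strand[todo] == "+", "T", "A")) ==
      want1U[todo]
    b2ok <- (base_at(p2) == ifelse(strand[todo] == "+", "A", "T")) ==
      want10A[todo]
    todo <- todo[!(b1ok & b2ok)]
    iter <- iter + 1L
    stop_if(iter > 2000L, "locus rejection sampling failed to converge")
  }

  l1 <- sample(lens, n_pri, replace = TRUE, prob = ldist)
  pstart <- ifelse(strand == "+", anchor, anchor - l1 + 1L)
  pend <- ifelse(strand == "+", anchor + l1, anchor + 1L)
  pseq <- substring(genome$sequence, pstart + 1L, pend)
  neg <- strand == "-"
  if (any(neg)) pseq[neg] <- revcomp(pseq[neg])

  pid <- sprintf("pi_%06d", seq_len(n_pri))
  out_reads <- data.frame(id = pid, sequence = pseq, count = 1L,
                          stringsAsFactors = FALSE)
  out_aln <- data.frame(id = pid, chrom = genome$name, start = pstart,
                        end = pend, strand = strand, count = 1L,
                        stringsAsFactors = FALSE)
  role <- rep("primary", n_pri)
  partner <- rep(NA_character_, n_pri)

  if (n_pairs > 0L) {
    pi_idx <- seq_len(n_pairs)  # first n_pairs primaries get a partner
    sstrand <- ifelse(strand[pi_idx] == "+", "-", "+")
    b <- ifelse(strand[pi_idx] == "+", anchor[pi_idx] + 9L,
                anchor[pi_idx] - 9L)
    l2 <- sample(lens, n_pairs, replace = TRUE, prob = ldist)
    sstart <- ifelse(sstrand == "+", b, b - l2 + 1L)
    send <- ifelse(sstrand == "+", b + l2, b + 1L)
    sseq <- substring(genome$sequence, sstart + 1L, send)
    sneg <- sstrand == "-"
    if (any(sneg)) sseq[sneg] <- revcomp(sseq[sneg])
    sid <- sprintf("pi_%06d", n_pri + seq_len(n_pairs))
    out_reads <- rbind(out_reads,
                       data.frame(id = sid, sequence = sseq, count = 1L,
                                  stringsAsFactors = FALSE))
    out_aln <- rbind(out_aln,
                     data.frame(id = sid, chrom = genome$name,
                                start = sstart, end = send, strand = sstrand,
                                count = 1L, stringsAsFactors = FALSE))
    role <- c(role, rep("secondary", n_pairs))
    partner[pi_idx] <- sid
    partner <- c(partner, pid[pi_idx])
    category <- c(cat_draw, cat_draw[pi_idx])
  } else {
    category <- cat_draw
  }

  list(reads = out_reads,
       alignments = out_aln,
       truth = data.frame(id = out_reads$id, class = "piRNA",
                          category = category, role = role,
                          partner_id = partner, stringsAsFactors = FALSE))
}
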