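# Positional base biases and the ping-pong overlap signature.

test_that("positional base frequencies are count-weighted and normalized", {
  pm <- positional_base_frequencies(c("TAAA", "TGGG"), k = 4)
  expect_equal(pm["1", "U"], 1.0)
  expect_equal(pm["2", "A"], 0.5)
  expect_true(all(abs(rowSums(pm) - 1) < 1e-9))

  # counts weight the contributions
  pm2 <- positional_base_frequencies(c("TAAA", "GGGG"), counts = c(3, 1),
                                     k = 1)
  expect_equal(pm2["1", "U"], 0.75)

  # shorter sequences only contribute to covered positions
  pm3 <- positional_base_frequencies(c("TT", "AAAA"), k = 4)
  expect_equal(pm3["3", "A"], 1.0)
  expect_error(positional_base_frequencies(character(0), k = 5), "no seq")
})

test_that("random sequences give near-uniform base composition", {
  set.seed(11)
  seqs <- replicate(10000, random_seq(30))
  pm <- positional_base_frequencies(seqs, k = 30)
  expect_true(all(abs(pm - 0.25) < 0.02))
})

test_that("position enrichment matches the hand-computed ratio", {
  pe <- position_enrichment("GGGGGGGGGA", base = "A", k = 10)
  expect_equal(pe$argmax, 10L)
  expect_equal(unname(pe$enrichment[["10"]]), 10)

  flat <- position_enrichment(c("AAAA", "AAAA"), base = "A", k = 4)
  expect_true(all(flat$enrichment == 1))
  expect_equal(flat$argmax, 1L)  # ties break to the smallest position
  expect_error(position_enrichment("GGGG", base = "A", k = 4),
               "does not occur")
})

test_that("first-base fractions by length are exact", {
  seqs <- c(strrep("T", 30), strrep("T", 30), strrep("A", 30),
            strrep("G", 29))
  fb <- first_base_by_length(seqs)
  expect_equal(fb["30", "U"], 2 / 3)
  expect_equal(fb["30", "A"], 1 / 3)
  expect_equal(fb["29", "G"], 1)
  expect_true(all(abs(rowSums(fb) - 1) < 1e-9))
})

test_that("candidate piRNAs prefer U at the first base at every length", {
  g <- simulate_genome(500000, 0.15, 0.01, seed = 3)
  lib <- simulate_library(generator_config(n_reads = 30000), g, "BSB",
                          seed = 3)
  cand <- call_pirna_candidates(lib$reads)
  fb <- first_base_by_length(cand$sequence, cand$count)
  expect_true(all(fb[as.character(27:32), "U"] >= 0.5))
})

test_that("ping-pong overlap geometry follows the 5'-5' rule", {
  aln <- data.frame(id = c("p", "m"), chrom = "chr1",
                    start = c(100L, 91L), end = c(130L, 110L),
                    strand = c("+", "-"), count = 1L)
  pp <- ping_pong_profile(aln)
  expect_equal(unname(pp$overlap_counts[["10"]]), 1)
  expect_equal(sum(pp$overlap_counts), 1)

  # reads on different chromosomes never pair
  aln2 <- aln; aln2$chrom <- c("chr1", "chr2")
  expect_equal(sum(ping_pong_profile(aln2)$overlap_counts), 0)
  expect_equal(ping_pong_profile(aln2)$z10, 0)
  # empty input -> all-zero profile
  expect_equal(ping_pong_profile(aln[0, ])$z10, 0)
})

test_that("the sweep implementation equals the all-pairs oracle", {
  set.seed(9)
  for (rep in 1:3) {
    n <- 120
    aln <- data.frame(
      id = sprintf("r%03d", 1:n),
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      start = sample(0:300, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      count = sample(1:3, n, replace = TRUE))
    aln$end <- aln$start + sample(27:32, n, replace = TRUE)
    pp <- ping_pong_profile(aln)
    expect_equal(pp$overlap_counts, naive_ping_pong(aln))
  }
})

test_that("profile is invariant under strand relabeling with reflection", {
  set.seed(13)
  n <- 80
  aln <- data.frame(id = sprintf("r%03d", 1:n), chrom = "c1",
                    start = sample(0:500, n, replace = TRUE),
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    count = 1L)
  aln$end <- aln$start + 30L
  ref <- aln
  ref$strand <- ifelse(aln$strand == "+", "-", "+")
  G <- 1000L
  ref$start <- G - aln$end
  ref$end <- G - aln$start
  expect_equal(ping_pong_profile(ref)$overlap_counts,
               ping_pong_profile(aln)$overlap_counts)
})

test_that("profiles add over disjoint chromosomes and z10 resists scaling", {
  set.seed(17)
  mk <- function(chrom, n) {
    a <- data.frame(id = paste0(chrom, "_", 1:n), chrom = chrom,
                    start = sample(0:400, n, replace = TRUE),
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    count = sample(1:2, n, replace = TRUE))
    a$end <- a$start + 30L
    a
  }
  a1 <- mk("c1", 60); a2 <- mk("c2", 60)
  both <- ping_pong_profile(rbind(a1, a2))
  expect_equal(both$overlap_counts,
               ping_pong_profile(a1)$overlap_counts +
                 ping_pong_profile(a2)$overlap_counts)

  # uniform count scaling multiplies every bin by c^2, leaving z10 unchanged
  scaled <- rbind(a1, a2)
  scaled$count <- scaled$count * 5L
  pp_s <- ping_pong_profile(scaled)
  expect_equal(pp_s$overlap_counts, both$overlap_counts * 25)
  expect_equal(pp_s$z10, both$z10)
})
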