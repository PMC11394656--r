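# Synthetic-data generator: genome structure, library composition,
# ping-pong pairing geometry, count-matrix truth, and determinism.

test_that("generator_config validates fractions and probabilities", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(q1U = 1.2), "probability")
  expect_error(generator_config(origin_fractions = c(`repeat` = 0.5,
                                                     gene = 0.5,
                                                     other = 0.5)),
               "sum to 1")
  bad_lens <- c(`20` = 0.5, `30` = 0.5)
  expect_error(generator_config(pirna_length_dist = bad_lens), "27")
  expect_error(generator_config(nb_dispersion = -1), "nb_dispersion")
})

test_that("generator_config survives a YAML round trip", {
  cfg <- generator_config(n_reads = 12345L, q1U = 0.9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config_yaml(cfg, path)
  cfg2 <- read_config_yaml(path)
  expect_equal(cfg2$n_reads, cfg$n_reads)
  expect_equal(cfg2$q1U, cfg$q1U)
  expect_equal(cfg2$class_fractions$BSB, cfg$class_fractions$BSB)
})

test_that("simulate_genome hits the requested coverage with disjoint intervals", {
  g0 <- simulate_genome(10000, 0, 0, seed = 1)
  expect_equal(nrow(g0$annotation), 0L)

  g <- simulate_genome(10000, 0.15, 0.01, seed = 1)
  anno <- g$annotation
  rep_cov <- sum(anno$end[anno$category == "repeat"] -
                   anno$start[anno$category == "repeat"]) / g$length
  expect_gte(rep_cov, 0.14)
  expect_lte(rep_cov, 0.16)
  # disjointness across all intervals
  anno <- anno[order(anno$start), ]
  expect_true(all(anno$start[-1] >= anno$end[-nrow(anno)]))
  expect_true(all(anno$start >= 0 & anno$end <= g$length))
  expect_error(simulate_genome(10000, 0.6, 0.4, seed = 1), "0.9")
  expect_error(simulate_genome(500, 0.1, 0.1, seed = 1), "1000")
})

test_that("the generator is deterministic in its seed", {
  g1 <- simulate_genome(20000, 0.15, 0.01, seed = 7)
  g2 <- simulate_genome(20000, 0.15, 0.01, seed = 7)
  expect_identical(g1, g2)
  cfg <- generator_config(n_reads = 2000)
  l1 <- simulate_library(cfg, g1, "BSB", seed = 3)
  l2 <- simulate_library(cfg, g2, "BSB", seed = 3)
  expect_identical(l1, l2)
  m1 <- simulate_count_matrix(cfg, 200, seed = 4)
  m2 <- simulate_count_matrix(cfg, 200, seed = 4)
  expect_identical(m1, m2)
})

test_that("forced 1U bias yields all-U piRNA reads", {
  g <- simulate_genome(50000, 0.15, 0.01, seed = 2)
  cfg <- generator_config(
    class_fractions = list(BSB = c(piRNA = 1)),
    pingpong_fraction = 0, q1U = 1, n_reads = 500)
  lib <- simulate_library(cfg, g, "BSB", seed = 2)
  expect_true(all(substring(lib$reads$sequence, 1, 1) == "T"))
  expect_true(all(lib$truth$role == "primary"))
})

test_that("ping-pong partners overlap by exactly 10 nt at their 5' ends", {
  g <- simulate_genome(100000, 0.15, 0.01, seed = 7)
  cfg <- generator_config(pingpong_fraction = 0.5, n_reads = 10000)
  lib <- simulate_library(cfg, g, "BSB", seed = 7)
  tr <- lib$truth
  sec <- tr[tr$role == "secondary", ]
  expect_gt(nrow(sec), 100)
  # partner relation is symmetric
  expect_identical(tr$partner_id[match(sec$partner_id, tr$id)], sec$id)
  aln <- lib$alignments
  fp <- ifelse(aln$strand == "+", aln$start, aln$end - 1L)
  names(fp) <- aln$id
  s_strand <- aln$strand[match(sec$id, aln$id)]
  a <- ifelse(s_strand == "-", fp[sec$partner_id], fp[sec$id])
  b <- ifelse(s_strand == "-", fp[sec$id], fp[sec$partner_id])
  overlap <- b - a + 1
  expect_gte(mean(overlap == 10), 0.99)
})

test_that("class truth fractions converge multinomially and reads match the genome", {
  g <- simulate_genome(500000, 0.15, 0.01, seed = 5)
  cfg <- generator_config(n_reads = 100000)
  lib <- simulate_library(cfg, g, "BSB", seed = 5)
  w <- lib$reads$count[match(lib$truth$id, lib$reads$id)]
  total <- sum(w)
  expect_equal(total, cfg$n_reads)
  fr <- cfg$class_fractions$BSB
  for (cls in names(fr)) {
    obs <- sum(w[lib$truth$class == cls]) / total
    sigma <- sqrt(fr[[cls]] * (1 - fr[[cls]]) / total)
    expect_lt(abs(obs - fr[[cls]]), 3 * sigma + 1 / total)
  }
  # genome-derived reads equal the genome substring at their coordinates
  aln <- lib$alignments
  seqs <- substring(g$sequence, aln$start + 1, aln$end)
  neg <- aln$strand == "-"
  seqs[neg] <- rc(seqs[neg])
  expect_identical(lib$reads$sequence[match(aln$id, lib$reads$id)], seqs)
})

test_that("library validation rejects unknown conditions", {
  g <- simulate_genome(50000, 0.15, 0.01, seed = 1)
  expect_error(simulate_library(generator_config(), g, "XXX"),
               "no entry for condition")
})

test_that("count-matrix truth respects de_fraction and de_up_share", {
  cfg0 <- generator_config(de_fraction = 0)
  sim0 <- simulate_count_matrix(cfg0, 500, seed = 3)
  expect_true(all(sim0$truth$de_status == "ns"))

  cfg <- generator_config(de_fraction = 0.2, de_up_share = 0.886)
  sim <- simulate_count_matrix(cfg, 5000, seed = 3)
  tr <- sim$truth
  n_de <- sum(tr$de_status != "ns")
  expect_equal(n_de, 1000L)
  upshare <- sum(tr$de_status == "up") / n_de
  expect_gte(upshare, 0.85)
  expect_lte(upshare, 0.92)
  expect_s3_class(sim$counts, "expression_matrix")
  expect_identical(sim$counts$kind, "count")
})

test_that("true-up piRNAs show the planted fold change in the counts", {
  cfg <- generator_config(de_fraction = 0.2, effect_log2fc = 2,
                          nb_mean = 500, nb_dispersion = 0.05)
  sim <- simulate_count_matrix(cfg, 2000, seed = 6)
  v <- sim$counts$values
  bsb <- rowMeans(v[, sim$counts$condition == "BSB"])
  nbs <- rowMeans(v[, sim$counts$condition == "NBS"])
  up <- sim$truth$de_status == "up"
  ratio <- log2(bsb[up] / nbs[up])
  expect_gte(median(ratio), 1.5)
  expect_lte(median(ratio), 2.5)
})
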