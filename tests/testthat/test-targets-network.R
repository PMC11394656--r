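# Duplex scoring, target prediction, and the bipartite regulatory network.

test_that("perfect and impossible duplexes score at the extremes", {
  set.seed(41)
  window <- random_seq(30)
  mrna <- paste0(random_seq(100), rc(window), random_seq(100))
  ds <- score_duplex(window, mrna)
  expect_equal(ds$best_score, 30)
  expect_equal(ds$seed_matches, 10L)
  expect_equal(ds$site_start, 100L)

  all_a <- score_duplex(strrep("A", 30), strrep("A", 60))
  expect_equal(all_a$best_score, -30)
  expect_equal(all_a$site_start, 0L)  # ties break to the smallest start

  expect_error(score_duplex(strrep("A", 10), strrep("A", 60)), ">= 11")
  expect_error(score_duplex(strrep("A", 30), strrep("A", 20)), "as long")
})

test_that("sliding scorer equals the all-offset oracle", {
  set.seed(9)
  for (rep in 1:5) {
    pirna <- random_seq(30)
    mrna <- random_seq(500)
    expect_equal(score_duplex(pirna, mrna), naive_score_duplex(pirna, mrna))
  }
  # wobble weights are honored: G:U pairs get the wobble weight
  ds <- score_duplex(strrep("G", 15), strrep("T", 40),
                     wobble_weight = 0.25)
  expect_equal(ds$best_score, 15 * 0.25)
})

test_that("target prediction recovers planted sites and is monotone", {
  set.seed(4)
  pirnas <- setNames(replicate(10, random_seq(30)), sprintf("pi%02d", 1:10))
  planted <- names(pirnas)[1:4]
  mrnas <- setNames(lapply(sprintf("m%02d", 1:10), function(i) {
    random_seq(300)
  }), sprintf("m%02d", 1:10))
  for (k in seq_along(planted)) {
    m <- sprintf("m%02d", k)
    mrnas[[m]] <- paste0(substr(mrnas[[m]], 1, 150), rc(pirnas[[planted[k]]]),
                         substr(mrnas[[m]], 151, 300))
  }
  mrnas <- unlist(mrnas)
  hits <- predict_targets(pirnas, mrnas, min_score = 25)
  expect_setequal(paste(hits$pirna, hits$mrna),
                  paste(planted, sprintf("m%02d", seq_along(planted))))

  # monotone in both thresholds
  fewer <- predict_targets(pirnas, mrnas, min_score = 29)
  expect_true(all(paste(fewer$pirna, fewer$mrna) %in%
                    paste(hits$pirna, hits$mrna)))
  none <- predict_targets(pirnas, mrnas, min_score = 25,
                          min_seed_matches = 11)
  expect_equal(nrow(none), 0L)
  expect_equal(nrow(predict_targets(pirnas, character(0), min_score = 0)),
               0L)
})

de_pi <- data.frame(id = sprintf("pi%02d", 1:20),
                    status = rep(c("up", "down"), 10))
de_m <- data.frame(id = c("geneA", "geneB"), status = c("down", "up"))

test_that("network construction enforces DE endpoints and distinct degrees", {
  edges <- data.frame(pirna = sprintf("pi%02d", 1:15), mrna = "geneA",
                      score = 25 + 1:15)
  net <- build_network(edges, de_pi, de_m)
  expect_equal(net$mrna_degree$degree[net$mrna_degree$mrna == "geneA"], 15L)
  expect_identical(unique(net$edges$mrna_status), "down")

  # duplicate edges collapse; degree counts distinct piRNA neighbors
  dup <- rbind(edges, edges[1:5, ])
  net2 <- build_network(dup, de_pi, de_m)
  expect_equal(nrow(net2$edges), 15L)
  expect_equal(sum(net2$mrna_degree$degree), nrow(net2$edges))

  empty <- build_network(edges[0, ], de_pi, de_m)
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(length(empty$pirnas), 0L)

  bad <- data.frame(pirna = "pi99", mrna = "geneA", score = 30)
  expect_error(build_network(bad, de_pi, de_m), "pi99")
  ns_edge <- data.frame(pirna = "pi01", mrna = "geneC", score = 30)
  expect_error(build_network(ns_edge, de_pi, de_m), "geneC")
})

test_that("network exports round-trip and keep the bipartite structure", {
  edges <- data.frame(pirna = c("pi01", "pi02", "pi03"),
                      mrna = c("geneA", "geneA", "geneB"),
                      score = c(27, 26.5, 30))
  net <- build_network(edges, de_pi, de_m)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_identical(readLines(sif),
                   c("pi01 regulates geneA", "pi02 regulates geneA",
                     "pi03 regulates geneB"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back <- import_network_tsv(tsv)
  expect_equal(back$edges, net$edges)
  expect_equal(back$mrna_degree, net$mrna_degree)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_true(igraph::is_bipartite(
    igraph::set_vertex_attr(g, "type",
                            value = as.logical(igraph::V(g)$type))))
  ends <- igraph::as_edgelist(g)
  expect_true(all(ends[, 1] %in% net$pirnas))
  expect_true(all(ends[, 2] %in% net$mrnas))
  expect_error(export_network(net, tsv, "xml"), "arg")
})
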