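write_edges <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("edge lists parse with comments, counts, and weights intact", {
  path <- write_edges(c("# co-functional links",
                        "A\tB\t1.5", "B\tC\t2", "C\tD\t0.25"))
  g <- read_network(path, quiet = TRUE)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  el <- igraph::as_data_frame(g, what = "edges")
  expect_equal(el$weight[el$from == "A" | el$to == "A"], 1.5)
})

test_that("duplicate pairs collapse to the maximum weight with a warning", {
  path <- write_edges(c("A\tB\t1.5", "B\tA\t2.0"))
  expect_warning(g <- read_network(path, quiet = TRUE), "duplicate")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 2.0)
})

test_that("self-loops, malformed lines, and bad weights fail with the line identified", {
  expect_error(read_network(write_edges("A\tA\t1.0"), quiet = TRUE),
               "self-loop.*line 1")
  expect_error(read_network(write_edges(c("A\tB\t1", "C\tD")), quiet = TRUE),
               "line 2")
  expect_error(read_network(write_edges("A\tB\tnope"), quiet = TRUE),
               "non-numeric.*line 1")
  expect_error(read_network(write_edges(c("A\tB\t1", "B\tC\t0")), quiet = TRUE),
               "non-positive.*line 2")
})

test_that("write/read round trip preserves nodes, edges, and weights exactly", {
  nt <- generate_network(small_sim(seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(nt$network, path)
  back <- read_network(path, quiet = TRUE)
  expect_setequal(igraph::V(back)$name, igraph::V(nt$network)$name[
    igraph::degree(nt$network) > 0])
  key <- function(g) {
    el <- igraph::as_data_frame(g, what = "edges")
    o <- order(pmin(el$from, el$to), pmax(el$from, el$to))
    data.frame(a = pmin(el$from, el$to)[o], b = pmax(el$from, el$to)[o],
               w = el$weight[o])
  }
  expect_equal(key(back), key(nt$network))
})

test_that("connected pathway subset keeps only genes linked to another pathway gene", {
  g <- toy_graph(from = c("P1", "P2", "P3", "X"),
                 to = c("P2", "P3", "P1", "P4"),
                 weight = c(1, 1, 1, 1))
  # P1..P3 form a triangle; P4 touches only the non-pathway gene X
  expect_equal(connected_pathway_subset(g, c("P1", "P2", "P3", "P4")),
               c("P1", "P2", "P3"))
  expect_equal(connected_pathway_subset(g, character(0)), character(0))
  expect_equal(connected_pathway_subset(g, c("Z1", "Z2")), character(0))
})

test_that("guide scores are summed LLS over direct guide edges", {
  g <- toy_graph(from = c("X", "X", "Y"), to = c("G1", "G2", "G1"),
                 weight = c(1.5, 2.5, 1.0))
  r <- guide_predict(g, c("G1", "G2"))
  expect_equal(r$gene, c("X", "Y"))
  expect_equal(r$statistic, c(4.0, 1.0))
  expect_equal(r$rank, c(1, 2))
  # a gene with no edge to any guide is absent
  g2 <- igraph::add_vertices(g, 1, name = "Z")
  expect_false("Z" %in% guide_predict(g2, c("G1", "G2"))$gene)
  expect_error(guide_predict(g, c("NOPE")), "none of the guide genes")
  # guides can be kept in the ranking; they then score their guide-guide edges
  g3 <- igraph::add_edges(g, c("G1", "G2"), attr = list(weight = 3))
  r_all <- guide_predict(g3, c("G1", "G2"), exclude_guides = FALSE)
  expect_equal(r_all$statistic[r_all$gene == "G1"], 3)  # its G1-G2 edge only
  expect_false("G1" %in% guide_predict(g3, c("G1", "G2"))$gene)
})

test_that("guide scores match an independent brute-force double loop", {
  withr::with_seed(31, {
    for (i in 1:30) {
      n <- sample(5:40, 1)
      g <- igraph::sample_gnp(n, 0.2)
      igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
      igraph::E(g)$weight <- runif(igraph::ecount(g), 0.5, 4)
      guides <- sample(igraph::V(g)$name, sample(1:4, 1))
      r <- guide_predict(g, guides)
      oracle <- brute_force_guide_scores(g, guides)
      expect_setequal(r$gene, if (length(oracle)) names(oracle) else character(0))
      expect_equal(r$statistic, unname(oracle[r$gene]), tolerance = 1e-12)
    }
  })
})

test_that("deleting one guide edge lowers exactly that gene's score by its weight", {
  nt <- generate_network(small_sim(seed = 17))
  g <- nt$network
  guides <- nt$truth$guide_genes
  r <- guide_predict(g, guides)
  el <- igraph::as_data_frame(g, what = "edges")
  hit <- which(xor(el$to %in% guides, el$from %in% guides))[1]
  gene <- if (el$to[hit] %in% guides) el$from[hit] else el$to[hit]
  w <- el$weight[hit]
  g2 <- igraph::delete_edges(g, hit)
  r2 <- guide_predict(g2, guides)
  s1 <- stats::setNames(r$statistic, r$gene)
  s2 <- stats::setNames(r2$statistic, r2$gene)
  expect_equal(unname(s1[gene] - (if (gene %in% names(s2)) s2[gene] else 0)),
               w, tolerance = 1e-12)
  others <- setdiff(names(s1), gene)
  expect_equal(s2[others], s1[others])
})

test_that("hub p-values are upper-tail hypergeometric with recorded overlap", {
  # star hub H with 3 neighbors, all DEGs, in a 10-gene universe with 4 DEGs
  g <- toy_graph(from = rep("H", 3), to = c("D1", "D2", "D3"),
                 weight = rep(1, 3),
                 isolates = sprintf("I%d", 1:6))
  r <- hub_predict(g, c("D1", "D2", "D3", "I1"), min_degree = 3)
  expect_equal(r$gene, "H")
  expect_equal(r$statistic, 4 / 120, tolerance = 1e-12)  # C(4,3)C(6,0)/C(10,3)
  expect_equal(r$overlap_k, 3L)
  expect_equal(r$neighborhood_n, 3L)
  # zero overlap has p = 1 (the upper tail includes the observed zero)
  r0 <- hub_predict(g, "I1", min_degree = 3)
  expect_equal(r0$statistic, 1)
  # monotone: p strictly decreases as k grows at fixed (N, K, n)
  p_seq <- vapply(0:3, function(k)
    coexcand:::hypergeom_upper_p(k, N = 10, K = 4, n = 3), numeric(1))
  expect_true(all(diff(p_seq) < 0))
})

test_that("hub prediction validates inputs and the universe", {
  g <- toy_graph(from = rep("H", 6), to = sprintf("D%d", 1:6),
                 weight = rep(1, 6))
  expect_error(hub_predict(g, "ABSENT"), "none of the DEGs")
  expect_error(hub_predict(g, "D1", universe = 3), "universe")
  expect_error(hub_predict(g, sprintf("D%d", 1:6), universe = 5), "universe")
})

test_that("top-n truncation re-ranks a prefix and breaks boundary ties lexicographically", {
  r <- mock_ranking(c("g1", "g2", "g3", "g4", "g5", "g6", "g7"), "guide",
                    statistic = c(9, 8, 7, 6, 5, 4, 3))
  expect_equal(nrow(top_n_ranking(r, 20)), 7)
  expect_equal(top_n_ranking(r, 3)$gene, c("g1", "g2", "g3"))
  expect_equal(top_n_ranking(r, 3)$rank, 1:3)
  # a tie at the boundary: ranking construction orders ties by gene id,
  # so truncation keeps the lexicographically smaller gene
  g <- toy_graph(from = c("B", "A", "C"), to = rep("G1", 3),
                 weight = c(2, 2, 5))
  r2 <- guide_predict(g, "G1")
  expect_equal(r2$gene, c("C", "A", "B"))
  expect_equal(top_n_ranking(r2, 2)$gene, c("C", "A"))
})

test_that("rankings survive a TSV round trip", {
  nt <- generate_network(small_sim(seed = 23))
  r <- top_n_ranking(guide_predict(nt$network, nt$truth$guide_genes), 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(r, path)
  back <- read_ranking(path)
  expect_equal(back$gene, r$gene)
  expect_equal(back$statistic, r$statistic)
  expect_equal(attr(back, "approach"), "guide")
})
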