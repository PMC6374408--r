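# fixtures and independent oracles used across test files

# two-genotype expression matrix from per-genotype replicate matrices
toy_expression <- function(case, control) {
  stopifnot(nrow(case) == nrow(control))
  m <- cbind(case, control)
  colnames(m) <- c(paste0("high_", seq_len(ncol(case))),
                   paste0("low_", seq_len(ncol(control))))
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%03d", seq_len(nrow(m)))
  design <- data.frame(
    sample_id = colnames(m),
    genotype = rep(c("high", "low"), c(ncol(case), ncol(control))),
    replicate = c(seq_len(ncol(case)), seq_len(ncol(control))),
    stringsAsFactors = FALSE)
  expression_matrix(m, design)
}

# expression matrix with exact planted log2 effects and fixed replicate
# offsets on the log2 scale (noiseless up to the offsets)
planted_expression <- function(effects, base_log2 = 5,
                               offsets = c(0.01, -0.01, 0)) {
  n <- length(effects)
  case <- 2^(outer(base_log2 + effects, offsets, `+`))
  control <- 2^(outer(rep(base_log2, n), offsets, `+`))
  rownames(case) <- rownames(control) <- sprintf("G%03d", seq_len(n))
  toy_expression(case, control)
}

# weighted undirected graph from an edge data.frame
toy_graph <- function(from, to, weight, isolates = character(0)) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = weight,
               stringsAsFactors = FALSE),
    directed = FALSE)
  if (length(isolates))
    g <- igraph::add_vertices(g, length(isolates), name = isolates)
  g
}

# independent brute-force guide scorer: explicit double loop over
# (gene, guide) pairs, one edge lookup at a time
brute_force_guide_scores <- function(network, guides, exclude_guides = TRUE) {
  nodes <- igraph::V(network)$name
  guides_in <- intersect(guides, nodes)
  targets <- if (exclude_guides) setdiff(nodes, guides) else nodes
  scores <- numeric(0)
  for (g in targets) {
    s <- 0
    for (gu in guides_in) {
      if (g != gu && igraph::are_adjacent(network, g, gu)) {
        e <- igraph::get_edge_ids(network, c(g, gu))
        s <- s + igraph::E(network)$weight[e]
      }
    }
    if (s > 0) scores[g] <- s
  }
  scores
}

# exhaustive hypergeometric upper tail: enumerate every size-n subset of
# 1..N, count those overlapping the first K elements in >= k items
enum_hyper_upper <- function(k, N, K, n) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# rankings assembled directly, for integration tests
mock_ranking <- function(genes, approach, statistic = rev(seq_along(genes))) {
  coexcand:::new_ranking(
    data.frame(gene = genes, statistic = statistic, stringsAsFactors = FALSE),
    approach = approach,
    statistic_type = if (approach == "hub") "p_value" else "score")
}

# minimal fast simulation settings for end-to-end tests
small_sim <- function(seed, ...) {
  args <- list(n_genes = 300, n_pathway = 20, n_guides = 10, n_deg = 40,
               frac_deg_in_pathway = 0.25, p_within = 0.6,
               p_background = 0.01, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
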