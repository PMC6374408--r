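test_that("degenerate probabilities force a complete planted clique and empty background", {
  cfg <- sim_config(n_genes = 100, n_pathway = 10, n_guides = 5,
                    p_within = 1, p_background = 0, n_deg = 10, seed = 1)
  nt <- generate_network(cfg)
  el <- igraph::as_data_frame(nt$network, what = "edges")
  expect_equal(nrow(el), 45)  # choose(10, 2)
  planted <- nt$truth$pathway_genes
  expect_true(all(el$from %in% planted) && all(el$to %in% planted))
  expect_equal(igraph::vcount(nt$network), 100)
})

test_that("generators are deterministic in the seed", {
  cfg <- small_sim(seed = 3)
  a <- generate_network(cfg)
  b <- generate_network(cfg)
  expect_identical(igraph::as_data_frame(a$network, what = "edges"),
                   igraph::as_data_frame(b$network, what = "edges"))
  expect_identical(a$truth, b$truth)
  ea <- generate_expression(cfg, a$truth)
  eb <- generate_expression(cfg, b$truth)
  expect_identical(ea$expression$fpkm, eb$expression$fpkm)
  ref <- setdiff(rownames(ea$expression$fpkm), names(a$truth$deg_genes))[1]
  qa <- generate_qpcr(a$truth, ea$expression, ref, seed = 9)
  qb <- generate_qpcr(b$truth, eb$expression, ref, seed = 9)
  expect_identical(qa$data, qb$data)
  # a different seed changes the draw
  c <- generate_network(small_sim(seed = 4))
  expect_false(identical(igraph::as_data_frame(a$network, "edges"),
                         igraph::as_data_frame(c$network, "edges")))
})

test_that("edge counts fall in the central 99% binomial interval", {
  cfg <- sim_config(n_genes = 1000, n_pathway = 20, n_guides = 10,
                    p_within = 0.8, p_background = 0.005, n_deg = 50, seed = 7)
  nt <- generate_network(cfg)
  el <- igraph::as_data_frame(nt$network, what = "edges")
  planted <- nt$truth$pathway_genes
  within <- el$from %in% planted & el$to %in% planted
  n_within_pairs <- choose(20, 2)
  n_bg_pairs <- choose(1000, 2) - n_within_pairs
  ci_within <- qbinom(c(0.005, 0.995), n_within_pairs, 0.8)
  ci_bg <- qbinom(c(0.005, 0.995), n_bg_pairs, 0.005)
  expect_gte(sum(within), ci_within[1])
  expect_lte(sum(within), ci_within[2])
  expect_gte(sum(!within), ci_bg[1])
  expect_lte(sum(!within), ci_bg[2])
})

test_that("effect placement, guide nesting, and hub recording follow the config", {
  cfg <- small_sim(seed = 11)
  nt <- generate_network(cfg)
  tr <- nt$truth
  expect_length(tr$deg_genes, cfg$n_deg)
  expect_true(all(abs(tr$deg_genes) >= cfg$deg_log2fc_range[1] &
                  abs(tr$deg_genes) <= cfg$deg_log2fc_range[2]))
  n_path_deg <- round(cfg$frac_deg_in_pathway * cfg$n_deg)
  expect_equal(sum(names(tr$deg_genes) %in% tr$pathway_genes), n_path_deg)
  expect_true(all(tr$guide_genes %in% tr$pathway_genes))
  deg_of <- igraph::degree(nt$network, v = tr$pathway_genes)
  expect_setequal(tr$hub_genes, tr$pathway_genes[deg_of >= cfg$hub_min_degree])
})

test_that("generated FPKM and edge weights are strictly positive", {
  cfg <- small_sim(seed = 2)
  nt <- generate_network(cfg)
  expect_true(all(igraph::E(nt$network)$weight > 0))
  ex <- generate_expression(cfg, nt$truth)
  expect_true(all(ex$expression$fpkm > 0))
})

test_that("within-module density exceeds background density on average", {
  dens <- vapply(1:50, function(s) {
    cfg <- sim_config(n_genes = 150, n_pathway = 15, n_guides = 5, n_deg = 10,
                      p_within = 0.3, p_background = 0.05, seed = 1000 + s)
    nt <- generate_network(cfg)
    el <- igraph::as_data_frame(nt$network, what = "edges")
    within <- el$from %in% nt$truth$pathway_genes &
      el$to %in% nt$truth$pathway_genes
    nw <- choose(15, 2)
    c(sum(within) / nw, sum(!within) / (choose(150, 2) - nw))
  }, numeric(2))
  expect_gt(mean(dens[1, ]), mean(dens[2, ]))
})

test_that("noiseless construction links planted effects to downstream fold changes exactly", {
  cfg <- sim_config(n_genes = 50, n_pathway = 5, n_guides = 2, n_deg = 5,
                    frac_deg_in_pathway = 0, deg_log2fc_range = c(3, 3),
                    base_log2fpkm_mean = 5, base_log2fpkm_sd = 0,
                    noise_sd = 0, seed = 21)
  nt <- generate_network(cfg)
  ex <- generate_expression(cfg, nt$truth)
  fpkm <- ex$expression$fpkm
  cs <- paste0("high_", 1:3)
  ct <- paste0("low_", 1:3)
  for (g in names(nt$truth$deg_genes)) {
    expect_equal(floored_log2fc(fpkm[g, cs], fpkm[g, ct]),
                 unname(nt$truth$deg_genes[g]))
  }
  nonplanted <- setdiff(rownames(fpkm), names(nt$truth$deg_genes))[1:5]
  for (g in nonplanted)
    expect_identical(floored_log2fc(fpkm[g, cs], fpkm[g, ct]), 0)
})

test_that("estimated fold changes track planted effects at default settings", {
  cfg <- sim_config(seed = 11)
  nt <- generate_network(cfg)
  ex <- generate_expression(cfg, nt$truth)
  tab <- call_degs(ex$expression)
  est <- tab$log2fc[match(names(nt$truth$deg_genes), tab$gene)]
  mae <- mean(abs(est - nt$truth$deg_genes))
  expect_lt(mae, 0.5)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_guides = 40, n_pathway = 30), "n_guides")
  expect_error(sim_config(n_pathway = 5000, n_genes = 100), "n_pathway")
  expect_error(sim_config(p_within = 1.4), "p_within")
  expect_error(sim_config(lls_within_range = c(4, 2)), "lls_within_range")
  expect_error(sim_config(lls_background_range = c(-1, 2)), "lls_background_range")
  expect_error(sim_config(n_deg = 1e6), "n_deg")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(frac_deg_in_pathway = 1, n_deg = 200, n_pathway = 30),
               "frac_deg_in_pathway")
})

test_that("expression generation rejects a mismatched ground truth", {
  big <- generate_network(small_sim(seed = 1))
  small <- sim_config(n_genes = 50, n_pathway = 5, n_guides = 2, n_deg = 5,
                      seed = 1)
  expect_error(generate_expression(small, big$truth), "universe|planted DEGs")
})

test_that("qPCR generation validates the reference gene", {
  cfg <- small_sim(seed = 6)
  nt <- generate_network(cfg)
  ex <- generate_expression(cfg, nt$truth)
  expect_error(generate_qpcr(nt$truth, ex$expression, "NOPE"), "absent")
  planted <- names(nt$truth$deg_genes)[1]
  expect_error(generate_qpcr(nt$truth, ex$expression, planted), "planted effect")
})

test_that("a constant reference with zero noise yields constant Ct", {
  cfg <- sim_config(n_genes = 30, n_pathway = 4, n_guides = 2, n_deg = 3,
                    frac_deg_in_pathway = 0, base_log2fpkm_sd = 0,
                    noise_sd = 0, seed = 8)
  nt <- generate_network(cfg)
  ex <- generate_expression(cfg, nt$truth)
  ref <- setdiff(rownames(ex$expression$fpkm), names(nt$truth$deg_genes))[1]
  ct <- generate_qpcr(nt$truth, ex$expression, ref, ct_noise_sd = 0, seed = 1)
  ref_ct <- ct$data$ct[ct$data$gene_id == ref]
  expect_equal(diff(range(ref_ct)), 0)
})

test_that("ground truth survives a JSON round trip", {
  nt <- generate_network(small_sim(seed = 13))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(nt$truth, path)
  back <- read_truth(path)
  expect_setequal(back$pathway_genes, nt$truth$pathway_genes)
  expect_setequal(back$guide_genes, nt$truth$guide_genes)
  expect_equal(back$deg_genes[order(names(back$deg_genes))],
               nt$truth$deg_genes[order(names(nt$truth$deg_genes))])
  expect_setequal(back$hub_genes, nt$truth$hub_genes)
})
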