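#' Configuration for an end-to-end candidate-discovery run
#'
#' Bundles the analysis parameters (significance level, fold-change
#' thresholds, top-N cutoff, hub settings, candidacy threshold, reference
#' gene) with either a simulation block (inputs are generated) or a set of
#' input paths (inputs are read from disk).
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; every random stage derives its stream
#'   from it by a fixed offset.
#' @param alpha DEG significance level.
#' @param thresholds nested log2 fold-change thresholds.
#' @param top_n genes kept per prediction approach.
#' @param min_degree minimum hub degree for \code{\link{hub_predict}}.
#' @param hub_universe hypergeometric background size (default: network
#'   size).
#' @param base_threshold threshold defining candidacy.
#' @param require_up restrict candidates to up-regulated genes.
#' @param reference_gene qPCR normalization gene; when NULL and simulating,
#'   the most abundant non-differential gene is chosen.
#' @param ct_intercept,ct_noise_sd synthetic qPCR parameters (cycles).
#' @param simulation a \code{\link{sim_config}}, or NULL when reading
#'   real inputs.
#' @param paths named list of input paths (\code{network},
#'   \code{expression}, \code{sample_sheet}, \code{pathway_genes}, and
#'   optionally \code{ct_table}); ignored when \code{simulation} is given.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir, seed = 1, alpha = 0.05,
                            thresholds = c(2, 3, 4, 5), top_n = 20,
                            min_degree = 5, hub_universe = NULL,
                            base_threshold = 2, require_up = FALSE,
                            reference_gene = NULL, ct_intercept = 35,
                            ct_noise_sd = 0, simulation = sim_config(seed = seed),
                            paths = NULL) {
  if (is.null(simulation)) {
    need <- c("network", "expression", "sample_sheet", "pathway_genes")
    if (is.null(paths) || !all(need %in% names(paths)))
      stop("without a simulation block, 'paths' must name network, expression, sample_sheet and pathway_genes files",
           call. = FALSE)
    missing <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(missing))
      stop(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")),
           call. = FALSE)
  } else if (!inherits(simulation, "sim_config")) {
    simulation <- do.call(sim_config, simulation)
  }
  if (!base_threshold %in% thresholds)
    stop("'base_threshold' must be one of 'thresholds'", call. = FALSE)
  structure(list(out_dir = out_dir, seed = check_count(seed, "seed"),
                 alpha = alpha, thresholds = thresholds, top_n = top_n,
                 min_degree = min_degree, hub_universe = hub_universe,
                 base_threshold = base_threshold, require_up = require_up,
                 reference_gene = reference_gene, ct_intercept = ct_intercept,
                 ct_noise_sd = ct_noise_sd, simulation = simulation,
                 paths = paths),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of \code{\link{pipeline_config}};
#' a nested \code{simulation:} mapping is passed to \code{\link{sim_config}}
#' and a nested \code{paths:} mapping supplies input files.
#'
#' @param path YAML file.
#' @param out_dir,seed optional overrides of the file's values.
#' @return A \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) y$simulation <- do.call(sim_config, y$simulation)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(seed)) y$seed <- seed
  if (!is.null(y$seed) && !is.null(y$simulation)) y$simulation$seed <- y$seed
  do.call(pipeline_config, y)
}

empty_ranking <- function(approach, statistic_type = "score") {
  df <- data.frame(gene = character(0), statistic = numeric(0),
                   stringsAsFactors = FALSE)
  if (approach == "hub") {
    df$overlap_k <- integer(0)
    df$neighborhood_n <- integer(0)
    df$p_adjust <- numeric(0)
  }
  new_ranking(df, approach = approach, statistic_type = statistic_type)
}

run_stage <- function(name, quiet, expr) {
  if (!quiet) message(sprintf("[%s] ...", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full candidate-discovery pipeline
#'
#' Orchestrates simulate (or load) -> DEG calling -> three network
#' prediction approaches -> candidate integration -> qPCR validation, and
#' writes every stage's table to \code{out_dir} together with a versioned
#' \code{summary.json}.  Identical config and seed give byte-identical
#' outputs.  Stage tables on disk use the package's standard TSV/CSV
#' formats, so any downstream stage can be re-run from files alone.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param quiet suppress progress messages.
#' @return The run summary (a list), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config", call. = FALSE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out))
    stop(sprintf("cannot create output directory '%s'", out), call. = FALSE)
  fp <- function(...) file.path(out, ...)

  # -- inputs ---------------------------------------------------------------
  inputs <- run_stage("inputs", quiet, {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      sim$seed <- config$seed
      nt <- generate_network(sim)
      ex <- generate_expression(sim, nt$truth)
      write_network(nt$network, fp("network.tsv"))
      write_expression_matrix(ex$expression, fp("expression.tsv"),
                              fp("samples.csv"))
      writeLines(nt$truth$pathway_genes, fp("pathway_genes.txt"))
      write_truth(nt$truth, fp("truth.json"))
      list(network = nt$network, expression = ex$expression,
           pathway_genes = nt$truth$pathway_genes, truth = nt$truth)
    } else {
      p <- config$paths
      list(network = read_network(p$network, quiet = quiet),
           expression = read_expression_matrix(p$expression, p$sample_sheet),
           pathway_genes = readLines(p$pathway_genes), truth = NULL)
    }
  })
  truth <- inputs$truth
  net <- inputs$network
  em <- inputs$expression
  if (!quiet)
    message(sprintf("[inputs] %d genes x %d samples; network %d nodes, %d edges; %d pathway genes",
                    nrow(em$fpkm), ncol(em$fpkm), igraph::vcount(net),
                    igraph::ecount(net), length(inputs$pathway_genes)))

  # -- DEG calling ----------------------------------------------------------
  deg_table <- run_stage("deg", quiet, {
    tab <- call_degs(em, alpha = config$alpha, thresholds = config$thresholds)
    write_deg_table(tab, fp("deg_table.tsv"))
    tab
  })
  deg_counts <- lapply(config$thresholds, function(t)
    direction_summary(deg_table, t)$n_total)
  names(deg_counts) <- paste0("deg", config$thresholds)
  base_sum <- direction_summary(deg_table, config$base_threshold)
  if (!quiet)
    message(sprintf("[deg] counts: %s; fraction up at base threshold: %.3f",
                    paste(sprintf("%s=%d", names(deg_counts), unlist(deg_counts)),
                          collapse = ", "), base_sum$fraction_up))

  # -- network prediction ---------------------------------------------------
  degs_base <- deg_genes_at(deg_table, config$base_threshold)
  rankings <- run_stage("predict", quiet, {
    guides <- connected_pathway_subset(net, inputs$pathway_genes)
    r_guide <- if (length(guides))
      top_n_ranking(guide_predict(net, guides), config$top_n)
    else empty_ranking("guide")
    deg_seeds <- intersect(guides, degs_base)
    r_deg_guide <- if (length(deg_seeds))
      top_n_ranking(guide_predict(net, deg_seeds, approach = "deg_guide"),
                    config$top_n)
    else empty_ranking("deg_guide")
    r_hub <- if (length(intersect(degs_base, igraph::V(net)$name)))
      top_n_ranking(hub_predict(net, degs_base,
                                min_degree = config$min_degree,
                                universe = config$hub_universe),
                    config$top_n)
    else empty_ranking("hub", "p_value")
    write_ranking(r_guide, fp("ranking_guide.tsv"))
    write_ranking(r_deg_guide, fp("ranking_deg_guide.tsv"))
    write_ranking(r_hub, fp("ranking_hub.tsv"))
    if (!quiet)
      message(sprintf("[predict] guides: %d connected (%d DEG seeds); top lists: guide %d, deg_guide %d, hub %d",
                      length(guides), length(deg_seeds), nrow(r_guide),
                      nrow(r_deg_guide), nrow(r_hub)))
    list(r_guide, r_deg_guide, r_hub)
  })

  # -- integration ----------------------------------------------------------
  candidates <- run_stage("integrate", quiet, {
    tab <- integrate_predictions(rankings, deg_table,
                                 base_threshold = config$base_threshold,
                                 require_up = config$require_up)
    export_candidates(tab, fp("candidates.tsv"), fp("candidates.summary.json"))
    tab
  })
  cand_sum <- candidate_summary(candidates)
  if (!quiet)
    message(sprintf("[integrate] %d candidates, %d with support >= 2",
                    cand_sum$n_candidates, cand_sum$n_support_ge2))

  # -- qPCR validation ------------------------------------------------------
  qpcr_sum <- run_stage("qpcr", quiet, {
    if (nrow(candidates) == 0L) {
      NULL
    } else if (!is.null(config$simulation)) {
      ref <- config$reference_gene %||% {
        nondeg <- setdiff(rownames(em$fpkm), names(truth$deg_genes))
        ab <- rowMeans(em$fpkm[nondeg, , drop = FALSE])
        nondeg[order(-ab, nondeg)][1]
      }
      ct <- generate_qpcr(truth, em, ref,
                          ct_intercept = config$ct_intercept,
                          ct_noise_sd = config$ct_noise_sd,
                          seed = config$seed + 2L,
                          genes = candidates$gene)
      write_ct_table(ct, fp("ct_table.csv"))
      fc <- stats::setNames(deg_table$log2fc, deg_table$gene)
      val <- qpcr_validate(ct, fc)
      write_tsv_file(val, fp("qpcr_validation.tsv"))
      concordance(fc[candidates$gene],
                  stats::setNames(val$rq, val$gene))
    } else if (!is.null(config$paths$ct_table)) {
      ref <- config$reference_gene
      if (is.null(ref))
        stop("a reference gene must be named when supplying a Ct table",
             call. = FALSE)
      ct <- read_ct_table(config$paths$ct_table, config$paths$sample_sheet, ref)
      fc <- stats::setNames(deg_table$log2fc, deg_table$gene)
      val <- qpcr_validate(ct, fc)
      write_tsv_file(val, fp("qpcr_validation.tsv"))
      shared <- intersect(candidates$gene, val$gene)
      if (length(shared))
        concordance(fc[shared], stats::setNames(val$rq, val$gene)[shared])
      else NULL
    } else {
      NULL
    }
  })
  if (!quiet && !is.null(qpcr_sum))
    message(sprintf("[qpcr] %d/%d candidates sign-concordant (%.3f)",
                    qpcr_sum$n_agree, qpcr_sum$n_genes, qpcr_sum$fraction))

  # -- summary --------------------------------------------------------------
  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    n_genes = nrow(em$fpkm),
    n_samples = ncol(em$fpkm),
    network = list(nodes = igraph::vcount(net), edges = igraph::ecount(net)),
    deg = c(deg_counts,
            list(fraction_up_base = base_sum$fraction_up,
                 base_threshold = config$base_threshold)),
    ranking_lengths = list(guide = nrow(rankings[[1]]),
                           deg_guide = nrow(rankings[[2]]),
                           hub = nrow(rankings[[3]])),
    candidates = cand_sum,
    qpcr_concordance = qpcr_sum
  )
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  if (!quiet) message(sprintf("[done] summary written to %s", fp("summary.json")))
  invisible(summary)
}
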