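#' Settings for the planted-module synthetic benchmark
#'
#' The generator emulates the statistical structure of the study design the
#' package targets: a sparse weighted co-functional network over tens of
#' thousands of genes in which a known biosynthetic pathway forms a densely
#' connected module, and a two-genotype RNA-seq experiment with three
#' biological replicates per genotype in which a subset of genes carries
#' large planted log2 effects, partly inside the pathway module.
#'
#' Gene identifiers are zero-padded synthetic strings (\code{"G000001"}
#' ...), so lexicographic order is stable and tie-breaking downstream is
#' deterministic.  The planted pathway occupies the first \code{n_pathway}
#' identifiers and the designated guides the first \code{n_guides} of
#' those; labels are arbitrary in a synthetic benchmark, so deterministic
#' placement loses no generality.
#'
#' @param n_genes number of genes in the universe.
#' @param n_pathway number of planted pathway-module genes.
#' @param n_guides number of planted genes designated as known guide genes
#'   (\code{n_guides <= n_pathway}).
#' @param p_within edge probability between two planted pathway genes.
#' @param p_background edge probability for every other gene pair.
#' @param lls_within_range,lls_background_range positive intervals from
#'   which edge log-likelihood scores (LLS) are drawn uniformly for planted
#'   and background edges.
#' @param n_replicates biological replicates per genotype.
#' @param n_deg number of genes given a planted differential effect.
#' @param deg_log2fc_range interval of planted absolute log2 effects.
#' @param frac_deg_in_pathway fraction of planted DEGs drawn from the
#'   planted pathway module (\code{round(frac_deg_in_pathway * n_deg)} genes,
#'   which must not exceed \code{n_pathway}).
#' @param base_log2fpkm_mean,base_log2fpkm_sd mean and sd of the Gaussian
#'   baseline on the log2 FPKM scale (log-normal FPKM).
#' @param noise_sd replicate-level Gaussian noise sd on the log2 scale.
#' @param hub_min_degree realized-degree threshold above which a planted
#'   pathway gene is recorded as a planted hub in the ground truth.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 2000, n_pathway = 30, n_guides = 15,
                       p_within = 0.6, p_background = 0.003,
                       lls_within_range = c(2, 4),
                       lls_background_range = c(0.5, 1.5),
                       n_replicates = 3, n_deg = 200,
                       deg_log2fc_range = c(2, 6),
                       frac_deg_in_pathway = 0.1,
                       base_log2fpkm_mean = 6, base_log2fpkm_sd = 1.5,
                       noise_sd = 0.25, hub_min_degree = 5, seed = 1) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", min = 2L),
    n_pathway = check_count(n_pathway, "n_pathway", min = 0L),
    n_guides = check_count(n_guides, "n_guides", min = 0L),
    p_within = check_prob(p_within, "p_within"),
    p_background = check_prob(p_background, "p_background"),
    lls_within_range = check_range(lls_within_range, "lls_within_range"),
    lls_background_range = check_range(lls_background_range, "lls_background_range"),
    n_replicates = check_count(n_replicates, "n_replicates", min = 2L),
    n_deg = check_count(n_deg, "n_deg", min = 0L),
    deg_log2fc_range = check_range(deg_log2fc_range, "deg_log2fc_range"),
    frac_deg_in_pathway = check_prob(frac_deg_in_pathway, "frac_deg_in_pathway"),
    base_log2fpkm_mean = check_number(base_log2fpkm_mean, "base_log2fpkm_mean"),
    base_log2fpkm_sd = check_number(base_log2fpkm_sd, "base_log2fpkm_sd", min = 0),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    hub_min_degree = check_count(hub_min_degree, "hub_min_degree", min = 1L),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$seed >= 2^31 - 2)
    stop("'seed' must be below 2^31 - 2", call. = FALSE)
  if (cfg$n_guides > cfg$n_pathway)
    stop("'n_guides' must not exceed 'n_pathway'", call. = FALSE)
  if (cfg$n_pathway > cfg$n_genes)
    stop("'n_pathway' must not exceed 'n_genes'", call. = FALSE)
  if (cfg$n_deg > cfg$n_genes)
    stop("'n_deg' must not exceed 'n_genes'", call. = FALSE)
  n_path_deg <- round(cfg$frac_deg_in_pathway * cfg$n_deg)
  if (n_path_deg > cfg$n_pathway)
    stop("'frac_deg_in_pathway' places more DEGs in the pathway than 'n_pathway' allows",
         call. = FALSE)
  if (cfg$n_deg - n_path_deg > cfg$n_genes - cfg$n_pathway)
    stop("'n_deg' exceeds the number of available non-pathway genes", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_ids <- function(n) sprintf("G%06d", seq_len(n))

#' Generate a synthetic co-expression network with a planted module
#'
#' Draws an undirected simple graph over \code{n_genes} genes.  Each pair of
#' planted pathway genes receives an edge independently with probability
#' \code{p_within} and, when present, a weight uniform in
#' \code{lls_within_range}; every other pair uses \code{p_background} and
#' \code{lls_background_range}.  The returned ground truth also fixes the
#' planted differential-expression effects (signed log2 effects, uniform in
#' magnitude over \code{deg_log2fc_range} with random sign) so that the
#' matching expression matrix can be generated afterwards, and records as
#' planted hubs the pathway genes whose realized degree reaches
#' \code{hub_min_degree}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with elements \code{network} (an igraph object whose edges
#'   carry a \code{weight} attribute, the LLS) and \code{truth}, a
#'   \code{"ground_truth"} list with \code{pathway_genes},
#'   \code{guide_genes}, \code{deg_genes} (named numeric vector of signed
#'   log2 effects), and \code{hub_genes}.
#' @examples
#' net <- generate_network(sim_config(n_genes = 100, n_pathway = 10,
#'                                    n_guides = 5, n_deg = 10, seed = 1))
#' igraph::ecount(net$network)
#' @export
generate_network <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, config)
  n <- config$n_genes
  np <- config$n_pathway
  ids <- sim_gene_ids(n)

  sim <- withr::with_seed(config$seed, {
    from <- vector("list", n - 1L)
    to <- vector("list", n - 1L)
    within <- vector("list", n - 1L)
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      pw <- (i <= np) & (j <= np)
      p <- ifelse(pw, config$p_within, config$p_background)
      hit <- stats::runif(n - i) < p
      if (any(hit)) {
        from[[i]] <- rep.int(i, sum(hit))
        to[[i]] <- j[hit]
        within[[i]] <- pw[hit]
      }
    }
    from <- unlist(from)
    to <- unlist(to)
    within <- unlist(within)
    m <- length(from)
    w <- numeric(m)
    if (any(within))
      w[within] <- stats::runif(sum(within), config$lls_within_range[1],
                                config$lls_within_range[2])
    if (any(!within))
      w[!within] <- stats::runif(sum(!within), config$lls_background_range[1],
                                 config$lls_background_range[2])

    # planted differential effects, fixed here so network and expression
    # share one ground truth
    n_path_deg <- round(config$frac_deg_in_pathway * config$n_deg)
    path_idx <- seq_len(np)
    deg_idx <- c(if (n_path_deg > 0) sample(path_idx, n_path_deg),
                 if (config$n_deg - n_path_deg > 0)
                   sample(setdiff(seq_len(n), path_idx), config$n_deg - n_path_deg))
    effects <- numeric(0)
    if (length(deg_idx)) {
      mag <- stats::runif(length(deg_idx), config$deg_log2fc_range[1],
                          config$deg_log2fc_range[2])
      sgn <- ifelse(stats::runif(length(deg_idx)) < 0.5, -1, 1)
      effects <- stats::setNames(mag * sgn, ids[deg_idx])
      effects <- effects[order(names(effects))]
    }
    list(from = from, to = to, weight = w, effects = effects)
  })

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(sim$from))
    g <- igraph::add_edges(g, rbind(sim$from, sim$to),
                           attr = list(weight = sim$weight))

  pathway <- ids[seq_len(np)]
  deg_of_pathway <- if (np > 0) igraph::degree(g, v = pathway) else integer(0)
  truth <- structure(list(
    pathway_genes = pathway,
    guide_genes = ids[seq_len(config$n_guides)],
    deg_genes = sim$effects,
    hub_genes = pathway[deg_of_pathway >= config$hub_min_degree]
  ), class = "ground_truth")
  list(network = g, truth = truth)
}

#' Generate an FPKM matrix matching a simulated ground truth
#'
#' Every gene gets a Gaussian baseline on the log2 scale
#' (\code{base_log2fpkm_mean}, \code{base_log2fpkm_sd}); genes with a
#' planted effect add it in the case ("high") genotype only; every
#' gene/sample cell adds independent Gaussian noise with sd
#' \code{noise_sd}.  FPKM is 2 to that sum, hence strictly positive
#' (log-normal, i.e. multiplicative noise).
#'
#' @inheritParams generate_network
#' @param truth the \code{"ground_truth"} produced by
#'   \code{\link{generate_network}} under the same \code{config}.
#' @return A list with elements \code{expression}
#'   (an \code{\link{expression_matrix}}; case genotype \code{"high"},
#'   control \code{"low"}) and \code{truth} (unchanged).
#' @export
generate_expression <- function(config, truth) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, config)
  if (!inherits(truth, "ground_truth"))
    stop("'truth' must come from generate_network()", call. = FALSE)
  n <- config$n_genes
  ids <- sim_gene_ids(n)
  if (!all(names(truth$deg_genes) %in% ids) ||
      !all(truth$pathway_genes %in% ids))
    stop("'truth' gene universe does not match 'config'", call. = FALSE)
  if (length(truth$deg_genes) != config$n_deg)
    stop("'truth' carries a different number of planted DEGs than 'config'",
         call. = FALSE)

  nrep <- config$n_replicates
  samples <- c(paste0("high_", seq_len(nrep)), paste0("low_", seq_len(nrep)))
  genotype <- rep(c("high", "low"), each = nrep)

  log2fpkm <- withr::with_seed(config$seed + 1L, {
    base <- stats::rnorm(n, config$base_log2fpkm_mean, config$base_log2fpkm_sd)
    effect <- numeric(n)
    names(base) <- ids
    effect[match(names(truth$deg_genes), ids)] <- truth$deg_genes
    mu <- matrix(base, n, 2L * nrep) +
      outer(effect, as.numeric(genotype == "high"))
    mu + matrix(stats::rnorm(n * 2L * nrep, 0, config$noise_sd), n, 2L * nrep)
  })
  fpkm <- 2^log2fpkm
  dimnames(fpkm) <- list(ids, samples)
  design <- data.frame(sample_id = samples, genotype = genotype,
                       replicate = rep(seq_len(nrep), 2L),
                       stringsAsFactors = FALSE)
  list(expression = expression_matrix(fpkm, design), truth = truth)
}

#' Generate a synthetic qRT-PCR Ct table from simulated expression
#'
#' Ct values follow the standard log-linear amplification model
#' \code{Ct = ct_intercept - log2(FPKM) + noise}: one more doubling of
#' template lowers the cycle threshold by one cycle.  The reference gene
#' (the Actin analog) must be present in the expression matrix and must not
#' carry a planted effect.
#'
#' @param truth a \code{"ground_truth"}.
#' @param expression an \code{\link{expression_matrix}} from
#'   \code{\link{generate_expression}}.
#' @param reference_gene gene id used for ddCt normalization downstream.
#' @param ct_intercept cycle-threshold intercept (cycles at 1 FPKM).
#' @param ct_noise_sd technical noise sd in cycles (0 for noiseless tables).
#' @param seed integer seed.
#' @param genes target genes to assay (default: all genes in
#'   \code{expression}); the reference gene is always included.
#' @return A \code{\link{ct_table}}.
#' @export
generate_qpcr <- function(truth, expression, reference_gene,
                          ct_intercept = 35, ct_noise_sd = 0, seed = 1,
                          genes = NULL) {
  if (!inherits(expression, "expression_matrix"))
    stop("'expression' must be an expression_matrix", call. = FALSE)
  all_genes <- rownames(expression$fpkm)
  if (length(reference_gene) != 1L || !reference_gene %in% all_genes)
    stop(sprintf("reference gene '%s' absent from the expression matrix",
                 as.character(reference_gene)[1]), call. = FALSE)
  if (reference_gene %in% names(truth$deg_genes))
    stop(sprintf("reference gene '%s' carries a planted effect and cannot normalize",
                 reference_gene), call. = FALSE)
  check_number(ct_intercept, "ct_intercept")
  check_number(ct_noise_sd, "ct_noise_sd", min = 0)
  genes <- genes %||% all_genes
  if (!all(genes %in% all_genes))
    stop("'genes' contains ids absent from the expression matrix", call. = FALSE)
  genes <- union(genes, reference_gene)
  genes <- genes[order(genes)]

  sub <- expression$fpkm[genes, , drop = FALSE]
  samples <- colnames(sub)
  ct <- withr::with_seed(check_count(seed, "seed"), {
    ct_intercept - log2(sub) +
      matrix(stats::rnorm(length(sub), 0, ct_noise_sd), nrow(sub), ncol(sub))
  })
  df <- data.frame(
    sample_id = rep(samples, each = length(genes)),
    gene_id = rep(genes, times = length(samples)),
    ct = as.vector(ct),
    stringsAsFactors = FALSE
  )
  ct_table(df, expression$design, reference_gene,
           case = expression$case, control = expression$control)
}

#' Write the simulation ground truth as JSON
#'
#' @param truth a \code{"ground_truth"}.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(
    pathway_genes = truth$pathway_genes,
    guide_genes = truth$guide_genes,
    deg_genes = as.list(truth$deg_genes),
    hub_genes = truth$hub_genes
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth JSON written by \code{write_truth}
#'
#' @param path path to the truth JSON.
#' @return A \code{"ground_truth"} list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    pathway_genes = as.character(x$pathway_genes),
    guide_genes = as.character(x$guide_genes),
    deg_genes = unlist(x$deg_genes) %||% stats::setNames(numeric(0), character(0)),
    hub_genes = as.character(x$hub_genes)
  ), class = "ground_truth")
}
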