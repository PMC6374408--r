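#' Read a weighted co-expression network from a 3-column edge list
#'
#' Expects tab-separated lines \code{geneA<TAB>geneB<TAB>LLS}; lines
#' starting with \code{#} and blank lines are ignored.  The LLS
#' (log-likelihood score) quantifies evidence that the two genes share
#' function and must be a positive number.  Duplicate pairs (in either
#' orientation) are collapsed keeping the maximum weight, with a warning;
#' self-loops, malformed lines and non-positive weights are errors that
#' name the offending line.
#'
#' @param path path to the edge-list TSV.
#' @param quiet suppress the node/edge count message.
#' @return An undirected simple igraph graph with a positive \code{weight}
#'   edge attribute.
#' @export
read_network <- function(path, quiet = FALSE) {
  if (!file.exists(path))
    stop(sprintf("network file '%s' does not exist", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("edge list contains no data lines", call. = FALSE)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop(sprintf("malformed edge line %d: expected 3 tab-separated fields, found %d",
                 idx[which(nf != 3L)[1]], nf[nf != 3L][1]), call. = FALSE)
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  a <- m[, 1]
  b <- m[, 2]
  w <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(w))
    stop(sprintf("non-numeric weight on line %d", idx[which(is.na(w))[1]]),
         call. = FALSE)
  if (any(w <= 0))
    stop(sprintf("non-positive weight on line %d (LLS must be > 0)",
                 idx[which(w <= 0)[1]]), call. = FALSE)
  if (any(a == b))
    stop(sprintf("self-loop on line %d: gene '%s' linked to itself",
                 idx[which(a == b)[1]], a[a == b][1]), call. = FALSE)

  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warning(sprintf("%d duplicate edge line(s) collapsed keeping the maximum weight",
                    n_dup), call. = FALSE)
    w <- stats::ave(w, key, FUN = max)
    first <- !duplicated(key)
    a <- a[first]; b <- b[first]; w <- w[first]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, weight = w, stringsAsFactors = FALSE),
    directed = FALSE)
  if (!quiet)
    message(sprintf("read_network: %d data lines -> %d genes, %d edges",
                    length(idx), igraph::vcount(g), igraph::ecount(g)))
  g
}

#' Write a network as a 3-column edge list TSV
#'
#' @param network an igraph graph with a \code{weight} edge attribute.
#' @param path output path.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_data_frame(network, what = "edges")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# geneA\tgeneB\tLLS", con)
  utils::write.table(el[, c("from", "to", "weight")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pathway genes connected to each other in the network
#'
#' Returns the pathway genes that have at least one edge to another
#' pathway gene, i.e. the non-isolated nodes of the induced subgraph.
#' Pathway genes absent from the network are excluded.  This mirrors the
#' standard step of trimming a homolog list down to its network-connected
#' core before using it as a guide set.
#'
#' @param network an igraph co-expression network.
#' @param pathway_genes character vector of pathway gene ids.
#' @return Sorted character vector.
#' @export
connected_pathway_subset <- function(network, pathway_genes) {
  present <- intersect(pathway_genes, igraph::V(network)$name)
  if (length(present) == 0L) return(character(0))
  sub <- igraph::induced_subgraph(network, present)
  sort(igraph::V(sub)$name[igraph::degree(sub) > 0])
}

new_ranking <- function(df, approach, statistic_type) {
  rownames(df) <- NULL
  df <- cbind(data.frame(approach = rep(approach, nrow(df)),
                         rank = seq_len(nrow(df)),
                         stringsAsFactors = FALSE),
              df)
  structure(df, class = c("gene_ranking", "data.frame"),
            approach = approach, statistic_type = statistic_type)
}

#' Rank genes by summed log-likelihood score to a guide set
#'
#' Guilt-by-association scoring: each gene's score is the sum of LLS
#' weights over its direct edges to guide genes.  Genes with no edge to any
#' guide (score 0) are omitted.  Ordering is by descending score, ties
#' broken by lexicographic gene id.  By default the guides themselves are
#' excluded, since the goal is new pathway members.
#'
#' @param network an igraph co-expression network with \code{weight}.
#' @param guides non-empty character vector of guide gene ids; at least one
#'   must be present in the network.
#' @param exclude_guides drop guide genes from the ranking (default TRUE).
#' @param approach label stored in the ranking (\code{"guide"} by default;
#'   use \code{"deg_guide"} when seeding with DEGs).
#' @return A \code{data.frame} of class \code{"gene_ranking"} with columns
#'   \code{approach}, \code{rank}, \code{gene}, \code{statistic} (the
#'   summed LLS).
#' @examples
#' g <- igraph::graph_from_data_frame(
#'   data.frame(from = c("X", "X", "Y"), to = c("G1", "G2", "G1"),
#'              weight = c(1.5, 2.5, 1.0)), directed = FALSE)
#' guide_predict(g, c("G1", "G2"))
#' @export
guide_predict <- function(network, guides, exclude_guides = TRUE,
                          approach = "guide") {
  if (length(guides) == 0L)
    stop("'guides' must be non-empty", call. = FALSE)
  nodes <- igraph::V(network)$name
  guides_in <- intersect(guides, nodes)
  if (length(guides_in) == 0L)
    stop("none of the guide genes is present in the network", call. = FALSE)
  el <- igraph::as_data_frame(network, what = "edges")
  score <- stats::setNames(numeric(length(nodes)), nodes)
  to_guide <- el$to %in% guides_in
  from_guide <- el$from %in% guides_in
  if (any(to_guide)) {
    add <- tapply(el$weight[to_guide], el$from[to_guide], sum)
    score[names(add)] <- score[names(add)] + add
  }
  if (any(from_guide)) {
    add <- tapply(el$weight[from_guide], el$to[from_guide], sum)
    score[names(add)] <- score[names(add)] + add
  }
  if (exclude_guides) score <- score[!names(score) %in% guides]
  score <- score[score > 0]
  ord <- order(-score, names(score))
  new_ranking(data.frame(gene = names(score)[ord],
                         statistic = unname(score)[ord],
                         stringsAsFactors = FALSE),
              approach = approach, statistic_type = "score")
}

# one-sided upper-tail hypergeometric p-value: probability of drawing at
# least k special items in n draws from a universe of N with K special
hypergeom_upper_p <- function(k, N, K, n) {
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Rank hub genes by DEG enrichment of their neighborhoods
#'
#' Every gene with degree at least \code{min_degree} is treated as the
#' central hub of the subnetwork formed by its direct neighbors.  The
#' overlap between the neighbors and the DEG set is scored with a one-sided
#' upper-tail hypergeometric test (equivalently one-sided Fisher's exact):
#' given \code{universe} genes of which K are DEGs, the p-value is the
#' probability that a random neighborhood of the hub's size contains at
#' least the observed number of DEGs.  Hubs are ranked by ascending
#' p-value, ties broken by larger overlap then gene id.  A
#' Benjamini-Hochberg adjusted column is included for reporting but plays
#' no role in the ranking.
#'
#' @param network an igraph co-expression network.
#' @param deg_genes character vector of DEG ids; the ones present in the
#'   network define K.
#' @param min_degree minimum hub degree (small neighborhoods give
#'   degenerate p-values).
#' @param universe hypergeometric background size; defaults to the number
#'   of network genes.
#' @return A \code{"gene_ranking"} with columns \code{approach},
#'   \code{rank}, \code{gene}, \code{statistic} (the p-value),
#'   \code{overlap_k}, \code{neighborhood_n}, \code{p_adjust}.
#' @export
hub_predict <- function(network, deg_genes, min_degree = 5, universe = NULL) {
  nodes <- igraph::V(network)$name
  deg_in <- intersect(deg_genes, nodes)
  if (length(deg_in) == 0L)
    stop("none of the DEGs is present in the network", call. = FALSE)
  min_degree <- check_count(min_degree, "min_degree", min = 1L)
  degree <- igraph::degree(network)
  K <- length(deg_in)
  N <- if (is.null(universe)) length(nodes) else check_count(universe, "universe", min = 1L)
  if (N < K)
    stop("'universe' is smaller than the number of DEGs in the network", call. = FALSE)
  if (length(degree) && N < max(degree))
    stop("'universe' is smaller than the largest hub neighborhood", call. = FALSE)

  # overlap k per node = number of incident edges whose other end is a DEG
  el <- igraph::as_data_frame(network, what = "edges")
  is_deg <- stats::setNames(nodes %in% deg_in, nodes)
  k <- stats::setNames(numeric(length(nodes)), nodes)
  if (nrow(el)) {
    add1 <- tapply(as.numeric(is_deg[el$to]), el$from, sum)
    add2 <- tapply(as.numeric(is_deg[el$from]), el$to, sum)
    k[names(add1)] <- k[names(add1)] + add1
    k[names(add2)] <- k[names(add2)] + add2
  }
  hubs <- nodes[degree >= min_degree]
  if (length(hubs) == 0L)
    return(new_ranking(data.frame(gene = character(0), statistic = numeric(0),
                                  overlap_k = integer(0),
                                  neighborhood_n = integer(0),
                                  p_adjust = numeric(0)),
                       approach = "hub", statistic_type = "p_value"))
  n <- degree[hubs]
  kk <- k[hubs]
  p <- hypergeom_upper_p(kk, N = N, K = K, n = n)
  padj <- stats::p.adjust(p, method = "BH")
  ord <- order(p, -kk, hubs)
  new_ranking(data.frame(gene = hubs[ord],
                         statistic = unname(p)[ord],
                         overlap_k = as.integer(unname(kk)[ord]),
                         neighborhood_n = as.integer(unname(n)[ord]),
                         p_adjust = unname(padj)[ord],
                         stringsAsFactors = FALSE),
              approach = "hub", statistic_type = "p_value")
}

#' Keep the top n entries of a ranking
#'
#' The ranking's documented tie-break (statistic, then overlap for hub
#' rankings, then lexicographic gene id) was applied when the ranking was
#' built, so the top n is a simple prefix; ranks are renumbered from 1.
#'
#' @param ranking a \code{"gene_ranking"}.
#' @param n number of entries to keep (>= 1).
#' @return A \code{"gene_ranking"} of at most n rows.
#' @export
top_n_ranking <- function(ranking, n = 20) {
  if (!inherits(ranking, "gene_ranking"))
    stop("'ranking' must be a gene_ranking", call. = FALSE)
  n <- check_count(n, "n", min = 1L)
  out <- utils::head(as.data.frame(ranking), n)
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("gene_ranking", "data.frame"),
            approach = attr(ranking, "approach"),
            statistic_type = attr(ranking, "statistic_type"))
}

#' Read / write a ranking TSV
#'
#' Columns: approach, rank, gene, statistic, plus overlap_k,
#' neighborhood_n, p_adjust for hub rankings.
#'
#' @param ranking a \code{"gene_ranking"}.
#' @param path file path.
#' @export
write_ranking <- function(ranking, path) {
  write_tsv_file(as.data.frame(ranking), path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  tab <- read_tsv_file(path)
  approach <- if (nrow(tab)) tab$approach[1] else "unknown"
  structure(tab, class = c("gene_ranking", "data.frame"),
            approach = approach,
            statistic_type = if ("overlap_k" %in% names(tab)) "p_value" else "score")
}
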