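#' Integrate approach rankings with the DEG table into a candidate table
#'
#' Mirrors the integration logic of multi-approach candidate discovery:
#' each approach contributes its top-N genes (pass rankings through
#' \code{\link{top_n_ranking}} first), and a gene becomes a candidate when
#' it appears in at least one top list AND is a DEG at
#' \code{base_threshold}.  DEG filtering happens after top-N selection, so
#' the per-approach DEG counts reported by \code{\link{export_candidates}}
#' correspond to "how many of this approach's top 20 are DEGs".
#'
#' @param rankings list of \code{"gene_ranking"} objects with distinct
#'   approach labels (top-N already applied).
#' @param deg_table a \code{"deg_table"}; ranked genes absent from it are
#'   treated as non-DEG.
#' @param base_threshold log2 fold-change threshold defining candidacy
#'   (must be one of the table's thresholds).
#' @param require_up if TRUE, keep only candidates up-regulated in the
#'   case genotype (off by default: up-regulation is an observation, not a
#'   filter).
#' @return A \code{data.frame} of class \code{"candidate_table"}: columns
#'   \code{gene}, \code{approaches} (comma-joined), \code{support},
#'   \code{log2fc}, \code{p_value}, \code{deg_threshold} (largest threshold
#'   passed), \code{direction}, and per-approach \code{<approach>_rank} /
#'   \code{<approach>_statistic} columns (NA when the gene is not in that
#'   approach's list).  Sorted by descending support, then best (smallest)
#'   per-approach rank, then gene id.
#' @export
integrate_predictions <- function(rankings, deg_table, base_threshold = 2,
                                  require_up = FALSE) {
  if (!is.list(rankings) || length(rankings) == 0L)
    stop("'rankings' must be a non-empty list of gene_ranking objects", call. = FALSE)
  labels <- vapply(rankings, function(r) attr(r, "approach") %||% "unknown", "")
  if (anyDuplicated(labels))
    stop("rankings carry duplicate approach labels", call. = FALSE)
  names(rankings) <- labels

  degs <- deg_genes_at(deg_table, base_threshold)
  ranked <- unique(unlist(lapply(rankings, function(r) r$gene)))
  cand <- intersect(ranked, degs)
  thresholds <- attr(deg_table, "thresholds") %||%
    sort(as.integer(sub("^deg", "", grep("^deg[0-9]+$", names(deg_table), value = TRUE))))

  if (length(cand) == 0L) {
    out <- data.frame(gene = character(0), approaches = character(0),
                      support = integer(0), log2fc = numeric(0),
                      p_value = numeric(0), deg_threshold = integer(0),
                      direction = character(0), stringsAsFactors = FALSE)
    for (lab in labels) {
      out[[paste0(lab, "_rank")]] <- integer(0)
      out[[paste0(lab, "_statistic")]] <- numeric(0)
    }
    return(structure(out, class = c("candidate_table", "data.frame"),
                     approaches = labels, base_threshold = base_threshold))
  }

  per_app <- lapply(rankings, function(r) {
    i <- match(cand, r$gene)
    list(rank = r$rank[i], statistic = r$statistic[i])
  })
  in_app <- vapply(per_app, function(x) !is.na(x$rank), logical(length(cand)))
  in_app <- matrix(in_app, nrow = length(cand),
                   dimnames = list(cand, labels))
  support <- as.integer(rowSums(in_app))
  approaches <- apply(in_app, 1L, function(row) paste(labels[row], collapse = ","))

  di <- match(cand, deg_table$gene)
  deg_threshold <- vapply(di, function(i) {
    passed <- thresholds[vapply(thresholds, function(t)
      isTRUE(deg_table[[paste0("deg", t)]][i]), logical(1))]
    if (length(passed)) max(passed) else NA_integer_
  }, integer(1))

  out <- data.frame(gene = cand,
                    approaches = unname(approaches),
                    support = support,
                    log2fc = deg_table$log2fc[di],
                    p_value = deg_table$p_value[di],
                    deg_threshold = deg_threshold,
                    direction = deg_table$direction[di],
                    stringsAsFactors = FALSE)
  for (lab in labels) {
    out[[paste0(lab, "_rank")]] <- per_app[[lab]]$rank
    out[[paste0(lab, "_statistic")]] <- per_app[[lab]]$statistic
  }
  if (require_up) out <- out[out$direction == "up", , drop = FALSE]

  rank_cols <- paste0(labels, "_rank")
  best_rank <- suppressWarnings(
    apply(as.matrix(out[, rank_cols, drop = FALSE]), 1L, min, na.rm = TRUE))
  if (nrow(out)) {
    out <- out[order(-out$support, best_rank, out$gene), , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, class = c("candidate_table", "data.frame"),
            approaches = labels, base_threshold = base_threshold)
}

candidate_summary <- function(table) {
  labels <- attr(table, "approaches") %||% character(0)
  per_approach <- lapply(labels, function(lab) {
    sum(!is.na(table[[paste0(lab, "_rank")]]))
  })
  names(per_approach) <- labels
  list(
    n_candidates = nrow(table),
    n_support_ge2 = sum(table$support >= 2),
    deg_candidates_per_approach = per_approach,
    n_up = sum(table$direction == "up")
  )
}

#' Export the candidate table as TSV plus a JSON summary
#'
#' The summary records the total candidate count, the count supported by
#' two or more approaches, the number of DEG candidates contributed by
#' each approach, and the up-regulated count.
#'
#' @param table a \code{"candidate_table"}.
#' @param path TSV output path.
#' @param summary_path JSON output path (default: \code{path} with a
#'   \code{.summary.json} suffix).
#' @return The summary list, invisibly.
#' @export
export_candidates <- function(table, path,
                              summary_path = paste0(path, ".summary.json")) {
  write_tsv_file(as.data.frame(table), path)
  s <- candidate_summary(table)
  jsonlite::write_json(s, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(s)
}

#' Read back a candidate table written by \code{export_candidates}
#'
#' @param path TSV path.
#' @return A \code{"candidate_table"}.
#' @export
read_candidates <- function(path) {
  tab <- read_tsv_file(path)
  labels <- sub("_rank$", "", grep("_rank$", names(tab), value = TRUE))
  structure(tab, class = c("candidate_table", "data.frame"),
            approaches = labels)
}
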