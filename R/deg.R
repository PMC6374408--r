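#' Floored log2 fold change between two replicate groups
#'
#' FPKM values below 1 are raised to 1 before averaging within each group
#' (value-level flooring); the statistic is
#' \code{log2(mean(floored case) / mean(floored control))}.  Flooring keeps
#' ratios between barely-detected genes from producing enormous fold
#' changes; it also makes the statistic exactly 0 whenever both groups sit
#' entirely below 1 FPKM.  The statistic is antisymmetric: swapping the
#' groups negates it.
#'
#' @param case_values,control_values non-empty numeric vectors of
#'   non-negative FPKM values (replicates of the case and control genotype).
#' @return A single number, positive when the case genotype is higher.
#' @examples
#' floored_log2fc(c(8, 8, 8), c(2, 2, 2))      # 2
#' floored_log2fc(c(0.3, 0.2, 0.9), c(0.5, 0.1, 0.05))  # 0: all floored
#' @export
floored_log2fc <- function(case_values, control_values) {
  for (v in list(case_values, control_values)) {
    if (length(v) == 0L)
      stop("replicate value vectors must be non-empty", call. = FALSE)
    if (any(v < 0) || anyNA(v))
      stop("FPKM values must be non-negative and non-missing", call. = FALSE)
  }
  log2(mean(pmax(case_values, 1)) / mean(pmax(control_values, 1)))
}

#' Replicate-level significance test for one gene
#'
#' Two-sided two-sample Student's t-test with pooled variance, applied by
#' default to log2 of the floored FPKM values (multiplicative noise is
#' roughly Gaussian on the log scale).  Degenerate inputs with zero pooled
#' variance return p = 1 when the group means are equal and p = 0 when they
#' differ, so that constant replicates never produce an undefined statistic.
#'
#' @inheritParams floored_log2fc
#' @param transform \code{"log2_floored"} (default) tests
#'   \code{log2(pmax(value, 1))}; \code{"raw"} tests the values as given.
#' @return p-value in [0, 1].
#' @export
replicate_test <- function(case_values, control_values,
                           transform = c("log2_floored", "raw")) {
  transform <- match.arg(transform)
  if (length(case_values) < 2L || length(control_values) < 2L)
    stop("each group needs at least 2 replicates", call. = FALSE)
  if (transform == "log2_floored") {
    case_values <- log2(pmax(case_values, 1))
    control_values <- log2(pmax(control_values, 1))
  }
  pooled_t_p(case_values, control_values)
}

#' Call differentially expressed genes at nested fold-change thresholds
#'
#' For every gene, computes the floored log2 fold change (case over
#' control), a pooled-variance t-test p-value on log2 floored FPKM, and
#' flags DEG status at each threshold t in \code{thresholds}: a gene passes
#' at t iff \code{|log2fc| >= t} and \code{p < alpha}.  The flags are
#' downward-nested by construction (passing at 5 implies passing at 4, 3,
#' 2).  \code{direction} is \code{"up"}/\code{"down"} relative to the case
#' genotype for genes passing the smallest threshold, otherwise
#' \code{"none"}.
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param alpha significance level in (0, 1).
#' @param thresholds integer log2 fold-change thresholds.
#' @param transform scale on which the t-test runs; see
#'   \code{\link{replicate_test}}.
#' @return A \code{data.frame} of class \code{"deg_table"} with columns
#'   \code{gene}, \code{mean_floored_case}, \code{mean_floored_control},
#'   \code{log2fc}, \code{p_value}, one logical column \code{deg<t>} per
#'   threshold, and \code{direction}.
#' @export
call_degs <- function(em, alpha = 0.05, thresholds = c(2, 3, 4, 5),
                      transform = c("log2_floored", "raw")) {
  if (!inherits(em, "expression_matrix"))
    stop("'em' must be an expression_matrix", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
  transform <- match.arg(transform)
  thresholds <- sort(unique(as.integer(thresholds)))
  if (length(thresholds) == 0L || any(thresholds <= 0))
    stop("'thresholds' must be positive integers", call. = FALSE)

  fl <- pmax(em$fpkm, 1)
  cs <- case_samples(em)
  ct <- control_samples(em)
  mean_case <- rowMeans(fl[, cs, drop = FALSE])
  mean_control <- rowMeans(fl[, ct, drop = FALSE])
  log2fc <- log2(mean_case / mean_control)

  test_mat <- if (transform == "log2_floored") log2(fl) else em$fpkm
  p <- row_pooled_t_p(test_mat[, cs, drop = FALSE], test_mat[, ct, drop = FALSE])

  out <- data.frame(gene = rownames(em$fpkm),
                    mean_floored_case = unname(mean_case),
                    mean_floored_control = unname(mean_control),
                    log2fc = unname(log2fc),
                    p_value = unname(p),
                    stringsAsFactors = FALSE)
  for (t in thresholds)
    out[[paste0("deg", t)]] <- abs(out$log2fc) >= t & out$p_value < alpha
  base <- paste0("deg", thresholds[1])
  out$direction <- ifelse(!out[[base]], "none",
                          ifelse(out$log2fc > 0, "up", "down"))
  rownames(out) <- NULL
  structure(out, class = c("deg_table", "data.frame"),
            alpha = alpha, thresholds = thresholds)
}

deg_genes_at <- function(table, threshold) {
  col <- paste0("deg", threshold)
  if (!col %in% names(table))
    stop(sprintf("threshold %s is not part of this DEG table", threshold),
         call. = FALSE)
  table$gene[table[[col]]]
}

#' Count DEGs and the up-regulated fraction at one threshold
#'
#' @param table a \code{"deg_table"} from \code{\link{call_degs}}.
#' @param threshold one of the table's log2 fold-change thresholds.
#' @return A list with \code{n_total}, \code{n_up}, and
#'   \code{fraction_up} (\code{n_up / n_total}; 0 when no DEGs).
#' @export
direction_summary <- function(table, threshold) {
  genes <- deg_genes_at(table, threshold)
  sel <- table$gene %in% genes
  n_total <- sum(sel)
  n_up <- sum(sel & table$log2fc > 0)
  list(n_total = n_total, n_up = n_up,
       fraction_up = if (n_total == 0) 0 else n_up / n_total)
}

#' Read / write a DEG table TSV
#'
#' Columns: gene, mean_floored_case, mean_floored_control, log2fc, p_value,
#' one deg<t> flag per threshold, direction.
#'
#' @param table a \code{"deg_table"}.
#' @param path file path.
#' @export
write_deg_table <- function(table, path) {
  write_tsv_file(as.data.frame(table), path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  tab <- read_tsv_file(path)
  deg_cols <- grep("^deg[0-9]+$", names(tab), value = TRUE)
  for (col in deg_cols) tab[[col]] <- as.logical(tab[[col]])
  thresholds <- sort(as.integer(sub("^deg", "", deg_cols)))
  structure(tab, class = c("deg_table", "data.frame"), thresholds = thresholds)
}
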