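#' Construct a replicated two-genotype expression matrix
#'
#' Bundles an FPKM matrix (genes in rows, samples in columns) with a sample
#' design assigning every sample to one of two genotypes.  FPKM is a
#' unit-free normalized abundance; values must be non-negative.  The "case"
#' genotype is the one in which positive log2 fold changes mean
#' up-regulation (here the high-metabolite genotype), the "control" genotype
#' is the comparison baseline.
#'
#' @param fpkm numeric matrix of FPKM values with unique rownames (gene ids)
#'   and colnames (sample ids).
#' @param design data.frame with columns \code{sample_id}, \code{genotype},
#'   \code{replicate}; one row per column of \code{fpkm}.
#' @param case,control the genotype labels in \code{design$genotype} playing
#'   the case and control roles (defaults \code{"high"} / \code{"low"}).
#' @return An object of class \code{"expression_matrix"}: a list with
#'   elements \code{fpkm}, \code{design}, \code{case}, \code{control}.
#' @examples
#' m <- matrix(2^rnorm(12, 5), 2, 6,
#'             dimnames = list(c("G1", "G2"), paste0("s", 1:6)))
#' d <- data.frame(sample_id = paste0("s", 1:6),
#'                 genotype = rep(c("high", "low"), each = 3),
#'                 replicate = rep(1:3, 2))
#' em <- expression_matrix(m, d)
#' @export
expression_matrix <- function(fpkm, design, case = "high", control = "low") {
  if (!is.matrix(fpkm) || !is.numeric(fpkm))
    stop("'fpkm' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(fpkm)) || anyDuplicated(rownames(fpkm)))
    stop("'fpkm' must have unique gene rownames", call. = FALSE)
  if (is.null(colnames(fpkm)) || anyDuplicated(colnames(fpkm)))
    stop("'fpkm' must have unique sample colnames", call. = FALSE)
  if (any(fpkm < 0) || anyNA(fpkm))
    stop("FPKM values must be non-negative and non-missing", call. = FALSE)
  req <- c("sample_id", "genotype", "replicate")
  if (!is.data.frame(design) || !all(req %in% names(design)))
    stop("'design' needs columns sample_id, genotype, replicate", call. = FALSE)
  design <- design[, req]
  design$sample_id <- as.character(design$sample_id)
  design$genotype <- as.character(design$genotype)
  if (!setequal(design$sample_id, colnames(fpkm)) ||
      nrow(design) != ncol(fpkm))
    stop("every sample in 'fpkm' must have exactly one design entry", call. = FALSE)
  design <- design[match(colnames(fpkm), design$sample_id), ]
  rownames(design) <- NULL
  for (lev in c(case, control)) {
    if (sum(design$genotype == lev) < 2L)
      stop(sprintf("genotype '%s' needs at least 2 samples", lev), call. = FALSE)
  }
  if (!all(design$genotype %in% c(case, control)))
    stop("design contains genotypes other than the case/control labels", call. = FALSE)
  structure(list(fpkm = fpkm, design = design, case = case, control = control),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (case '%s': %d, control '%s': %d)\n",
              nrow(x$fpkm), ncol(x$fpkm),
              x$case, sum(x$design$genotype == x$case),
              x$control, sum(x$design$genotype == x$control)))
  invisible(x)
}

case_samples <- function(em) em$design$sample_id[em$design$genotype == em$case]
control_samples <- function(em) em$design$sample_id[em$design$genotype == em$control]

#' Read / write an expression matrix and its sample sheet
#'
#' The expression TSV has a first column \code{gene} followed by one column
#' per sample; the sample sheet is a CSV with columns \code{sample_id},
#' \code{genotype}, \code{replicate}.
#'
#' @param expr_path path to the expression TSV.
#' @param sheet_path path to the sample-sheet CSV.
#' @inheritParams expression_matrix
#' @return \code{read_expression_matrix} returns an
#'   \code{\link{expression_matrix}}; the writers return their paths
#'   invisibly.
#' @export
read_expression_matrix <- function(expr_path, sheet_path,
                                   case = "high", control = "low") {
  tab <- read_tsv_file(expr_path)
  if (names(tab)[1] != "gene")
    stop("expression TSV must have 'gene' as its first column", call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  design <- utils::read.csv(sheet_path, stringsAsFactors = FALSE)
  expression_matrix(m, design, case = case, control = control)
}

#' @rdname read_expression_matrix
#' @param em an \code{\link{expression_matrix}}.
#' @export
write_expression_matrix <- function(em, expr_path, sheet_path) {
  df <- data.frame(gene = rownames(em$fpkm), em$fpkm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, expr_path)
  utils::write.csv(em$design, sheet_path, row.names = FALSE, quote = FALSE)
  invisible(c(expr_path, sheet_path))
}
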