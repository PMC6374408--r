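#' Construct a qRT-PCR Ct table
#'
#' Long-format cycle-threshold measurements, one row per (sample, gene)
#' reading, with the replicated two-genotype design attached and a named
#' reference gene (the Actin analog) used for ddCt normalization.  When a
#' sample/gene combination appears several times (technical replicates),
#' downstream functions average the readings to one Ct per sample first,
#' keeping significance testing at the biological-replicate level.
#'
#' @param data data.frame with columns \code{sample_id}, \code{gene_id},
#'   \code{ct} (finite positive cycles).
#' @param design data.frame with columns \code{sample_id}, \code{genotype},
#'   \code{replicate}.
#' @param reference_gene gene id measured in every sample.
#' @param case,control genotype labels (defaults \code{"high"}/\code{"low"}).
#' @return A list of class \code{"ct_table"}.
#' @export
ct_table <- function(data, design, reference_gene,
                     case = "high", control = "low") {
  req <- c("sample_id", "gene_id", "ct")
  if (!is.data.frame(data) || !all(req %in% names(data)))
    stop("'data' needs columns sample_id, gene_id, ct", call. = FALSE)
  data <- data[, req]
  data$sample_id <- as.character(data$sample_id)
  data$gene_id <- as.character(data$gene_id)
  if (anyNA(data$ct) || any(!is.finite(data$ct)) || any(data$ct <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)
  if (!all(data$sample_id %in% design$sample_id))
    stop("Ct table contains samples absent from the design", call. = FALSE)
  samples <- unique(data$sample_id)
  ref_samples <- unique(data$sample_id[data$gene_id == reference_gene])
  if (!all(samples %in% ref_samples))
    stop(sprintf("reference gene '%s' is not measured in every sample",
                 reference_gene), call. = FALSE)
  design <- design[design$sample_id %in% samples,
                   c("sample_id", "genotype", "replicate")]
  for (lev in c(case, control)) {
    if (sum(design$genotype == lev) < 2L)
      stop(sprintf("genotype '%s' needs at least 2 biological replicates", lev),
           call. = FALSE)
  }
  structure(list(data = data, design = design, reference_gene = reference_gene,
                 case = case, control = control),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d readings, %d genes, %d samples (reference '%s')\n",
              nrow(x$data), length(unique(x$data$gene_id)),
              length(unique(x$data$sample_id)), x$reference_gene))
  invisible(x)
}

# mean Ct per sample for one gene (averages technical replicates)
sample_ct <- function(tab, gene) {
  rows <- tab$data[tab$data$gene_id == gene, ]
  if (nrow(rows) == 0L)
    stop(sprintf("gene '%s' has no Ct measurements", gene), call. = FALSE)
  tapply(rows$ct, rows$sample_id, mean)
}

#' Relative quantification by the 2^-ddCt (Livak) method
#'
#' For each sample, dCt = Ct(gene) - Ct(reference); ddCt is the mean dCt of
#' the case genotype minus the mean dCt of the control genotype, and the
#' relative quantity is \code{rq = 2^-ddCt} (amplification efficiency fixed
#' at 2 per the standard assumption).  An rq above 1 means the gene is more
#' abundant in the case genotype.  Because the reference is subtracted
#' within each sample, any sample-wide Ct offset cancels.
#'
#' @param table a \code{\link{ct_table}}.
#' @param gene target gene id (must be measured in every sample where the
#'   reference is).
#' @return A list with \code{rq}, \code{delta_delta_ct},
#'   \code{delta_ct_case}, \code{delta_ct_control}.
#' @export
relative_quantity <- function(table, gene) {
  if (!inherits(table, "ct_table"))
    stop("'table' must be a ct_table", call. = FALSE)
  ref <- sample_ct(table, table$reference_gene)
  tgt <- sample_ct(table, gene)
  samples <- names(tgt)
  if (!all(samples %in% names(ref)))
    stop("reference measurements missing for some samples", call. = FALSE)
  dct <- tgt - ref[samples]
  geno <- table$design$genotype[match(samples, table$design$sample_id)]
  dcase <- unname(dct[geno == table$case])
  dctrl <- unname(dct[geno == table$control])
  if (length(dcase) == 0L || length(dctrl) == 0L)
    stop("both genotypes must be measured for the target gene", call. = FALSE)
  ddct <- mean(dcase) - mean(dctrl)
  list(rq = 2^(-ddct), delta_delta_ct = ddct,
       delta_ct_case = dcase, delta_ct_control = dctrl)
}

#' Student's t-test on per-sample dCt values
#'
#' Two-sided pooled-variance t-test comparing the case and control dCt
#' distributions, with the same degenerate zero-variance convention as the
#' DEG module (p = 1 for equal means, 0 otherwise).
#'
#' @param delta_ct_case,delta_ct_control numeric vectors of per-sample dCt
#'   (>= 2 each).
#' @return p-value in [0, 1].
#' @export
qpcr_test <- function(delta_ct_case, delta_ct_control) {
  pooled_t_p(delta_ct_case, delta_ct_control)
}

#' Sign concordance between RNA-seq fold changes and qPCR quantities
#'
#' A gene agrees when the sign of its RNA-seq log2 fold change equals the
#' sign of log2(rq); rq = 1 (log2 rq = 0) agrees only with log2fc = 0.
#'
#' @param rnaseq_log2fc named numeric vector of RNA-seq log2 fold changes.
#' @param qpcr_rq named numeric vector of positive qPCR relative
#'   quantities.
#' @return A list with \code{n_genes}, \code{n_agree}, \code{fraction}.
#' @export
concordance <- function(rnaseq_log2fc, qpcr_rq) {
  shared <- intersect(names(rnaseq_log2fc), names(qpcr_rq))
  if (length(shared) == 0L)
    stop("no genes shared between the RNA-seq and qPCR results", call. = FALSE)
  agree <- sign(rnaseq_log2fc[shared]) == sign(log2(qpcr_rq[shared]))
  list(n_genes = length(shared), n_agree = sum(agree),
       fraction = mean(agree))
}

#' Per-gene qPCR validation table
#'
#' Computes rq, ddCt and the dCt t-test for every target gene in the Ct
#' table (reference excluded) and, when RNA-seq log2 fold changes are
#' supplied, flags sign concordance.
#'
#' @param table a \code{\link{ct_table}}.
#' @param rnaseq_log2fc optional named numeric vector of RNA-seq log2 fold
#'   changes for (a superset of) the assayed genes.
#' @return data.frame with columns \code{gene}, \code{rq},
#'   \code{delta_delta_ct}, \code{p_value}, and (when fold changes are
#'   given) \code{rnaseq_log2fc}, \code{concordant_with_rnaseq}.
#' @export
qpcr_validate <- function(table, rnaseq_log2fc = NULL) {
  genes <- sort(setdiff(unique(table$data$gene_id), table$reference_gene))
  rows <- lapply(genes, function(g) {
    rq <- relative_quantity(table, g)
    data.frame(gene = g, rq = rq$rq, delta_delta_ct = rq$delta_delta_ct,
               p_value = qpcr_test(rq$delta_ct_case, rq$delta_ct_control),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), rq = numeric(0),
               delta_delta_ct = numeric(0), p_value = numeric(0),
               stringsAsFactors = FALSE)
  if (!is.null(rnaseq_log2fc)) {
    out$rnaseq_log2fc <- unname(rnaseq_log2fc[out$gene])
    out$concordant_with_rnaseq <-
      sign(out$rnaseq_log2fc) == sign(log2(out$rq))
  }
  rownames(out) <- NULL
  out
}

#' Read / write a Ct table CSV
#'
#' The CSV has columns \code{sample_id}, \code{gene_id}, \code{ct}; the
#' design comes from the shared sample sheet.
#'
#' @param path Ct CSV path.
#' @param sheet_path sample-sheet CSV path.
#' @inheritParams ct_table
#' @export
read_ct_table <- function(path, sheet_path, reference_gene,
                          case = "high", control = "low") {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  design <- utils::read.csv(sheet_path, stringsAsFactors = FALSE)
  ct_table(data, design, reference_gene, case = case, control = control)
}

#' @rdname read_ct_table
#' @param table a \code{\link{ct_table}}.
#' @export
write_ct_table <- function(table, path) {
  utils::write.csv(table$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
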