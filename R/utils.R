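# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar checks that name the offending field in the error message
check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", field, min), call. = FALSE)
  as.integer(x)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", field), call. = FALSE)
  as.numeric(x)
}

check_range <- function(x, field, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] > x[2])
    stop(sprintf("'%s' must be a numeric interval c(lower, upper) with lower <= upper",
                 field), call. = FALSE)
  if (positive && x[1] <= 0)
    stop(sprintf("'%s' must be strictly positive", field), call. = FALSE)
  as.numeric(x)
}

check_number <- function(x, field, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop(sprintf("'%s' must be a single number >= %s", field, format(min)), call. = FALSE)
  as.numeric(x)
}

# two-sided pooled-variance Student's t-test with the degenerate-variance
# convention: zero pooled variance returns p = 1 for equal means, 0 otherwise
pooled_t_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 values for the replicate t-test", call. = FALSE)
  d <- mean(x) - mean(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2L)
  if (sp2 == 0)
    return(if (d == 0) 1 else 0)
  tstat <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tstat), df = n1 + n2 - 2L)
}

# vectorised version over matrix rows; xm/ym are genes x replicates
row_pooled_t_p <- function(xm, ym) {
  n1 <- ncol(xm)
  n2 <- ncol(ym)
  if (n1 < 2L || n2 < 2L)
    stop("each genotype needs at least 2 replicates", call. = FALSE)
  m1 <- rowMeans(xm)
  m2 <- rowMeans(ym)
  ss1 <- rowSums((xm - m1)^2)
  ss2 <- rowSums((ym - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2L)
  d <- m1 - m2
  p <- ifelse(d == 0, 1, 0)
  ok <- sp2 > 0
  tstat <- d[ok] / sqrt(sp2[ok] * (1 / n1 + 1 / n2))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2L)
  p
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", ...)
}
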