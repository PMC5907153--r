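#' Impute missing expression values with the per-gene mean
#'
#' Every missing entry is replaced by the mean of that gene's observed values;
#' observed entries are left untouched.  A gene with no observed value at all
#' is an error (there is nothing to impute from).
#'
#' @param expr An [expression_matrix()].
#' @return The imputed [expression_matrix()]; idempotent on complete input.
#' @examples
#' m <- matrix(c(1, NA, 3, 4, 5, 6), 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' impute_missing(expression_matrix(m))$values
#' @export
impute_missing <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  all_na <- rowSums(!is.na(v)) == 0
  if (any(all_na))
    stop("gene(s) with all values missing: ",
         paste(expr$gene_ids[all_na], collapse = ", "))
  miss <- which(is.na(v), arr.ind = TRUE)
  if (nrow(miss)) {
    gm <- rowMeans(v, na.rm = TRUE)
    v[miss] <- gm[miss[, 1]]
  }
  expr$values <- v
  expr
}

#' Select genes differentially expressed between two conditions
#'
#' For every shared gene a two-sided Welch t test and a two-sided asymptotic
#' Kolmogorov-Smirnov test compare its values across the two sample groups.
#' The p values of each test family are Benjamini-Hochberg adjusted across
#' genes separately, and genes with both adjusted p values strictly below
#' `alpha` are returned, in the input gene order.  Genes constant in both
#' conditions cannot be tested and are excluded with a warning.
#'
#' @param expr_a,expr_b [expression_matrix()] objects over the same gene
#'   universe (order may differ; `expr_b` is realigned).  No missing values.
#' @param alpha Significance threshold on the adjusted p values, in \[0, 1).
#' @return Character vector of selected gene IDs.  The operation is symmetric
#'   in its first two arguments.
#' @export
filter_differential_genes <- function(expr_a, expr_b, alpha = 0.01) {
  stopifnot(inherits(expr_a, "expression_matrix"),
            inherits(expr_b, "expression_matrix"))
  if (!setequal(expr_a$gene_ids, expr_b$gene_ids))
    stop("the two expression matrices must share one gene universe")
  if (anyNA(expr_a$values) || anyNA(expr_b$values))
    stop("missing values present; run impute_missing() first")
  if (alpha < 0 || alpha >= 1) stop("'alpha' must lie in [0, 1)")
  genes <- expr_a$gene_ids
  vb <- expr_b$values[genes, , drop = FALSE]
  va <- expr_a$values
  n <- length(genes)
  p_t <- p_ks <- rep(NA_real_, n)
  const <- logical(n)
  for (i in seq_len(n)) {
    x <- va[i, ]; y <- vb[i, ]
    if (var(x) == 0 && var(y) == 0) {
      const[i] <- TRUE
      next
    }
    p_t[i] <- tryCatch(t.test(x, y, var.equal = FALSE)$p.value,
                       error = function(e) NA_real_)
    p_ks[i] <- suppressWarnings(ks.test(x, y, exact = FALSE)$p.value)
  }
  if (any(const))
    warning(sum(const), " gene(s) constant in both conditions excluded: ",
            paste(genes[const][seq_len(min(5, sum(const)))], collapse = ", "),
            if (sum(const) > 5) ", ..." else "")
  ok <- !is.na(p_t) & !is.na(p_ks)
  q_t <- q_ks <- rep(NA_real_, n)
  q_t[ok] <- p.adjust(p_t[ok], method = "BH")
  q_ks[ok] <- p.adjust(p_ks[ok], method = "BH")
  sel <- ok & q_t < alpha & q_ks < alpha
  genes[which(sel)]
}

#' Restrict an expression matrix to a gene list
#'
#' Keeps the rows whose gene ID is in `keep`, preserving the original row
#' order.  An empty intersection is an error.
#'
#' @param expr An [expression_matrix()].
#' @param keep Character vector of gene IDs to retain.
#' @return The restricted [expression_matrix()].
#' @export
restrict_to_genes <- function(expr, keep) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!length(keep)) stop("'keep' must be nonempty")
  sel <- expr$gene_ids %in% keep
  if (!any(sel))
    stop("no gene in 'keep' occurs in the expression matrix")
  expression_matrix(expr$values[sel, , drop = FALSE], condition = expr$condition)
}
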