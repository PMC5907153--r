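#' Correlation set container
#'
#' A symmetric genes x genes matrix of (possibly transformed) correlations
#' together with a stage tag recording how far along the network-construction
#' chain it is: `raw` Pearson r, `z` after the Fisher transform,
#' `normalized-z` after standardization, `normalized-r` after mapping back.
#' The diagonal is structural (r = 1) and excluded from every quantile or
#' normalization computation.
#'
#' @param r Symmetric numeric matrix with gene IDs as dimnames.
#' @param stage One of `"raw"`, `"z"`, `"normalized-z"`, `"normalized-r"`.
#' @return An object of class `correlation_set`.
#' @export
correlation_set <- function(r, stage = c("raw", "z", "normalized-z", "normalized-r")) {
  stage <- match.arg(stage)
  if (!is.matrix(r) || nrow(r) != ncol(r))
    stop("'r' must be a square matrix")
  if (is.null(rownames(r)))
    stop("'r' must carry gene IDs as dimnames")
  if (max(abs(r - t(r))) > 1e-10)
    stop("'r' must be symmetric")
  structure(list(r = r, genes = rownames(r), stage = stage),
            class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(sprintf("correlation_set (%s): %d genes\n", x$stage, length(x$genes)))
  invisible(x)
}

#' Pairwise Pearson correlation of all genes
#'
#' Standard Pearson correlation for every gene pair across samples.  Genes with
#' zero variance have undefined correlations; these are set to 0 with a
#' warning.  The diagonal is set to 1 but treated as structural downstream.
#'
#' @param expr An [expression_matrix()] without missing values, >= 3 samples.
#' @return A [correlation_set()] at stage `"raw"`.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3), g2 = c(1, 3, 2))
#' colnames(m) <- paste0("s", 1:3)
#' pearson_matrix(expression_matrix(m))$r
#' @export
pearson_matrix <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (anyNA(expr$values))
    stop("missing values present; run impute_missing() first")
  if (ncol(expr$values) < 3)
    stop("at least 3 samples are required")
  sds <- apply(expr$values, 1, sd)
  zero <- sds == 0
  r <- suppressWarnings(cor(t(expr$values)))
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s); their correlations set to 0: ",
            paste(expr$gene_ids[zero][seq_len(min(5, sum(zero)))], collapse = ", "))
    r[zero, ] <- 0
    r[, zero] <- 0
  }
  diag(r) <- 1
  correlation_set(r, "raw")
}

#' Fisher z transform of a correlation set
#'
#' Applies \eqn{z = 0.5 \log((1 + r) / (1 - r))} elementwise.  Off-diagonal
#' entries with |r| >= 1 make the transform diverge; they are an error unless
#' `clip = TRUE`, in which case they are clipped to +/-(1 - 1e-12) with a
#' warning (useful when duplicated synthetic rows create exact +/-1).
#'
#' @param cs A [correlation_set()] at stage `"raw"`.
#' @param clip Clip perfect off-diagonal correlations instead of failing.
#' @return A [correlation_set()] at stage `"z"`.
#' @export
fisher_z <- function(cs, clip = FALSE) {
  stopifnot(inherits(cs, "correlation_set"))
  if (cs$stage != "raw")
    stop("fisher_z expects a correlation_set at stage 'raw'")
  r <- cs$r
  off <- abs(r) >= 1
  diag(off) <- FALSE
  if (any(off)) {
    if (!clip)
      stop(sum(off) / 2, " off-diagonal perfect correlation(s) (|r| >= 1); ",
           "drop or jitter them, or call fisher_z(clip = TRUE)")
    warning(sum(off) / 2, " perfect off-diagonal correlation(s) clipped to +/-(1 - 1e-12)")
    r[off] <- sign(r[off]) * (1 - 1e-12)
  }
  z <- atanh(r)
  diag(z) <- 0  # structural; excluded from all downstream computations
  correlation_set(z, "z")
}

#' Normalize Fisher z scores of two conditions to a common scale
#'
#' Within each condition the off-diagonal z values are standardized (their
#' empirical mean subtracted and standard deviation divided out, computed on
#' the upper triangle only), then mapped back to the correlation scale with
#' \eqn{r' = \tanh(z')}.  After this step the two conditions' correlation
#' populations are location/scale aligned, so one pooled threshold is
#' meaningful.
#'
#' @param z_a,z_b [correlation_set()] objects at stage `"z"` over the same
#'   genes.
#' @return A list with elements `a` and `b`, both at stage `"normalized-r"`,
#'   all off-diagonal values strictly inside (-1, 1).
#' @export
normalize_z <- function(z_a, z_b) {
  stopifnot(inherits(z_a, "correlation_set"), inherits(z_b, "correlation_set"))
  if (z_a$stage != "z" || z_b$stage != "z")
    stop("normalize_z expects correlation_sets at stage 'z'")
  if (!identical(z_a$genes, z_b$genes))
    stop("the two correlation sets must share one gene index")
  norm1 <- function(cs) {
    z <- cs$r
    ut <- upper.tri(z)
    vals <- z[ut]
    s <- sd(vals)
    if (!is.finite(s) || s == 0)
      stop("z values have zero standard deviation; cannot normalize")
    zn <- (z - mean(vals)) / s
    rn <- tanh(zn)
    diag(rn) <- 1
    correlation_set(rn, "normalized-r")
  }
  list(a = norm1(z_a), b = norm1(z_b))
}

#' Hard-threshold two normalized correlation sets into unweighted networks
#'
#' The threshold is the empirical `q` quantile (inclusive linear-interpolation
#' definition, R type 7) of the pooled absolute off-diagonal values of both
#' conditions; a gene pair is connected in a condition iff its absolute
#' normalized correlation strictly exceeds the threshold.  With
#' `pooled = FALSE` each condition uses its own quantile instead.
#'
#' @param r_a,r_b [correlation_set()] objects at stage `"normalized-r"` over
#'   the same genes.
#' @param q Quantile in (0, 1); default 0.995 keeps the top 0.5% of pairs.
#' @param pooled Pool both conditions' values before taking the quantile
#'   (default `TRUE`).
#' @return A list with the two [coexpression_network()]s (`net_a`, `net_b`)
#'   and the threshold(s) used (`threshold`).
#' @export
threshold_networks <- function(r_a, r_b, q = 0.995, pooled = TRUE) {
  stopifnot(inherits(r_a, "correlation_set"), inherits(r_b, "correlation_set"))
  if (r_a$stage != "normalized-r" || r_b$stage != "normalized-r")
    stop("threshold_networks expects correlation_sets at stage 'normalized-r'")
  if (!identical(r_a$genes, r_b$genes))
    stop("the two correlation sets must share one gene index")
  if (q <= 0 || q >= 1) stop("'q' must lie strictly inside (0, 1)")
  ut <- upper.tri(r_a$r)
  va <- abs(r_a$r[ut]); vb <- abs(r_b$r[ut])
  if (pooled) {
    thr <- unname(quantile(c(va, vb), q, type = 7))
    thr_a <- thr_b <- thr
  } else {
    thr_a <- unname(quantile(va, q, type = 7))
    thr_b <- unname(quantile(vb, q, type = 7))
  }
  mk <- function(r, thr) {
    A <- (abs(r) > thr) * 1L
    diag(A) <- 0L
    storage.mode(A) <- "integer"
    dimnames(A) <- list(r_a$genes, r_a$genes)
    coexpression_network(A, r_a$genes)
  }
  net_a <- mk(r_a$r, thr_a)
  net_b <- mk(r_b$r, thr_b)
  if (sum(net_a$adjacency) + sum(net_b$adjacency) == 0)
    warning("threshold equals the maximum pooled value; both networks are empty")
  list(net_a = net_a, net_b = net_b,
       threshold = if (pooled) thr_a else c(a = thr_a, b = thr_b))
}

#' Build two cross-comparable coexpression networks from expression matrices
#'
#' Convenience chain: [pearson_matrix()] on each condition, [fisher_z()],
#' [normalize_z()], [threshold_networks()].
#'
#' @param expr_a,expr_b [expression_matrix()] objects over the same genes, no
#'   missing values.
#' @param q Threshold quantile, default 0.995.
#' @param pooled Pool conditions for the quantile (default `TRUE`).
#' @param clip Passed to [fisher_z()]; clip perfect correlations.
#' @return As [threshold_networks()].
#' @export
build_networks <- function(expr_a, expr_b, q = 0.995, pooled = TRUE,
                           clip = FALSE) {
  if (!identical(expr_a$gene_ids, expr_b$gene_ids))
    stop("the two expression matrices must share one gene index and order")
  za <- fisher_z(pearson_matrix(expr_a), clip = clip)
  zb <- fisher_z(pearson_matrix(expr_b), clip = clip)
  nz <- normalize_z(za, zb)
  threshold_networks(nz$a, nz$b, q = q, pooled = pooled)
}
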