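#' Hypergeometric over-representation test
#'
#' Tests whether a module overlaps a gene set more than expected by chance in
#' a background universe of N genes: with K set members in the universe and a
#' module of n universe genes, the p value is the upper-tail hypergeometric
#' probability of observing at least the realized overlap k.  One-sided
#' (over-representation only).
#'
#' @param module Character vector of gene IDs.
#' @param geneset Character vector of gene IDs.
#' @param universe Character vector of background gene IDs (nonempty).
#'   `module` and `geneset` are restricted to it.
#' @return A list with `overlap` (k), `module_size` (n, after restriction),
#'   `set_size` (K), `universe_size` (N) and `p`.
#' @examples
#' # 3 of 3 drawn genes inside a 4-gene set over a 10-gene universe: p = 1/30
#' u <- paste0("g", 1:10)
#' hypergeom_ora(u[1:3], u[1:4], u)
#' @export
hypergeom_ora <- function(module, geneset, universe) {
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (N < 1) stop("universe must contain at least one gene")
  mod <- intersect(unique(as.character(module)), universe)
  set <- intersect(unique(as.character(geneset)), universe)
  if (!length(mod))
    stop("module has no genes in the universe")
  k <- length(intersect(mod, set))
  n <- length(mod)
  K <- length(set)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = k, module_size = n, set_size = K, universe_size = N, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment: adjusted values are
#' capped at 1, monotone nondecreasing in the sorted order, and returned in
#' the original order.  Values outside \[0, 1\] are an error.
#'
#' @param pvals Numeric vector of p values.
#' @return Adjusted p values, `>= pvals` elementwise.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop("'pvals' must be numeric")
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Over-representation analysis of every module against a gene-set collection
#'
#' Runs [hypergeom_ora()] for each module against each gene set, adjusts the
#' p values per module (Benjamini-Hochberg across that module's tested sets,
#' matching per-query behaviour of standard enrichment tools) and keeps rows
#' with adjusted p below `cutoff`, sorted by raw p within module.
#'
#' @param ms A `module_set` (or a named list of gene-ID vectors).
#' @param collection A `gene_set_collection` from [read_gmt()].
#' @param cutoff Adjusted-p threshold in (0, 1\]; default 0.05.
#' @return A data frame with columns `module`, `set`, `overlap`,
#'   `module_size`, `set_size`, `universe_size`, `p`, `p_adj`.
#' @export
enrich_modules <- function(ms, collection, cutoff = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (cutoff <= 0 || cutoff > 1) stop("'cutoff' must lie in (0, 1]")
  modules <- if (inherits(ms, "module_set")) ms$modules else ms
  if (!length(modules) || !length(collection$sets))
    return(empty_enrichment())
  out <- list()
  for (mid in names(modules)) {
    mod_u <- intersect(modules[[mid]], collection$universe)
    if (!length(mod_u)) next
    recs <- lapply(names(collection$sets), function(sn) {
      h <- hypergeom_ora(mod_u, collection$sets[[sn]], collection$universe)
      data.frame(module = mid, set = sn, overlap = h$overlap,
                 module_size = h$module_size, set_size = h$set_size,
                 universe_size = h$universe_size, p = h$p,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, recs)
    tab$p_adj <- bh_adjust(tab$p)
    tab <- tab[tab$p_adj < cutoff, , drop = FALSE]
    out[[mid]] <- tab[order(tab$p), , drop = FALSE]
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) empty_enrichment() else res
}

empty_enrichment <- function() {
  data.frame(module = character(0), set = character(0), overlap = integer(0),
             module_size = integer(0), set_size = integer(0),
             universe_size = integer(0), p = numeric(0), p_adj = numeric(0))
}
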