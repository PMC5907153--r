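#' Average degree and density of a module's induced subgraph
#'
#' For a module of \eqn{n_m} genes inducing m edges in a network, the average
#' degree is \eqn{\bar d = 2m/n_m} and the density
#' \eqn{D = 2m/(n_m(n_m-1))}; the two are related by
#' \eqn{D = \bar d/(n_m - 1)} exactly.
#'
#' @param module Character vector of gene IDs, all present in the network,
#'   length >= 2.
#' @param net A [coexpression_network()].
#' @return Named numeric vector with `avg_degree` and `density`.
#' @examples
#' # complete graph on 4 genes
#' A <- 1 - diag(4); dimnames(A) <- list(letters[1:4], letters[1:4])
#' module_degree_density(letters[1:4], coexpression_network(A))
#' @export
module_degree_density <- function(module, net) {
  stopifnot(inherits(net, "coexpression_network"))
  module <- as.character(module)
  if (length(module) < 2)
    stop("module must contain at least 2 genes")
  if (!all(module %in% net$genes))
    stop("module gene(s) missing from the network: ",
         paste(setdiff(module, net$genes), collapse = ", "))
  sub <- net$adjacency[module, module, drop = FALSE]
  m <- sum(sub) / 2
  n_m <- length(module)
  c(avg_degree = 2 * m / n_m, density = 2 * m / (n_m * (n_m - 1)))
}

# edge indicator vector over the n_m(n_m-1)/2 unordered gene pairs of a module
edge_indicators <- function(module, net) {
  sub <- net$adjacency[module, module, drop = FALSE]
  as.numeric(sub[upper.tri(sub)])
}

#' Test whether a module's edge probability differs between networks
#'
#' Edges are modelled as Bernoulli draws: the module's
#' \eqn{n_m(n_m-1)/2} pair indicators (1 = edge) are collected in each
#' network, and a two-sided two-sample t test compares the two indicator
#' vectors.  The default is the Welch (unequal variance) test; a
#' pooled-variance test is available via `var_equal = TRUE`.  When both
#' indicator vectors are constant the t statistic is undefined: the p value is
#' 1 when their means agree (no evidence of difference) and 0 when one induced
#' subgraph is complete and the other empty.
#'
#' @param module Character vector of gene IDs, length >= 3, all present in
#'   both networks.
#' @param net_a,net_b [coexpression_network()]s over the same gene index.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return The p value (symmetric in the two networks).
#' @export
structure_test <- function(module, net_a, net_b, var_equal = FALSE) {
  stopifnot(inherits(net_a, "coexpression_network"),
            inherits(net_b, "coexpression_network"))
  module <- as.character(module)
  if (length(module) < 3)
    stop("module must contain at least 3 genes (>= 3 pairs)")
  if (!all(module %in% net_a$genes) || !all(module %in% net_b$genes))
    stop("module gene(s) missing from a network")
  x <- edge_indicators(module, net_a)
  y <- edge_indicators(module, net_b)
  if (var(x) == 0 && var(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  t.test(x, y, var.equal = var_equal)$p.value
}

#' Per-module structure statistics for both networks
#'
#' Combines [module_degree_density()] in each network with
#' [structure_test()] into one record per module, in module order.
#'
#' @param ms A `module_set`.
#' @param net_a,net_b [coexpression_network()]s containing all module genes.
#' @param var_equal Passed to [structure_test()].
#' @return A data frame with columns `module`, `size`, `avg_degree_a`,
#'   `avg_degree_b`, `density_a`, `density_b`, `p_value`.
#' @export
stats_table <- function(ms, net_a, net_b, var_equal = FALSE) {
  stopifnot(inherits(ms, "module_set"))
  recs <- lapply(names(ms$modules), function(mid) {
    g <- ms$modules[[mid]]
    da <- module_degree_density(g, net_a)
    db <- module_degree_density(g, net_b)
    data.frame(module = mid, size = length(g),
               avg_degree_a = da[["avg_degree"]],
               avg_degree_b = db[["avg_degree"]],
               density_a = da[["density"]],
               density_b = db[["density"]],
               p_value = structure_test(g, net_a, net_b,
                                        var_equal = var_equal),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(module = character(0), size = integer(0),
                      avg_degree_a = numeric(0), avg_degree_b = numeric(0),
                      density_a = numeric(0), density_b = numeric(0),
                      p_value = numeric(0))
  out
}
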