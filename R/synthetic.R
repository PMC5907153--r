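#' Define a two-layer planted-module scenario
#'
#' Describes the synthetic ground truth shared by both generators: a gene
#' universe of `n_genes`, the first `sum(module_sizes)` of which tile into
#' planted modules (the remainder are background genes belonging to no
#' module), per-module per-layer edge probabilities for the direct graph
#' generator, per-module per-layer within-module expression correlations for
#' the expression generator, and a background edge probability for every
#' non-co-module pair.  A module with equal parameters in both layers is
#' *shared*; one that is dense/correlated in a single layer is *differential*.
#'
#' @param n_genes Total gene count; must be >= `sum(module_sizes)`.
#' @param module_sizes Integer vector of planted module sizes.
#' @param layer_intra_p Numeric matrix (modules x 2) of within-module edge
#'   probabilities per layer, or a single pair recycled to all modules.
#' @param background_p Edge probability between every non-co-module pair, in
#'   both layers.
#' @param rho Numeric matrix (modules x 2) of within-module expression
#'   correlations per layer in \[0, 1), or a single pair recycled.
#' @param samples_per_layer Samples drawn per condition by the expression
#'   generator (>= 10).
#' @param seed Optional integer seed; generators are reproducible given the
#'   scenario.
#' @return A list of class `sbm_scenario`.
#' @examples
#' sc <- sbm_scenario(seed = 1)        # 4 shared modules of 25 genes
#' sc$module_sizes
#' @export
sbm_scenario <- function(n_genes = 100L,
                         module_sizes = rep(25L, 4),
                         layer_intra_p = c(0.30, 0.30),
                         background_p = 0.02,
                         rho = c(0.7, 0.7),
                         samples_per_layer = 100L,
                         seed = NULL) {
  module_sizes <- as.integer(module_sizes)
  n_genes <- as.integer(n_genes)
  if (sum(module_sizes) > n_genes)
    stop("module sizes exceed 'n_genes'")
  expand <- function(x, what, upper_open = FALSE) {
    m <- if (is.matrix(x)) x else matrix(x, nrow = length(module_sizes),
                                         ncol = 2, byrow = TRUE)
    if (nrow(m) != length(module_sizes) || ncol(m) != 2)
      stop("'", what, "' must be a (modules x 2) matrix or a length-2 pair")
    if (any(m < 0) || any(if (upper_open) m >= 1 else m > 1))
      stop("'", what, "' values out of range")
    colnames(m) <- c("a", "b")
    m
  }
  layer_intra_p <- expand(layer_intra_p, "layer_intra_p")
  rho <- expand(rho, "rho", upper_open = TRUE)
  if (background_p < 0 || background_p > 1)
    stop("'background_p' must lie in [0, 1]")
  samples_per_layer <- as.integer(samples_per_layer)
  structure(list(n_genes = n_genes, module_sizes = module_sizes,
                 layer_intra_p = layer_intra_p, background_p = background_p,
                 rho = rho, samples_per_layer = samples_per_layer,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sbm_scenario")
}

#' The packaged default recovery scenario
#'
#' Four shared planted modules of 25 genes tiling a 100-gene universe,
#' within-module edge probability 0.30 in both layers, background edge
#' probability 0.02, within-module expression correlation 0.7.
#'
#' @param seed Integer seed.
#' @return An [sbm_scenario()].
#' @export
default_scenario <- function(seed = NULL) {
  sbm_scenario(seed = seed)
}

#' The packaged differential-module scenario
#'
#' Three shared modules (correlation 0.7 in both layers) plus one
#' differential module that is essentially uncorrelated in layer A
#' (rho = 0.05) and strongly correlated in layer B (rho = 0.8); 100 extra
#' background genes of pure noise.  For the graph generator the differential
#' module is dense in layer A only (0.30 vs background-level 0.02).
#'
#' @param seed Integer seed.
#' @return An [sbm_scenario()].
#' @export
differential_scenario <- function(seed = NULL) {
  sbm_scenario(n_genes = 200L,
               module_sizes = rep(25L, 4),
               layer_intra_p = rbind(c(0.30, 0.30), c(0.30, 0.30),
                                     c(0.30, 0.30), c(0.30, 0.02)),
               background_p = 0.02,
               rho = rbind(c(0.7, 0.7), c(0.7, 0.7),
                           c(0.7, 0.7), c(0.05, 0.8)),
               samples_per_layer = 100L,
               seed = seed)
}

planted_labels <- function(scenario) {
  lab <- rep(0L, scenario$n_genes)
  i <- 1L
  for (m in seq_along(scenario$module_sizes)) {
    lab[i:(i + scenario$module_sizes[m] - 1L)] <- m
    i <- i + scenario$module_sizes[m]
  }
  names(lab) <- sprintf("g%04d", seq_len(scenario$n_genes))
  lab
}

new_planted_truth <- function(scenario) {
  structure(list(labels = planted_labels(scenario), scenario = scenario),
            class = "planted_truth")
}

#' Generate two planted-partition network layers
#'
#' Every unordered gene pair gets an independent Bernoulli edge in each layer:
#' probability `layer_intra_p[m, k]` when both genes belong to planted module
#' m, `background_p` otherwise.
#'
#' @param scenario An [sbm_scenario()].
#' @return A list with `net_a`, `net_b` ([coexpression_network()]s) and
#'   `truth` (a `planted_truth` holding the gene -> module labels, 0 =
#'   background).
#' @export
generate_two_layer_sbm <- function(scenario) {
  stopifnot(inherits(scenario, "sbm_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  truth <- new_planted_truth(scenario)
  lab <- truth$labels
  n <- scenario$n_genes
  mk <- function(layer) {
    P <- matrix(scenario$background_p, n, n)
    for (m in seq_along(scenario$module_sizes)) {
      idx <- which(lab == m)
      P[idx, idx] <- scenario$layer_intra_p[m, layer]
    }
    A <- matrix(0L, n, n)
    ut <- upper.tri(A)
    A[ut] <- as.integer(runif(sum(ut)) < P[ut])
    A <- A + t(A)
    dimnames(A) <- list(names(lab), names(lab))
    coexpression_network(A, names(lab))
  }
  list(net_a = mk(1L), net_b = mk(2L), truth = truth)
}

#' Generate two-condition expression with planted coexpression modules
#'
#' A one-factor-per-module Gaussian model: in layer k, gene g of module m in
#' sample s takes the value
#' \eqn{\sqrt{\rho_{mk}} f_{ms} + \sqrt{1 - \rho_{mk}}\, \epsilon_{gs}} with
#' independent standard normal module factors f and gene noise
#' \eqn{\epsilon}, so the expected within-module Pearson correlation is
#' \eqn{\rho_{mk}} and between-module correlation 0.  Background genes are
#' pure noise.
#'
#' @param scenario An [sbm_scenario()] with `samples_per_layer >= 10`.
#' @return A list with `expr_a`, `expr_b` ([expression_matrix()]s) and
#'   `truth`.
#' @export
generate_correlated_expression <- function(scenario) {
  stopifnot(inherits(scenario, "sbm_scenario"))
  if (scenario$samples_per_layer < 10)
    stop("'samples_per_layer' must be at least 10")
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  truth <- new_planted_truth(scenario)
  lab <- truth$labels
  n <- scenario$n_genes
  S <- scenario$samples_per_layer
  mk <- function(layer, cond) {
    X <- matrix(rnorm(n * S), n, S,
                dimnames = list(names(lab), sprintf("%s_s%03d", cond, 1:S)))
    for (m in seq_along(scenario$module_sizes)) {
      idx <- which(lab == m)
      rho <- scenario$rho[m, layer]
      f <- rnorm(S)
      X[idx, ] <- sqrt(rho) * matrix(f, length(idx), S, byrow = TRUE) +
        sqrt(1 - rho) * X[idx, ]
    }
    expression_matrix(X, condition = cond)
  }
  list(expr_a = mk(1L, "A"), expr_b = mk(2L, "B"), truth = truth)
}

#' Adjusted Rand index between recovered modules and the planted truth
#'
#' The recovered (possibly overlapping) union modules are flattened to a
#' partition by first membership -- each gene is assigned to the first module
#' that contains it, all unassigned genes form one background class -- and
#' compared to the planted labels by the adjusted Rand index (1 = identical,
#' about 0 = chance).
#'
#' @param found A `module_set`, or a list of gene-ID vectors.
#' @param truth A `planted_truth` from a generator.
#' @return The ARI, a real in \[-1, 1\].
#' @export
recovery_score <- function(found, truth) {
  stopifnot(inherits(truth, "planted_truth"))
  modules <- if (inherits(found, "module_set")) found$modules else found
  genes <- names(truth$labels)
  part <- setNames(rep(0L, length(genes)), genes)
  for (i in seq_along(modules)) {
    mem <- intersect(modules[[i]], genes)
    fresh <- mem[part[mem] == 0L]
    part[fresh] <- i
  }
  mclust::adjustedRandIndex(part, truth$labels)
}
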