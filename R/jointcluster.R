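#' Remove genes isolated in both networks
#'
#' Genes with degree zero in *both* layers carry no connectivity information
#' and are dropped before clustering.  A gene isolated in only one layer is
#' retained: the coupling term lets the other layer place it in a module,
#' which is precisely how condition-specific modules are recovered.
#'
#' @param net_a,net_b [coexpression_network()]s over the same gene index.
#' @return A list with the reduced networks (`net_a`, `net_b`) and the kept
#'   gene IDs (`kept`).
#' @export
remove_dual_isolated <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "coexpression_network"),
            inherits(net_b, "coexpression_network"))
  if (!identical(net_a$genes, net_b$genes))
    stop("the two networks must share one gene index and order")
  keep <- !(net_a$degree == 0 & net_b$degree == 0)
  if (!any(keep))
    warning("all genes are isolated in both networks; result is empty")
  sub <- function(net) {
    coexpression_network(net$adjacency[keep, keep, drop = FALSE],
                         net$genes[keep])
  }
  list(net_a = sub(net_a), net_b = sub(net_b), kept = net_a$genes[keep])
}

#' Assemble the coupled Laplacian matrix of two networks
#'
#' Builds the symmetric `2n x 2n` matrix
#' \deqn{C = \begin{pmatrix} L_1 & -\beta I \\ -\beta I & L_2 \end{pmatrix}}
#' where \eqn{L_k = D_k - A_k} is the unnormalized graph Laplacian of layer k
#' and the off-diagonal \eqn{-\beta I} blocks couple each gene's two layer
#' copies.  Rows 1..n are layer-A vertex copies, rows n+1..2n layer-B copies.
#' Every eigenvalue of C is >= -beta (each \eqn{L_k} is positive semidefinite
#' and the coupling block has spectrum +/-beta).
#'
#' @param net_a,net_b [coexpression_network()]s over the same gene index.
#' @param beta Non-negative coupling weight; `beta = 0` decouples the layers.
#' @return An object of class `joint_model` with elements `beta`, `n`,
#'   `genes`, `C`; `eigenvalues`, `embedding` and `M` are filled in by
#'   [spectral_embed()].
#' @export
assemble_C <- function(net_a, net_b, beta = 1) {
  stopifnot(inherits(net_a, "coexpression_network"),
            inherits(net_b, "coexpression_network"))
  if (!identical(net_a$genes, net_b$genes))
    stop("the two networks must share one gene index and order")
  if (beta < 0) stop("'beta' must be non-negative")
  n <- length(net_a$genes)
  lap <- function(net) diag(net$degree, n) - net$adjacency
  I <- diag(1, n)
  C <- rbind(cbind(lap(net_a), -beta * I),
             cbind(-beta * I, lap(net_b)))
  dimnames(C) <- NULL
  structure(list(beta = beta, n = n, genes = net_a$genes, C = C,
                 eigenvalues = NULL, embedding = NULL, M = NULL),
            class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat(sprintf("joint_model: n = %d genes (C is %d x %d), beta = %g%s\n",
              x$n, 2 * x$n, 2 * x$n, x$beta,
              if (is.null(x$M)) "" else sprintf(", embedded with M = %d", x$M)))
  invisible(x)
}

# Deterministic orthonormal basis within each (near-)degenerate eigenvalue
# group: the spanned subspace is basis-independent, so rebuild it from the
# projector via column-pivoted QR, which does not depend on the solver's
# arbitrary within-group rotation.
canonical_eigenbasis <- function(vectors, values, tol = 1e-8) {
  grp <- cumsum(c(TRUE, diff(values) > tol))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    B <- vectors[, idx, drop = FALSE]
    P <- B %*% t(B)
    qrP <- qr(P, LAPACK = TRUE)
    vectors[, idx] <- qr.Q(qrP)[, seq_along(idx), drop = FALSE]
  }
  vectors
}

# Sign convention: the entry of largest absolute value in each eigenvector is
# made positive; which.max breaks ties at the lowest index.  Spearman row
# distances are not invariant to column sign flips, so this fixes determinism.
fix_signs <- function(vectors) {
  for (j in seq_len(ncol(vectors))) {
    i0 <- which.max(abs(vectors[, j]))
    if (vectors[i0, j] < 0) vectors[, j] <- -vectors[, j]
  }
  vectors
}

#' Spectral embedding from the M smallest eigenvalues of C
#'
#' Dense symmetric eigen-decomposition of the coupled matrix; the eigenvectors
#' of the `M` smallest eigenvalues, scaled by \eqn{\sqrt 2} so that the relaxed
#' constraint \eqn{\tilde S^T \tilde S = 2 I_M} holds, form the `2n x M`
#' embedding (row v is the coordinate vector of vertex copy v).  Eigenvector
#' signs and near-degenerate subspaces are made deterministic; each
#' eigenpair's residual is checked against `1e-8 * ||C||_2`.
#'
#' @param model A `joint_model` from [assemble_C()].
#' @param M Number of embedding dimensions, `1 <= M <= 2n`.
#' @return The `joint_model` with `eigenvalues` (all 2n, ascending),
#'   `embedding` and `M` filled in.
#' @export
spectral_embed <- function(model, M) {
  stopifnot(inherits(model, "joint_model"))
  M <- as.integer(M)
  if (M < 1 || M > 2 * model$n)
    stop("'M' must lie in [1, 2n]")
  e <- eigen(model$C, symmetric = TRUE)
  ord <- rev(seq_len(2 * model$n))  # eigen() returns descending
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  vectors <- canonical_eigenbasis(vectors, values)
  vectors <- fix_signs(vectors)
  nrmC <- max(abs(values))
  res <- vapply(seq_len(M), function(j) {
    sqrt(sum((model$C %*% vectors[, j] - values[j] * vectors[, j])^2))
  }, numeric(1))
  if (any(res > 1e-8 * max(nrmC, 1)))
    stop(sprintf(paste0("eigensolver residual too large: max ||C u - lambda u|| = %.3e",
                        " (||C|| = %.3e); decomposition unreliable"),
                 max(res), nrmC))
  model$eigenvalues <- values
  model$embedding <- vectors[, seq_len(M), drop = FALSE] * sqrt(2)
  model$M <- M
  model
}

#' Choose the number of clusters M from the first big eigengap
#'
#' Scans the ascending eigenvalues over `search_range` and returns the
#' smallest index M whose gap \eqn{\lambda_{M+1} - \lambda_M} is at least
#' `factor` times the median gap over the range (and strictly positive).  If
#' no gap qualifies, the index of the largest gap is returned with a warning.
#' A fully degenerate spectrum (all gaps zero) is an error.
#'
#' @param eigenvalues Ascending numeric vector (as stored by
#'   [spectral_embed()]).
#' @param search_range Integer pair `(lo, hi)` with `2 <= lo <= hi <=
#'   length(eigenvalues) - 1`; `NULL` means `[2, min(50, length - 1)]`.
#' @param factor Positive multiple of the median gap that defines "big".
#' @return The selected M (positive integer).
#' @examples
#' select_M(c(-1, -1, -1, 1, 1, 1, 4, 4, 9, 10), search_range = c(2, 6))
#' @export
select_M <- function(eigenvalues, search_range = NULL, factor = 3) {
  L <- length(eigenvalues)
  if (L < 3) stop("need at least 3 eigenvalues")
  if (is.null(search_range))
    search_range <- c(2L, min(50L, L - 1L))
  lo <- as.integer(search_range[1]); hi <- as.integer(search_range[2])
  if (lo < 2 || hi > L - 1 || lo > hi)
    stop("'search_range' must lie within [2, length(eigenvalues) - 1]")
  idx <- lo:hi
  gaps <- eigenvalues[idx + 1L] - eigenvalues[idx]
  tol <- 1e-10 * max(1, max(abs(eigenvalues)))
  if (all(gaps <= tol))
    stop("degenerate spectrum: all eigengaps in the search range are zero")
  med <- median(gaps)
  qual <- which(gaps >= factor * med & gaps > tol)
  if (length(qual)) return(idx[qual[1]])
  warning("no eigengap exceeds ", factor, " times the median gap; ",
          "falling back to the largest gap in the search range")
  idx[which.max(gaps)]
}

#' Module set container
#'
#' Holds per-network cluster label vectors (each gene has exactly one label
#' per network), the union modules as gene sets (possibly overlapping), a
#' membership table with per-network presence flags, and a provenance note per
#' module recording which post-processing steps produced it.
#'
#' @name module_set
#' @keywords internal
new_module_set <- function(genes, labels_a, labels_b, membership, provenance,
                           M = NULL) {
  mids <- unique(membership$module)
  modules <- split(membership$gene, factor(membership$module, levels = mids))
  structure(list(genes = genes, labels_a = labels_a, labels_b = labels_b,
                 modules = modules, membership = membership,
                 provenance = provenance, M = M),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- lengths(x$modules)
  cat(sprintf("module_set: %d module(s) over %d genes (sizes: %s)\n",
              length(x$modules), length(x$genes),
              if (length(sizes)) paste(sizes, collapse = ", ") else "-"))
  invisible(x)
}

#' Cluster the joint embedding into M aligned clusters
#'
#' All 2n embedding rows (layer-A copies then layer-B copies) are clustered
#' jointly by agglomerative hierarchical clustering with complete linkage on
#' the distance 1 - Spearman rank correlation between rows.  The tree is cut
#' into `M` clusters; labels of rows 1..n become the network-A labels and rows
#' n+1..2n the network-B labels.  Rank order is stable even when eigenvector
#' entry magnitudes vary wildly, which is why rank correlation rather than
#' Euclidean distance is used.  A constant embedding row has no rank variation
#' (Spearman undefined); it is assigned distance 1 to every other row, with a
#' warning.
#'
#' @param model A `joint_model` embedded with [spectral_embed()] (`M >= 2`).
#' @return A `module_set` with per-network labels; union modules are built by
#'   [union_modules()].
#' @export
cluster_embedding <- function(model) {
  stopifnot(inherits(model, "joint_model"))
  if (is.null(model$embedding))
    stop("embedding missing; run spectral_embed() first")
  if (model$M < 2) stop("clustering needs an embedding with M >= 2 columns")
  emb <- model$embedding
  # force exact ties where entries differ only by numerical noise: rank-based
  # distances are otherwise non-deterministic on degenerate embeddings
  scale <- max(abs(emb))
  if (scale > 0) emb <- round(emb / scale, 10) * scale
  const <- apply(emb, 1, function(r) max(r) - min(r) == 0)
  D <- suppressWarnings(1 - cor(t(emb), method = "spearman"))
  if (any(const)) {
    warning(sum(const), " constant embedding row(s); Spearman undefined, ",
            "distance 1 assigned")
    D[const, ] <- 1
    D[, const] <- 1
  }
  D[is.na(D)] <- 1
  diag(D) <- 0
  cl <- cutree(hclust(as.dist(D), method = "complete"), k = model$M)
  n <- model$n
  new_module_set(genes = model$genes,
                 labels_a = setNames(cl[seq_len(n)], model$genes),
                 labels_b = setNames(cl[n + seq_len(n)], model$genes),
                 membership = data.frame(module = character(0),
                                         gene = character(0),
                                         in_a = logical(0), in_b = logical(0),
                                         stringsAsFactors = FALSE),
                 provenance = character(0),
                 M = model$M)
}

#' Take the union of corresponding clusters across the two networks
#'
#' Cluster m's union module is the set of genes labeled m in network A or in
#' network B.  A gene whose two layer copies received different labels belongs
#' to two union modules; with `overlap = "keep"` (the default, the literal
#' union rule) it appears in both, with `"majority"` it is kept only where
#' both copies agree, falling back to the network-A label when they disagree.
#'
#' @param ms A `module_set` with per-network labels (from
#'   [cluster_embedding()]).
#' @param overlap `"keep"` or `"majority"`.
#' @return The `module_set` with union modules and membership flags filled in.
#'   Module IDs are `"M<cluster index>"`.
#' @export
union_modules <- function(ms, overlap = c("keep", "majority")) {
  stopifnot(inherits(ms, "module_set"))
  overlap <- match.arg(overlap)
  if (is.null(ms$labels_a) || is.null(ms$labels_b))
    stop("per-network labels missing")
  genes <- ms$genes
  la <- ms$labels_a[genes]
  lb <- ms$labels_b[genes]
  if (overlap == "majority") {
    # resolve disagreements to the network-A label so modules partition genes
    lb <- ifelse(la == lb, lb, la)
  }
  rows <- list()
  prov <- character(0)
  for (m in sort(unique(c(la, lb)))) {
    in_a <- la == m
    in_b <- lb == m
    mem <- in_a | in_b
    if (!any(mem)) next
    mid <- paste0("M", m)
    rows[[mid]] <- data.frame(module = mid, gene = genes[mem],
                              in_a = in_a[mem], in_b = in_b[mem],
                              stringsAsFactors = FALSE)
    prov[mid] <- sprintf("union of cluster %d%s", m,
                         if (any(xor(in_a[mem], in_b[mem])))
                           " (layers disagree for some genes)" else "")
  }
  membership <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  new_module_set(genes, ms$labels_a, ms$labels_b, membership, prov, ms$M)
}

#' Split modules that induce disconnected subgraphs
#'
#' The joint clustering can group genes that are not actually connected; each
#' module is therefore replaced by the connected components of its induced
#' subgraph.  Connectivity is judged by default in the union graph
#' (an edge present in either layer), the weakest requirement consistent with
#' one layer lending connectivity to the other; per-layer variants are
#' available.
#'
#' @param ms A `module_set` with union modules.
#' @param net_a,net_b [coexpression_network()]s over (a superset of) the
#'   module genes.
#' @param connectivity `"union"` (default), `"a"` or `"b"`.
#' @return A `module_set` in which every module induces a connected subgraph.
#'   Split products get IDs `<parent>.<component>`.
#' @export
split_disconnected <- function(ms, net_a, net_b,
                               connectivity = c("union", "a", "b")) {
  stopifnot(inherits(ms, "module_set"))
  connectivity <- match.arg(connectivity)
  if (!identical(net_a$genes, net_b$genes))
    stop("the two networks must share one gene index and order")
  A <- switch(connectivity,
              union = pmax(net_a$adjacency, net_b$adjacency),
              a = net_a$adjacency,
              b = net_b$adjacency)
  g_all <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  rows <- list()
  prov <- character(0)
  for (mid in names(ms$modules)) {
    mem_rows <- ms$membership[ms$membership$module == mid, , drop = FALSE]
    vids <- match(mem_rows$gene, net_a$genes)
    if (anyNA(vids))
      stop("module ", mid, " names gene(s) outside the network index")
    comp <- igraph::components(igraph::induced_subgraph(g_all, vids))$membership
    ncomp <- max(comp)
    for (cc in seq_len(ncomp)) {
      sub <- mem_rows[comp == cc, , drop = FALSE]
      nid <- if (ncomp == 1) mid else paste0(mid, ".", cc)
      sub$module <- nid
      rows[[nid]] <- sub
      prov[nid] <- paste0(ms$provenance[mid],
                          if (ncomp > 1)
                            sprintf("; component %d of %d", cc, ncomp) else "")
    }
  }
  membership <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(membership))
    membership <- ms$membership[0, , drop = FALSE]
  new_module_set(ms$genes, ms$labels_a, ms$labels_b, membership, prov, ms$M)
}

#' Filter modules by size
#'
#' Retains modules whose gene count lies in `[min_size, max_size]` (inclusive
#' bounds), preserving order.
#'
#' @param ms A `module_set`.
#' @param min_size,max_size Integer bounds; defaults 5 and 800.
#' @return The filtered `module_set`.
#' @export
filter_size <- function(ms, min_size = 5L, max_size = 800L) {
  stopifnot(inherits(ms, "module_set"))
  if (min_size > max_size) stop("'min_size' must not exceed 'max_size'")
  sizes <- lengths(ms$modules)
  keep <- names(ms$modules)[sizes >= min_size & sizes <= max_size]
  membership <- ms$membership[ms$membership$module %in% keep, , drop = FALSE]
  rownames(membership) <- NULL
  new_module_set(ms$genes, ms$labels_a, ms$labels_b, membership,
                 ms$provenance[keep], ms$M)
}

#' Run the full joint module identification pipeline
#'
#' Chains [remove_dual_isolated()], [assemble_C()], [spectral_embed()],
#' [select_M()] (unless `M_override` fixes M), [cluster_embedding()],
#' [union_modules()], [split_disconnected()] and [filter_size()] under one
#' [jm_config()].
#'
#' @param net_a,net_b [coexpression_network()]s over the same gene index.
#' @param config A [jm_config()]; its `beta`, `M_override`, `M_search_range`,
#'   `eigengap_factor`, size bounds, `connectivity` and `overlap` fields drive
#'   the run.
#' @return A list with `modules` (the final `module_set`), `model` (the
#'   embedded `joint_model`), `kept` (genes surviving
#'   [remove_dual_isolated()]) and `M`.
#' @export
joint_modules <- function(net_a, net_b, config = jm_config()) {
  stopifnot(inherits(config, "jm_config"))
  red <- remove_dual_isolated(net_a, net_b)
  model <- assemble_C(red$net_a, red$net_b, beta = config$beta)
  n2 <- 2 * model$n
  if (!is.null(config$M_override)) {
    M <- min(config$M_override, n2)
    model <- spectral_embed(model, M)
  } else {
    # need the spectrum before M is known: embed maximally once, then trim
    model <- spectral_embed(model, n2)
    M <- select_M(model$eigenvalues, config$M_search_range,
                  config$eigengap_factor)
    model$embedding <- model$embedding[, seq_len(M), drop = FALSE]
    model$M <- M
  }
  ms <- cluster_embedding(model)
  ms <- union_modules(ms, overlap = config$overlap)
  ms <- split_disconnected(ms, red$net_a, red$net_b,
                           connectivity = config$connectivity)
  ms <- filter_size(ms, config$min_module_size, config$max_module_size)
  list(modules = ms, model = model, kept = red$kept, M = M)
}
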