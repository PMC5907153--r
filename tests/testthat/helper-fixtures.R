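# Shared fixture builders: everything is generated in code, no data files.

# network from a character edge matrix/vector over an explicit universe
make_net <- function(edges, genes) {
  A <- matrix(0L, length(genes), length(genes), dimnames = list(genes, genes))
  if (length(edges)) {
    em <- if (is.matrix(edges)) edges else matrix(edges, ncol = 2, byrow = TRUE)
    A[cbind(em[, 1], em[, 2])] <- 1L
    A[cbind(em[, 2], em[, 1])] <- 1L
  }
  coexpression_network(A, genes)
}

# disjoint cliques of the given sizes (gene IDs c1_1, ..., c2_1, ...)
clique_net <- function(sizes) {
  genes <- unlist(lapply(seq_along(sizes), function(i)
    paste0("c", i, "_", seq_len(sizes[i]))))
  A <- matrix(0L, length(genes), length(genes), dimnames = list(genes, genes))
  off <- 0L
  for (s in sizes) {
    idx <- off + seq_len(s)
    A[idx, idx] <- 1L
    off <- off + s
  }
  diag(A) <- 0L
  coexpression_network(A, genes)
}

# Erdos-Renyi layer over a fixed universe
rand_net <- function(n, p, seed) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n))
  A <- matrix(0L, n, n, dimnames = list(genes, genes))
  ut <- upper.tri(A)
  A[ut] <- as.integer(runif(sum(ut)) < p)
  A <- A + t(A)
  dimnames(A) <- list(genes, genes)
  coexpression_network(A, genes)
}

# expression matrix with named rows from a plain matrix
make_expr <- function(m, condition = NA_character_) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  expression_matrix(m, condition)
}

# hand-rolled adjusted Rand index from the contingency table (oracle for
# recovery_score's mclust backend)
ari_oracle <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  mx <- (b + cc) / 2
  if (mx == expected) return(0)
  (a - expected) / (mx - expected)
}

# brute-force evaluation of the combinatorial joint-clustering objective for a
# hard assignment: sum_k sum_m ratio-cut term minus the cross-layer cosine
# coupling (both orders k != l), used to validate assemble_C algebraically
objective_bruteforce <- function(net_a, net_b, beta, labels_a, labels_b, M) {
  lap <- function(net) diag(net$degree, length(net$genes)) - net$adjacency
  L <- list(lap(net_a), lap(net_b))
  S <- list(
    sapply(seq_len(M), function(m) as.numeric(labels_a == m)),
    sapply(seq_len(M), function(m) as.numeric(labels_b == m))
  )
  rc <- 0
  for (k in 1:2) for (m in seq_len(M)) {
    s <- S[[k]][, m]
    if (sum(s) > 0) rc <- rc + as.numeric(t(s) %*% L[[k]] %*% s) / sum(s)
  }
  cs <- 0
  for (m in seq_len(M)) {
    s1 <- S[[1]][, m]; s2 <- S[[2]][, m]
    n1 <- sqrt(sum(s1)); n2 <- sqrt(sum(s2))
    if (n1 > 0 && n2 > 0) cs <- cs + sum(s1 * s2) / (n1 * n2)
  }
  rc - 2 * beta * cs
}

# Tr(S~' C S~) for the same hard assignment, via the assembled C
objective_trace <- function(model, labels_a, labels_b, M) {
  n <- model$n
  St <- matrix(0, 2 * n, M)
  for (m in seq_len(M)) {
    s1 <- as.numeric(labels_a == m)
    s2 <- as.numeric(labels_b == m)
    if (sum(s1) > 0) St[seq_len(n), m] <- s1 / sqrt(sum(s1))
    if (sum(s2) > 0) St[n + seq_len(n), m] <- s2 / sqrt(sum(s2))
  }
  sum(diag(t(St) %*% model$C %*% St))
}
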