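test_that("dual-isolated genes are removed, singly-isolated genes kept", {
  genes <- c("a", "b", "c", "d")
  net_a <- make_net(c("a", "b"), genes)          # c, d isolated in A
  net_b <- make_net(rbind(c("a", "b"), c("b", "c")), genes)  # d isolated in B
  red <- remove_dual_isolated(net_a, net_b)
  expect_identical(red$kept, c("a", "b", "c"))   # c kept: linked in B only
  expect_identical(red$net_a$genes, red$net_b$genes)

  ring <- make_net(cbind(genes, c(genes[-1], genes[1])), genes)
  none <- remove_dual_isolated(ring, ring)
  expect_identical(none$kept, genes)             # no dual-isolated: identity
})

test_that("C follows the block formula: symmetry, decoupling, coupling spectrum", {
  net1 <- rand_net(12, 0.3, seed = 2)
  net2 <- rand_net(12, 0.25, seed = 3)

  # beta = 0: block diagonal, spectrum = union of the Laplacian spectra
  m0 <- assemble_C(net1, net2, beta = 0)
  lap <- function(net) diag(net$degree, 12) - net$adjacency
  ev_expected <- sort(c(eigen(lap(net1), symmetric = TRUE)$values,
                        eigen(lap(net2), symmetric = TRUE)$values))
  ev_got <- sort(eigen(m0$C, symmetric = TRUE)$values)
  expect_equal(ev_got, ev_expected, tolerance = 1e-10)

  # any input: exact symmetry
  m1 <- assemble_C(net1, net2, beta = 1.5)
  expect_identical(m1$C, t(m1$C))

  # two empty networks, beta = 1: spectrum is -1 (n times), +1 (n times)
  empty <- make_net(character(0), paste0("g", 1:6))
  me <- assemble_C(empty, empty, beta = 1)
  expect_equal(sort(eigen(me$C, symmetric = TRUE)$values),
               rep(c(-1, 1), each = 6), tolerance = 1e-12)

  expect_error(assemble_C(net1, rand_net(11, 0.3, seed = 1)), "gene index")
})

test_that("every eigenvalue of C is at least -beta", {
  for (s in 1:5) {
    beta <- c(0, 0.5, 1, 2, 5)[s]
    net1 <- rand_net(15, 0.3, seed = 100 + s)
    net2 <- rand_net(15, 0.4, seed = 200 + s)
    model <- spectral_embed(assemble_C(net1, net2, beta), M = 2)
    expect_gte(min(model$eigenvalues), -beta - 1e-10)
  }
})

test_that("embedding satisfies the relaxed scaling and residual bound", {
  net1 <- rand_net(10, 0.4, seed = 4)
  net2 <- rand_net(10, 0.4, seed = 5)
  model <- spectral_embed(assemble_C(net1, net2, 1), M = 4)
  # S~' S~ = 2 I_M
  expect_equal(crossprod(model$embedding), diag(2, 4), tolerance = 1e-10)
  expect_equal(model$eigenvalues, sort(model$eigenvalues))
  # sign convention: largest-magnitude entry of each column is positive
  for (j in 1:4) {
    col <- model$embedding[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("identical layers give a symmetric embedding and aligned labels", {
  net <- clique_net(c(6, 6, 6))
  # lambda_M(L) = 0 for the 3 component directions < 2 beta = 2
  model <- spectral_embed(assemble_C(net, net, beta = 1), M = 3)
  n <- model$n
  # the 3 smallest eigenvalues are all exactly -beta (Laplacian kernel of 3
  # components shifted down by the coupling)
  expect_equal(model$eigenvalues[1:3], rep(-1, 3), tolerance = 1e-10)
  expect_gt(model$eigenvalues[4], -1 + 0.5)
  # row i equals row n + i: in-phase eigenvectors dominate
  expect_equal(model$embedding[seq_len(n), ],
               model$embedding[n + seq_len(n), ], tolerance = 1e-8)
  ms <- cluster_embedding(model)
  expect_identical(unname(ms$labels_a), unname(ms$labels_b))
  # each clique is one cluster
  expect_equal(ari_oracle(ms$labels_a, rep(1:3, each = 6)), 1)
})

test_that("beta = 0 eigenvectors live on a single block", {
  net1 <- rand_net(8, 0.5, seed = 6)
  net2 <- rand_net(8, 0.5, seed = 7)
  model <- spectral_embed(assemble_C(net1, net2, beta = 0), M = 6)
  for (j in 1:6) {
    a_part <- sum(model$embedding[1:8, j]^2)
    b_part <- sum(model$embedding[9:16, j]^2)
    expect_lt(min(a_part, b_part) / max(a_part, b_part), 1e-12)
  }
})

test_that("eigengap selection finds the first big gap with fallbacks", {
  ev <- c(-1, -1, -1, 1, 1, 1, 4, 4, 9, 10)
  expect_equal(select_M(ev, search_range = c(2, 6)), 3)

  # linear spectrum: uniform gaps, no qualifying gap -> warned argmax
  expect_warning(m <- select_M(as.numeric(1:30), search_range = c(2, 10)),
                 "falling back")
  expect_equal(m, 2)

  expect_error(select_M(rep(2, 10), search_range = c(2, 8)), "degenerate")

  # duplicated disjoint cliques: spectrum {-1 x c, +1 x c, s - 1, ...} so the
  # first big gap sits after M = c
  net <- clique_net(c(6, 6, 6, 6))
  model <- spectral_embed(assemble_C(net, net, beta = 1), M = 2)
  expect_equal(select_M(model$eigenvalues, search_range = c(2, 12)), 4)
})

test_that("clustering recovers groups with distinct rank patterns exactly", {
  # 3 groups of rows sharing a rank pattern, patterns mutually distinct:
  # zero within-group Spearman distance forces exact recovery
  pat <- rbind(c(0.1, 0.5, 0.9, 0.2),
               c(0.9, 0.1, 0.4, 0.6),
               c(0.3, 0.8, 0.1, 0.7))
  rows <- pat[rep(1:3, each = 4), ] * rep(seq(1, 2, length.out = 12), 4)
  model <- structure(list(beta = 1, n = 6, genes = paste0("g", 1:6),
                          C = NULL, eigenvalues = NULL,
                          embedding = rows, M = 3),
                     class = "joint_model")
  ms <- cluster_embedding(model)
  joint <- c(ms$labels_a, ms$labels_b)
  expect_equal(ari_oracle(joint, rep(1:3, each = 4)), 1)
})

test_that("a constant embedding row is handled with distance one", {
  emb <- rbind(matrix(rnorm(12), 3), rep(0.5, 4))
  model <- structure(list(beta = 1, n = 2, genes = c("g1", "g2"), C = NULL,
                          eigenvalues = NULL, embedding = emb, M = 2),
                     class = "joint_model")
  expect_warning(ms <- cluster_embedding(model), "constant")
  expect_length(ms$labels_a, 2)
})

test_that("union modules keep genes labeled differently across layers in both", {
  genes <- paste0("g", 1:6)
  ms <- jointmod:::new_module_set(
    genes,
    labels_a = setNames(c(1, 1, 1, 2, 2, 2), genes),
    labels_b = setNames(c(1, 1, 2, 2, 2, 2), genes),
    membership = data.frame(module = character(0), gene = character(0),
                            in_a = logical(0), in_b = logical(0)),
    provenance = character(0), M = 2)
  um <- union_modules(ms)
  expect_setequal(um$modules$M1, c("g1", "g2", "g3"))
  expect_setequal(um$modules$M2, c("g3", "g4", "g5", "g6"))  # g3 in both
  maj <- union_modules(ms, overlap = "majority")
  expect_setequal(maj$modules$M1, c("g1", "g2", "g3"))       # A label wins
  expect_setequal(maj$modules$M2, c("g4", "g5", "g6"))

  # agreeing labels: unions equal either layer's clusters
  ms2 <- ms
  ms2$labels_b <- ms$labels_a
  um2 <- union_modules(ms2)
  expect_setequal(um2$modules$M1, c("g1", "g2", "g3"))
  expect_true(all(um2$membership$in_a & um2$membership$in_b))
})

test_that("disconnected modules split into union-graph components", {
  genes <- paste0("g", 1:13)
  # module of 13 genes inducing two union components (6 + 7)
  ring <- function(ids) cbind(ids, c(ids[-1], ids[1]))
  net_a <- make_net(ring(genes[1:6]), genes)
  net_b <- make_net(ring(genes[7:13]), genes)
  mem <- data.frame(module = "M1", gene = genes, in_a = TRUE, in_b = FALSE,
                    stringsAsFactors = FALSE)
  ms <- jointmod:::new_module_set(genes, NULL, NULL, mem, c(M1 = "test"))
  sp <- split_disconnected(ms, net_a, net_b)
  expect_length(sp$modules, 2)
  expect_setequal(lengths(sp$modules), c(6, 7))

  # already union-connected: unchanged
  net_c <- make_net(ring(genes), genes)
  sp2 <- split_disconnected(ms, net_c, net_b)
  expect_length(sp2$modules, 1)
  expect_setequal(sp2$modules$M1, genes)

  # pairwise-unlinked genes fall apart into singletons, then size filter
  lonely <- jointmod:::new_module_set(
    genes, NULL, NULL,
    data.frame(module = "M1", gene = genes[1:3], in_a = TRUE, in_b = TRUE),
    c(M1 = "test"))
  iso <- make_net(ring(genes[4:13]), genes)
  sp3 <- split_disconnected(lonely, iso, iso)
  expect_length(sp3$modules, 3)
  expect_length(filter_size(sp3, 5, 800)$modules, 0)
})

test_that("size filter applies inclusive bounds in order", {
  genes <- paste0("g", 1:1700)
  sizes <- c(4, 5, 800, 801)
  mem <- data.frame(module = rep(paste0("M", 1:4), sizes),
                    gene = genes[1:sum(sizes)], in_a = TRUE, in_b = TRUE,
                    stringsAsFactors = FALSE)
  ms <- jointmod:::new_module_set(genes, NULL, NULL, mem,
                                  setNames(rep("t", 4), paste0("M", 1:4)))
  kept <- filter_size(ms, 5, 800)
  expect_identical(names(kept$modules), c("M2", "M3"))
  expect_identical(lengths(kept$modules), c(M2 = 5L, M3 = 800L))
  expect_identical(lengths(filter_size(ms, 1, 10000)$modules),
                   lengths(ms$modules))
})

test_that("trace objective equals the brute-force combinatorial objective", {
  # algebraic identity Tr(S~' C S~) = sum ratio-cut - 2 beta sum cosine,
  # checked for hard assignments on random small networks
  for (s in 1:4) {
    set.seed(400 + s)
    n <- c(10, 20, 35, 50)[s]
    net_a <- rand_net(n, 0.3, seed = 500 + s)
    net_b <- rand_net(n, 0.3, seed = 600 + s)
    beta <- c(0, 1, 2, 0.5)[s]
    M <- 3
    la <- sample(1:M, n, replace = TRUE)
    lb <- sample(1:M, n, replace = TRUE)
    model <- assemble_C(net_a, net_b, beta)
    expect_equal(objective_trace(model, la, lb, M),
                 objective_bruteforce(net_a, net_b, beta, la, lb, M),
                 tolerance = 1e-8)
  }
})

test_that("beta = 0 joint labels match single-network spectral clustering", {
  # algebraic decoupling property, checked on cleanly separated planted
  # instances (disjoint cliques) where both routes must recover the planted
  # partition exactly
  for (s in 1:3) {
    c_mod <- 3; size <- c(8, 10, 12)[s]
    sc <- sbm_scenario(n_genes = c_mod * size,
                       module_sizes = rep(size, c_mod),
                       layer_intra_p = c(1, 1), background_p = 0,
                       seed = 700 + s)
    sim <- generate_two_layer_sbm(sc)
    truth <- sim$truth$labels

    res <- joint_modules(sim$net_a, sim$net_b,
                         jm_config(beta = 0, M_override = 2 * c_mod,
                                   min_module_size = 2))
    la <- res$modules$labels_a[res$kept]

    # independent single-network oracle: same spectral recipe on L1 alone
    net <- sim$net_a
    A <- net$adjacency
    L1 <- diag(rowSums(A)) - A
    e <- eigen(L1, symmetric = TRUE)
    V <- e$vectors[, rev(seq_len(ncol(e$vectors)))][, 1:c_mod]
    for (j in 1:c_mod) {
      i0 <- which.max(abs(V[, j])); if (V[i0, j] < 0) V[, j] <- -V[, j]
    }
    D <- suppressWarnings(1 - cor(t(V), method = "spearman"))
    D[is.na(D)] <- 1; diag(D) <- 0
    oracle <- setNames(cutree(hclust(as.dist(D), method = "complete"),
                              k = c_mod), net$genes)
    shared <- intersect(names(la), names(oracle))
    expect_equal(ari_oracle(la[shared], oracle[shared]), 1)
    expect_equal(ari_oracle(la, truth[names(la)]), 1)
  }
})

test_that("joint pipeline recovers strong planted modules across layers", {
  # strongly separated instance: recovery should be exact
  sc <- sbm_scenario(n_genes = 60, module_sizes = rep(20L, 3),
                     layer_intra_p = c(0.9, 0.9), background_p = 0.01,
                     seed = 42)
  sim <- generate_two_layer_sbm(sc)
  res <- joint_modules(sim$net_a, sim$net_b, jm_config(M_override = 6))
  expect_gte(recovery_score(res$modules, sim$truth), 0.95)
  # all final modules are union-connected and size-bounded by construction
  sizes <- lengths(res$modules$modules)
  expect_true(all(sizes >= 5 & sizes <= 800))
})
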