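# jointmod

Joint module detection and comparison in paired gene coexpression networks.

## What problem this solves

Comparing the module structure of two gene coexpression networks — say, two
tumour types profiled on the same gene universe — is awkward when each
network is clustered on its own: the two module sets neither align nor share
labels, and shared structure fragments differently in each solution.
`jointmod` clusters both networks **simultaneously**.  The two graph
Laplacians $L_k = D_k - A_k$ are coupled into one symmetric matrix

$$C = \begin{pmatrix} L_1 & -\beta I \\ -\beta I & L_2 \end{pmatrix},$$

whose off-diagonal $-\beta I$ blocks pull each gene's two layer copies into
the same cluster.  The eigenvectors of the $M$ smallest eigenvalues of $C$
(the relaxed solution of a ratio-cut-plus-cosine-coupling objective
$\min \operatorname{Tr}(\tilde S^\top C \tilde S)$,
$\tilde S^\top \tilde S = 2I_M$) embed all $2n$ vertex copies in a common
space; complete-linkage hierarchical clustering with Spearman rank-correlation
distance, cut into $M$ clusters, yields aligned labels in both networks at
once.  Corresponding clusters are merged by gene-set union, split into
connected components, and size-filtered into the final modules.  Per-module
average degree, density and a Bernoulli edge-probability test (Welch t on the
induced edge indicators) then quantify how each module's structure differs
between the conditions, and a hypergeometric over-representation test scores
modules against user-supplied GMT gene sets.

The package is aimed at desk-scale analyses and simulation studies: it ships
a two-layer planted-partition generator (graphs or correlated expression)
with adjusted-Rand-index recovery scoring, so every stage is testable without
external data.

## Worked example

Simulate two conditions in which three modules are coexpressed in both layers
and one module is coexpressed only in layer B, build cross-comparable
networks, and identify modules jointly:

```r
library(jointmod)

sc   <- differential_scenario(seed = 7)     # 4 x 25-gene modules + 100 background genes
sim  <- generate_correlated_expression(sc)  # 200 genes x 100 samples per layer
nets <- build_networks(sim$expr_a, sim$expr_b, q = 0.995)
nets$net_a
#> coexpression_network: 200 genes, 120 edges (mean degree 1.20)
nets$net_b
#> coexpression_network: 200 genes, 79 edges (mean degree 0.79)

res <- joint_modules(nets$net_a, nets$net_b, jm_config(M_override = 8))
res$modules
#> module_set: 5 module(s) over 84 genes (sizes: 17, 20, 14, 5, 21)

stats_table(res$modules, nets$net_a, nets$net_b)
#>   module size avg_degree_a avg_degree_b density_a density_b  p_value
#> 1     M3   17         4.00        0.000     0.250     0.000 4.95e-10
#> 2     M4   20         4.40        0.000     0.232     0.000 1.83e-12
#> 3     M6   14         3.29        0.286     0.253     0.022 5.61e-06
#> 4     M7    5         1.60        0.000     0.400     0.000 3.68e-02
#> 5     M8   21         0.00        7.238     0.000     0.362 3.71e-22
```

Module `M8` is the planted differential module: 21 of its genes were
recovered as one unit even though they are completely unconnected in layer A
(density 0.00 vs 0.36; its connectivity was "borrowed" from layer B through
the coupling), and the structure test flags the difference at
p ≈ 4e-22.  The modules dense in layer A only (`M3`, `M4`) mirror the
opposite case.  `recovery_score(res$modules, sim$truth)` compares the found
modules with the planted labels by adjusted Rand index (0.68 here; background
genes thresholded out of both networks are the main loss).

Key entry points: `read_expression()` / `impute_missing()` /
`filter_differential_genes()` for expression input; `build_networks()` (or
`pearson_matrix()`, `fisher_z()`, `normalize_z()`, `threshold_networks()`
individually); `joint_modules()` (or the individual steps `assemble_C()`,
`spectral_embed()`, `select_M()`, `cluster_embedding()`, `union_modules()`,
`split_disconnected()`, `filter_size()`); `stats_table()`;
`enrich_modules()` with `read_gmt()`.  See the vignette
(`vignettes/joint-module-detection.Rmd`) for the model, the choice of M, and
every numerical convention.

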