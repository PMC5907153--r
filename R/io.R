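#' Expression matrix container
#'
#' A thin wrapper around a numeric genes x samples matrix carrying gene and
#' sample identifiers in its dimnames plus an optional condition label.
#' Missing entries are `NA` and must be removed with [impute_missing()] before
#' network construction.
#'
#' @param values Numeric matrix, genes in rows.  Rownames are gene IDs,
#'   colnames sample IDs; both must be present and the gene IDs unique.
#' @param condition Optional single character label for the condition the
#'   samples were measured under.
#' @return An object of class `expression_matrix` with elements `values`,
#'   `gene_ids`, `sample_ids`, `condition`.
#' @export
expression_matrix <- function(values, condition = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene IDs as rownames and sample IDs as colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicated gene ID(s): ", paste(unique(dup), collapse = ", "))
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 condition = as.character(condition)[1]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (condition: %s, %d missing)\n",
              nrow(x$values), ncol(x$values), x$condition, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a genes x samples expression matrix from tab-separated text
#'
#' The first column holds gene identifiers and the header row sample
#' identifiers.  `NA` or empty cells are treated as missing (flagged `NA`, not
#' dropped); any other non-numeric cell is an error naming the offending line.
#' Ragged rows and duplicated gene IDs are rejected.
#'
#' @param path Path to the TSV file.
#' @param condition Optional condition label attached to the result.
#' @return An [expression_matrix()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\tNA\t0.5"), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path, condition = NA_character_) {
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    fill = FALSE, quote = "", comment.char = "")
  if (ncol(raw) < 2)
    stop("expression file must have a gene ID column plus at least one sample column")
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated gene ID(s) in '", path, "': ", paste(dup, collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  missing <- cells == "" | cells == "NA"
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !missing, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("non-numeric cell '%s' at line %d (gene '%s', sample '%s') in '%s'",
                 cells[i, j], i + 1L, ids[i], colnames(cells)[j], path))
  }
  num[missing] <- NA_real_
  dimnames(num) <- list(ids, colnames(raw)[-1])
  expression_matrix(num, condition = condition)
}

#' Coexpression network container
#'
#' An undirected, unweighted network over an ordered gene index: a symmetric
#' 0/1 adjacency matrix with zero diagonal, plus the degree vector.
#'
#' @param adjacency Symmetric numeric 0/1 matrix; rownames/colnames, if
#'   present, must agree with `genes`.
#' @param genes Character vector of gene IDs, one per row of `adjacency`.
#' @return An object of class `coexpression_network` with elements `genes`,
#'   `adjacency` (integer matrix, dimnames = genes) and `degree`.
#' @export
coexpression_network <- function(adjacency, genes = rownames(adjacency)) {
  if (is.null(genes))
    stop("gene IDs required (pass 'genes' or set rownames)")
  genes <- as.character(genes)
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("'adjacency' must be a square matrix")
  if (length(genes) != nrow(adjacency))
    stop("length of 'genes' must match the adjacency dimension")
  if (anyDuplicated(genes))
    stop("duplicated gene IDs in network index")
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency must be 0/1")
  if (!isTRUE(all.equal(adjacency, t(adjacency), check.attributes = FALSE)))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0))
    stop("adjacency must have a zero diagonal")
  A <- matrix(as.integer(adjacency), nrow(adjacency),
              dimnames = list(genes, genes))
  structure(list(genes = genes, adjacency = A, degree = rowSums(A)),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, %d edges (mean degree %.2f)\n",
              length(x$genes), sum(x$adjacency) / 2, mean(x$degree)))
  invisible(x)
}

#' Read an undirected network from a two-column edge list
#'
#' Each line names one gene pair, tab-separated.  Reciprocal duplicates are
#' collapsed, self-loops dropped with a warning, and any edge naming a gene
#' outside `gene_universe` is an error.
#'
#' @param path Path to the edge-list TSV (no header).
#' @param gene_universe Ordered character vector of gene IDs defining the
#'   network index; isolated genes are retained.
#' @return A [coexpression_network()].
#' @export
read_edge_list <- function(path, gene_universe) {
  gene_universe <- as.character(gene_universe)
  n <- length(gene_universe)
  A <- matrix(0L, n, n, dimnames = list(gene_universe, gene_universe))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nc <- lengths(parts)
    if (any(nc < 2))
      stop("edge list line ", which(nc < 2)[1], " has fewer than two columns")
    a <- vapply(parts, `[`, character(1), 1)
    b <- vapply(parts, `[`, character(1), 2)
    unknown <- setdiff(c(a, b), gene_universe)
    if (length(unknown))
      stop("edge references gene(s) outside the universe: ",
           paste(unknown, collapse = ", "))
    loops <- a == b
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped")
      a <- a[!loops]; b <- b[!loops]
    }
    A[cbind(a, b)] <- 1L
    A[cbind(b, a)] <- 1L
  }
  coexpression_network(A, gene_universe)
}

#' Write an edge list for a coexpression network
#'
#' One tab-separated gene pair per line, each undirected edge written once
#' (upper triangle).
#'
#' @param net A [coexpression_network()].
#' @param path Output path.
#' @return Invisibly, the number of edges written.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  df <- data.frame(from = net$genes[idx[, 1]], to = net$genes[idx[, 2]])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(nrow(df))
}

#' Write module memberships and statistics to tab-separated files
#'
#' Produces `<prefix>_membership.tsv` (module ID, gene ID, per-network presence
#' flags) and, when `stats` is supplied, `<prefix>_stats.tsv` with size, average
#' degree and density per network, and the structure-difference p value, all at
#' full precision.  [read_modules()] on the same prefix round-trips the gene
#' sets.
#'
#' @param modules A `module_set` (see [union_modules()]).
#' @param stats Optional data frame from [stats_table()]; its module IDs must
#'   match `modules` one-to-one.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_modules <- function(modules, stats = NULL, prefix) {
  stopifnot(inherits(modules, "module_set"))
  mem_path <- paste0(prefix, "_membership.tsv")
  write.table(modules$membership, mem_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  paths <- mem_path
  if (!is.null(stats)) {
    if (!setequal(stats$module, names(modules$modules)) ||
        nrow(stats) != length(modules$modules))
      stop("module IDs in 'stats' do not match 'modules'")
    stats_path <- paste0(prefix, "_stats.tsv")
    write.table(stats, stats_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    paths <- c(paths, stats_path)
  }
  invisible(paths)
}

#' Read a module set written by [write_modules()]
#'
#' @param prefix The path prefix used when writing.
#' @return A `module_set` holding the gene sets and presence flags (cluster
#'   label vectors are not serialized and come back `NULL`).
#' @export
read_modules <- function(prefix) {
  mem <- read.delim(paste0(prefix, "_membership.tsv"), sep = "\t",
                    header = TRUE, colClasses = c("character", "character",
                                                  "logical", "logical"))
  genes <- unique(mem$gene)
  new_module_set(genes = genes, labels_a = NULL, labels_b = NULL,
                 membership = mem,
                 provenance = setNames(rep("read from file",
                                           length(unique(mem$module))),
                                       unique(mem$module)))
}

#' Read a gene-set collection in GMT format
#'
#' Each line is `set name<TAB>description<TAB>member<TAB>member...`.  Empty
#' sets are dropped with a warning.  The background universe defaults to the
#' union of all member genes, or can be supplied explicitly (sets are then
#' restricted to it).
#'
#' @param path Path to the GMT file.
#' @param universe Optional character vector of background gene IDs.
#' @return A list of class `gene_set_collection` with elements `sets` (named
#'   list of character vectors) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short))
    warning(sum(short), " GMT line(s) with no member genes dropped")
  parts <- parts[!short]
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names(sets)))
    stop("duplicated gene-set names in '", path, "'")
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets)))
  } else {
    universe <- as.character(universe)
    sets <- lapply(sets, intersect, universe)
  }
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sum(empty), " empty gene set(s) dropped: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}
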