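#' Run configuration for the joint module pipeline
#'
#' Collects every tunable scalar of the pipeline in one validated list.  The
#' defaults reproduce the reference settings of the method: hard thresholding
#' at the pooled 99.5% quantile, coupling weight `beta = 1`, eigengap factor 3,
#' module size bounds \[5, 800\], and differential-gene significance 0.01.
#' Calling `jm_config()` with no arguments therefore yields a configuration
#' that runs the pipeline exactly as published.
#'
#' @param quantile_threshold Fraction in (0, 1); pooled absolute-correlation
#'   quantile used as the hard edge threshold.  Default 0.995.
#' @param beta Non-negative coupling weight between the two network layers.
#'   Default 1 (inter-layer links weighted like intra-layer ones).
#' @param M_override Optional positive integer; fixes the number of clusters
#'   `M` instead of eigengap selection.  Default `NULL`.
#' @param M_search_range Integer vector of length 2, the interval over which
#'   the eigengap is searched.  `NULL` (default) means `[2, min(50, 2n - 2)]`.
#' @param eigengap_factor Positive real; a gap must exceed this multiple of the
#'   median gap in the search range to count as the "first big eigengap".
#'   Default 3.
#' @param min_module_size,max_module_size Integer size bounds applied to final
#'   modules.  Defaults 5 and 800.
#' @param de_alpha Fraction in (0, 1); adjusted-p cutoff for differential gene
#'   selection.  Default 0.01.
#' @param rng_seed Optional integer seed recorded for provenance.
#' @param linkage Agglomeration method for hierarchical clustering; only
#'   `"complete"` is supported.
#' @param distance Row distance for the embedding; only `"spearman"`
#'   (1 - Spearman rank correlation) is supported.
#' @param pooled_quantile Logical; pool the absolute correlations of both
#'   conditions before taking the threshold quantile (default `TRUE`), or take
#'   a per-network quantile (`FALSE`).
#' @param connectivity Graph used when splitting disconnected modules: the
#'   union of both layers (`"union"`, default), or a single layer (`"a"`,
#'   `"b"`).
#' @param overlap How genes whose two layer copies received different labels
#'   are treated in union modules: kept in both (`"keep"`, default) or
#'   assigned to one module by majority (`"majority"`).
#'
#' @return A named list of class `jm_config`.
#' @examples
#' cfg <- jm_config()
#' cfg$quantile_threshold
#' @export
jm_config <- function(quantile_threshold = 0.995,
                      beta = 1,
                      M_override = NULL,
                      M_search_range = NULL,
                      eigengap_factor = 3,
                      min_module_size = 5L,
                      max_module_size = 800L,
                      de_alpha = 0.01,
                      rng_seed = NULL,
                      linkage = "complete",
                      distance = "spearman",
                      pooled_quantile = TRUE,
                      connectivity = c("union", "a", "b"),
                      overlap = c("keep", "majority")) {
  stopifnot(is.numeric(quantile_threshold), length(quantile_threshold) == 1)
  if (quantile_threshold <= 0 || quantile_threshold >= 1)
    stop("'quantile_threshold' must lie strictly inside (0, 1)")
  stopifnot(is.numeric(beta), length(beta) == 1)
  if (beta < 0) stop("'beta' must be non-negative")
  if (!is.null(M_override)) {
    M_override <- as.integer(M_override)
    if (M_override < 1) stop("'M_override' must be a positive integer")
  }
  if (!is.null(M_search_range)) {
    M_search_range <- as.integer(M_search_range)
    if (length(M_search_range) != 2 || M_search_range[1] > M_search_range[2] ||
        M_search_range[1] < 2)
      stop("'M_search_range' must be an increasing integer pair with lower bound >= 2")
  }
  stopifnot(is.numeric(eigengap_factor), eigengap_factor > 0)
  min_module_size <- as.integer(min_module_size)
  max_module_size <- as.integer(max_module_size)
  if (min_module_size > max_module_size)
    stop("'min_module_size' must not exceed 'max_module_size'")
  if (de_alpha < 0 || de_alpha >= 1)
    stop("'de_alpha' must lie in [0, 1)")
  linkage <- match.arg(linkage, "complete")
  distance <- match.arg(distance, "spearman")
  connectivity <- match.arg(connectivity)
  overlap <- match.arg(overlap)
  structure(list(
    quantile_threshold = quantile_threshold,
    beta = beta,
    M_override = M_override,
    M_search_range = M_search_range,
    eigengap_factor = eigengap_factor,
    min_module_size = min_module_size,
    max_module_size = max_module_size,
    de_alpha = de_alpha,
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
    linkage = linkage,
    distance = distance,
    pooled_quantile = isTRUE(pooled_quantile),
    connectivity = connectivity,
    overlap = overlap
  ), class = "jm_config")
}

#' Read a run configuration from a flat key-value file
#'
#' The file holds one `key = value` (or tab-separated `key<TAB>value`) pair per
#' line; blank lines and lines starting with `#` are ignored.  Keys must be
#' valid [jm_config()] argument names; unknown keys are rejected rather than
#' silently ignored so that typos cannot change a run.
#'
#' @param path Path to the configuration file.
#' @return A validated `jm_config` list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(jm_config())
  kv <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "=|\t", fixed = FALSE)[[1]]
    if (length(parts) < 2)
      stop("malformed config line: '", ln, "'")
    c(trimws(parts[1]), trimws(paste(parts[-1], collapse = "=")))
  })
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  known <- names(formals(jm_config))
  bad <- setdiff(keys, known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicated config key(s): ", paste(unique(keys[duplicated(keys)]), collapse = ", "))
  args <- list()
  char_keys <- c("linkage", "distance", "connectivity", "overlap")
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    args[[k]] <- if (k %in% char_keys) {
      v
    } else if (k == "pooled_quantile") {
      as.logical(v)
    } else if (k == "M_search_range") {
      as.integer(strsplit(v, "[,;[:space:]]+")[[1]])
    } else {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) stop("non-numeric value for config key '", k, "': '", v, "'")
      num
    }
  }
  do.call(jm_config, args)
}
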