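#' Read a GMT gene-set collection
#'
#' GMT format: one set per line, tab-separated — set name, description, then
#' members. Members outside the universe are dropped with a message; sets
#' left empty after restriction are removed.
#'
#' @param path GMT file path.
#' @param universe Optional character vector restricting the gene universe;
#'   defaults to the union of all set members.
#' @return A list of class `gene_set_collection` with `sets` (named list of
#'   character vectors) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- stats::setNames(
    lapply(parts, function(p) unique(p[-(1:2)])),
    vapply(parts, `[`, "", 1)
  )
  gene_set_collection(sets, universe)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (each non-empty).
#' @param universe Optional gene universe; set members outside it are dropped
#'   (logged), then empty sets removed.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (any(lengths(sets) == 0)) stop("empty gene set", call. = FALSE)
  if (is.null(universe)) universe <- unique(unlist(sets))
  restricted <- lapply(sets, intersect, universe)
  dropped <- sum(lengths(sets)) - sum(lengths(restricted))
  if (dropped > 0) {
    message(dropped, " set member(s) outside the universe dropped")
  }
  restricted <- restricted[lengths(restricted) > 0]
  structure(list(sets = restricted, universe = unique(universe)),
            class = "gene_set_collection")
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X hypergeometric: drawing `n` genes from a universe of
#' `N` of which `K` belong to the set. Evaluated in log space for stability.
#'
#' @param k Observed overlap.
#' @param K Set size.
#' @param n Query size.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  if (any(k < 0) || any(k > pmin(K, n)) || any(K > N) || any(n > N)) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  ifelse(k == 0, 1, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Over-representation analysis
#'
#' Tests a query gene list against every set of a collection with the
#' hypergeometric upper tail, then applies Benjamini-Hochberg correction
#' across the sets. Query genes outside the universe are dropped first.
#'
#' @param query Character vector of gene ids.
#' @param collection A [gene_set_collection()].
#' @param fdr_max Significance cut-off on the adjusted p. Default 0.05.
#' @return A tibble sorted by p ascending: `set_name`, `overlap` (k),
#'   `set_size` (K), `query_size` (n), `universe_size` (N), `p_value`,
#'   `fdr`, `significant`.
#' @export
ora <- function(query, collection, fdr_max = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- intersect(unique(query), collection$universe)
  if (!length(query)) stop("query empty after universe restriction",
                           call. = FALSE)
  N <- length(collection$universe)
  n <- length(query)
  res <- purrr::imap_dfr(collection$sets, function(members, nm) {
    K <- length(members)
    k <- length(intersect(query, members))
    tibble::tibble(set_name = nm, overlap = k, set_size = K,
                   query_size = n, universe_size = N,
                   p_value = hypergeometric_upper_tail(k, K, n, N))
  })
  res |>
    dplyr::mutate(fdr = bh_adjust(.data$p_value),
                  significant = .data$fdr <= fdr_max) |>
    dplyr::arrange(.data$p_value, .data$set_name)
}
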