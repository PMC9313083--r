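#' Absolute-Pearson similarity matrix
#'
#' `S[i, j] = |cor(gene_i, gene_j)|` across the selected samples. Constant
#' genes (undefined correlation) get similarity 0 to every other gene and are
#' flagged with a warning; the diagonal is always 1.
#'
#' @param ds An `expression_dataset`.
#' @param genes Genes to include (default: all). Every requested gene must be
#'   present in `ds`.
#' @param samples Which samples to correlate over: `"all"` (default) or
#'   `"case"` only.
#' @return A symmetric numeric matrix in \[0, 1\] with gene dimnames, of
#'   class `similarity_matrix`.
#' @export
pearson_abs_similarity <- function(ds, genes = gene_ids(ds),
                                   samples = c("all", "case")) {
  samples <- match.arg(samples)
  missing_g <- setdiff(genes, gene_ids(ds))
  if (length(missing_g)) {
    stop("genes not in dataset: ", paste(missing_g, collapse = ", "),
         call. = FALSE)
  }
  v <- ds$values[genes, , drop = FALSE]
  if (samples == "case") v <- v[, ds$sample_class == "case", drop = FALSE]
  if (ncol(v) < 3) stop("need at least 3 samples for correlation",
                        call. = FALSE)
  constant <- apply(v, 1, function(r) stats::var(r) == 0)
  S <- abs(suppressWarnings(stats::cor(t(v))))
  if (any(constant)) {
    warning(sum(constant), " constant gene(s): similarity set to 0",
            call. = FALSE)
    S[constant, ] <- 0
    S[, constant] <- 0
  }
  diag(S) <- 1
  S[is.na(S)] <- 0
  structure(S, class = c("similarity_matrix", class(S)))
}

#' Mean local clustering coefficient
#'
#' Average over nodes of degree >= 2 of the fraction of closed triangles
#' among each node's neighbour pairs: `2 * t_i / (k_i * (k_i - 1))`. Returns
#' 0 when no node has degree >= 2. This observed coefficient, compared
#' against a random-graph expectation, drives the correlation-threshold
#' selection.
#'
#' @param adjacency Symmetric logical/0-1 matrix (simple undirected graph,
#'   no self-loops).
#' @return The mean local clustering coefficient.
#' @export
clustering_coefficient <- function(adjacency) {
  A <- (adjacency != 0) * 1
  diag(A) <- 0
  k <- rowSums(A)
  elig <- k >= 2
  if (!any(elig)) return(0)
  tri <- diag(A %*% A %*% A) / 2
  mean(2 * tri[elig] / (k[elig] * (k[elig] - 1)))
}

#' Expected clustering coefficient of a size-matched random graph
#'
#' For an Erdos-Renyi graph the expected clustering coefficient equals the
#' edge density `2 e / (n (n - 1))`.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param n_edges Number of edges.
#' @return Expected clustering coefficient.
#' @export
random_expected_cc <- function(n_nodes, n_edges) {
  stopifnot(n_nodes >= 2)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Select the coexpression threshold by the clustering-coefficient criterion
#'
#' For each candidate threshold tau the graph with edges `S >= tau` is built
#' and `D(tau) = C_obs(tau) - C_rand(tau)` computed, where `C_rand` is the
#' density of a size-matched random graph. The default criterion
#' (`method = "max_diff"`) picks the *onset of the plateau of maximal
#' difference*: the smallest tau, among thresholds keeping at least one
#' edge, whose D is within a fraction `rel_tol` of the maximum. With
#' `rel_tol = 0` this is the strict argmax (smallest tau on ties); the
#' default `rel_tol = 0.1` guards against the argmax drifting onto a
#' near-empty graph whose few surviving edges happen to close triangles —
#' there D approaches 1 while the network has lost most of its nodes.
#' `method = "first_positive"` instead picks the first tau where D > 0
#' holds for `k_sustain` consecutive grid points. The full curves are
#' returned for audit and plotting.
#'
#' @param S A similarity matrix from [pearson_abs_similarity()].
#' @param grid Ascending thresholds in (0, 1). Default 0.01..0.99 step 0.01.
#' @param method Selection rule; see Details.
#' @param rel_tol Plateau tolerance for `"max_diff"`, as a fraction of the
#'   maximum difference. Default 0.1.
#' @param k_sustain Consecutive positive grid points required by
#'   `"first_positive"`. Default 3.
#' @return A list with `tau_star` and `curves` (tibble: `tau`, `c_obs`,
#'   `c_rand`, `n_edges`).
#' @export
select_threshold <- function(S, grid = seq(0.01, 0.99, by = 0.01),
                             method = c("max_diff", "first_positive"),
                             rel_tol = 0.1, k_sustain = 3) {
  method <- match.arg(method)
  stopifnot(all(grid > 0 & grid < 1), !is.unsorted(grid))
  n <- nrow(S)
  off <- S
  diag(off) <- 0
  curves <- purrr::map_dfr(grid, function(tau) {
    A <- off >= tau
    e <- sum(A) / 2
    tibble::tibble(tau = tau,
                   c_obs = clustering_coefficient(A),
                   c_rand = random_expected_cc(n, e),
                   n_edges = e)
  })
  has_edge <- curves$n_edges >= 1
  if (!any(has_edge)) stop("no threshold on the grid yields an edge",
                           call. = FALSE)
  d <- curves$c_obs - curves$c_rand
  if (method == "max_diff") {
    cand <- which(has_edge)
    d_max <- max(d[cand])
    cutoff <- if (d_max > 0) d_max * (1 - rel_tol) else d_max
    tau_star <- curves$tau[cand[which(d[cand] >= cutoff)[1]]]
  } else {
    pos <- d > 0 & has_edge
    run <- stats::filter(as.numeric(pos), rep(1, k_sustain), sides = 1)
    idx <- which(run == k_sustain)[1]
    if (is.na(idx)) stop("no sustained positive difference found",
                         call. = FALSE)
    tau_star <- curves$tau[idx - k_sustain + 1]
  }
  list(tau_star = tau_star, curves = curves)
}

#' Build a coexpression network at a chosen threshold
#'
#' Edges connect gene pairs with similarity at or above `tau_star`; no
#' self-loops. Nodes are tiered by degree: `most` at or above the 90th
#' percentile of positive degrees, `less` at or below the 10th percentile
#' (isolated nodes are always `less`), `average` otherwise.
#'
#' @param S A similarity matrix.
#' @param tau_star Threshold in (0, 1), typically from [select_threshold()].
#' @param curves Optional threshold curves to carry along for plotting.
#' @return An object of class `coexpression_network` with fields `gene_ids`,
#'   `tau_star`, `adjacency` (logical matrix), `similarity`, `degree_tier`
#'   (tibble), `curves`.
#' @export
build_network <- function(S, tau_star, curves = NULL) {
  stopifnot(tau_star > 0, tau_star < 1)
  A <- S >= tau_star
  diag(A) <- FALSE
  deg <- rowSums(A)
  pos <- deg[deg > 0]
  tier <- rep("less", length(deg))
  if (length(pos)) {
    hi <- stats::quantile(pos, 0.9, names = FALSE)
    lo <- stats::quantile(pos, 0.1, names = FALSE)
    tier[deg >= hi & deg > 0] <- "most"
    tier[deg > lo & deg < hi] <- "average"
  }
  structure(
    list(gene_ids = rownames(S),
         tau_star = tau_star,
         adjacency = A,
         similarity = unclass(S),
         degree_tier = tibble::tibble(gene_id = rownames(S),
                                      degree = unname(deg), tier = tier),
         curves = curves),
    class = "coexpression_network"
  )
}

#' Build a network from a dataset in one call
#'
#' Convenience wrapper: similarity, threshold selection, then
#' [build_network()].
#'
#' @inheritParams pearson_abs_similarity
#' @inheritParams select_threshold
#' @return A `coexpression_network`.
#' @export
coexpression_network <- function(ds, genes = gene_ids(ds),
                                 samples = c("all", "case"),
                                 grid = seq(0.01, 0.99, by = 0.01),
                                 method = c("max_diff", "first_positive"),
                                 rel_tol = 0.1, k_sustain = 3) {
  S <- pearson_abs_similarity(ds, genes, samples)
  sel <- select_threshold(S, grid, method,
                          rel_tol = rel_tol, k_sustain = k_sustain)
  build_network(S, sel$tau_star, sel$curves)
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d nodes, %d edges at tau* = %.2f\n",
              length(x$gene_ids), sum(x$adjacency) / 2, x$tau_star))
  invisible(x)
}

#' Edge list of a coexpression network
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @return A tibble: `gene_a`, `gene_b`, `similarity` (gene_a < gene_b).
#' @export
tidy.coexpression_network <- function(x, ...) {
  idx <- which(x$adjacency & upper.tri(x$adjacency), arr.ind = TRUE)
  tibble::tibble(gene_a = x$gene_ids[idx[, 1]],
                 gene_b = x$gene_ids[idx[, 2]],
                 similarity = x$similarity[idx]) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' One-row summary of a coexpression network
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @return A tibble: `n_nodes`, `n_edges`, `tau_star`, `c_obs`, `c_rand`.
#' @export
glance.coexpression_network <- function(x, ...) {
  e <- sum(x$adjacency) / 2
  tibble::tibble(n_nodes = length(x$gene_ids), n_edges = e,
                 tau_star = x$tau_star,
                 c_obs = clustering_coefficient(x$adjacency),
                 c_rand = random_expected_cc(length(x$gene_ids), e))
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency * 1, mode = "undirected")
}

#' Common connectivity patterns between two networks
#'
#' The shared-edge graph keeps the nodes present in both networks and the
#' edges present in both; its connected components with at least 2 nodes are
#' the common connectivity patterns (CCPs), returned largest first with ties
#' broken by the lexicographically smallest member. Symmetric in its
#' arguments.
#'
#' @param net_a,net_b `coexpression_network` objects over a comparable gene
#'   namespace.
#' @return A tibble with one row per (CCP, gene): `ccp_id`, `size`,
#'   `gene_id`. Zero rows when nothing is shared.
#' @export
find_ccps <- function(net_a, net_b) {
  common <- intersect(net_a$gene_ids, net_b$gene_ids)
  empty <- tibble::tibble(ccp_id = integer(), size = integer(),
                          gene_id = character())
  if (length(common) < 2) return(empty)
  A <- net_a$adjacency[common, common, drop = FALSE] &
    net_b$adjacency[common, common, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(A * 1, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  keep <- which(sizes >= 2)
  if (!length(keep)) return(empty)
  members <- lapply(keep, function(i) sort(common[comp$membership == i]))
  ord <- order(-sizes[keep], vapply(members, `[`, "", 1))
  purrr::imap_dfr(members[ord], function(m, i) {
    tibble::tibble(ccp_id = i, size = length(m), gene_id = m)
  })
}

#' Write a network as an edge-list TSV
#' @param net A `coexpression_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_edgelist <- function(net, path) {
  readr::write_tsv(tidy(net), path)
  invisible(path)
}

#' Write a network as GraphML
#' @param net A `coexpression_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::V(g)$tier <- net$degree_tier$tier
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write threshold-selection curves as TSV
#' @param net A `coexpression_network` built with curves.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_curves <- function(net, path) {
  if (is.null(net$curves)) stop("network carries no curves", call. = FALSE)
  readr::write_tsv(net$curves, path)
  invisible(path)
}
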