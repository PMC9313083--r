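#' Collapse probe-level rows to gene level
#'
#' Microarray matrices arrive at probe resolution; downstream stages work per
#' gene. For genes measured by several probes the probe with the highest
#' variance across samples is kept, preserving dynamic range for the
#' correlation networks. Rows absent from the map are dropped with a message.
#'
#' @param ds An `expression_dataset` whose rows are probe ids.
#' @param probe_map Data frame with columns `probe_id` and `gene_id`
#'   (many probes to one gene allowed).
#' @return An `expression_dataset` with one row per gene.
#' @export
collapse_probes <- function(ds, probe_map) {
  stopifnot(is.data.frame(probe_map),
            all(c("probe_id", "gene_id") %in% names(probe_map)))
  if (any(!nzchar(probe_map$gene_id)) || anyNA(probe_map$gene_id)) {
    stop("probe map contains empty gene ids", call. = FALSE)
  }
  map <- stats::setNames(as.character(probe_map$gene_id),
                         as.character(probe_map$probe_id))
  probes <- rownames(ds$values)
  mapped <- probes %in% names(map)
  if (any(!mapped)) message(sum(!mapped), " unmapped probe(s) dropped")
  if (!any(mapped)) stop("no probes left after mapping", call. = FALSE)
  v <- ds$values[mapped, , drop = FALSE]
  gene <- unname(map[rownames(v)])
  rv <- apply(v, 1, stats::var)
  # per gene keep the max-variance probe; first occurrence wins ties
  ord <- order(gene, -rv)
  keep <- ord[!duplicated(gene[ord])]
  keep <- sort(keep)  # preserve original row order
  out <- v[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  expression_dataset(out, ds$sample_class, ds$dataset_id, ds$disease_group)
}

#' Quantile-normalise a dataset across samples
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' row-wise mean of the per-column sorted values. Ties within a column
#' receive the mean of the quantile values they span. Idempotent.
#'
#' @param ds An `expression_dataset` (or a bare genes x samples matrix) with
#'   at least 2 samples; a single column is returned unchanged.
#' @return The input, quantile-normalised.
#' @export
quantile_normalize <- function(ds) {
  if (is.matrix(ds)) {
    if (ncol(ds) < 2) return(ds)
    out <- limma::normalizeQuantiles(ds, ties = TRUE)
    dimnames(out) <- dimnames(ds)
    return(out)
  }
  if (ncol(ds$values) < 2) return(ds)
  out <- limma::normalizeQuantiles(ds$values, ties = TRUE)
  dimnames(out) <- dimnames(ds$values)
  expression_dataset(out, ds$sample_class, ds$dataset_id, ds$disease_group)
}

#' Keep the most variable genes
#'
#' Retains the `ceiling(keep_fraction * n_genes)` genes with the highest
#' variance across all samples, in their original order. `keep_fraction = 1`
#' (the default elsewhere in the pipeline) disables filtering.
#'
#' @param ds An `expression_dataset`.
#' @param keep_fraction Fraction of genes to keep, in (0, 1].
#' @return A filtered `expression_dataset`.
#' @export
variance_filter <- function(ds, keep_fraction) {
  stopifnot(is.numeric(keep_fraction), length(keep_fraction) == 1,
            keep_fraction > 0, keep_fraction <= 1)
  n <- nrow(ds$values)
  k <- ceiling(keep_fraction * n)
  if (k >= n) return(ds)
  rv <- apply(ds$values, 1, stats::var)
  keep <- sort(order(rv, decreasing = TRUE)[seq_len(k)])
  expression_dataset(ds$values[keep, , drop = FALSE], ds$sample_class,
                     ds$dataset_id, ds$disease_group)
}
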