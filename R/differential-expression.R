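#' Log2 fold change between case and control
#'
#' On an already-log2 matrix the fold change is the difference of group
#' means: `mean(case) - mean(control)`.
#'
#' @param case_values,control_values Numeric vectors of log2 expression.
#' @return The log2 fold change (positive = up in cases).
#' @export
log2_fold_change <- function(case_values, control_values) {
  if (!length(case_values) || !length(control_values)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  mean(case_values) - mean(control_values)
}

# Row-vectorised Welch statistics for a genes x samples matrix split into
# case/control columns. Zero variance in both groups is degenerate:
# equal means -> t = 0, p = 1; unequal means -> p = 0, flagged.
welch_rows <- function(case_mat, control_mat) {
  n1 <- ncol(case_mat); n2 <- ncol(control_mat)
  if (n1 < 2 || n2 < 2) stop("need >= 2 values per group", call. = FALSE)
  m1 <- rowMeans(case_mat); m2 <- rowMeans(control_mat)
  v1 <- rowSums((case_mat - m1)^2) / (n1 - 1)
  v2 <- rowSums((control_mat - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  degen <- se2 == 0
  if (any(degen)) {
    same <- degen & (m1 == m2)
    t_stat[same] <- 0; p[same] <- 1
    diff <- degen & (m1 != m2)
    t_stat[diff] <- Inf * sign(m1 - m2)[diff]; p[diff] <- 0
  }
  list(t_stat = t_stat, p_value = p, df = df, degenerate = degen & (m1 != m2))
}

#' Welch unequal-variance t-test
#'
#' Two-sided Welch t with Satterthwaite degrees of freedom. When both groups
#' have zero variance the test is degenerate: equal means give `t = 0, p = 1`;
#' unequal means give `p = 0` with `degenerate = TRUE`.
#'
#' @param case_values,control_values Numeric vectors (>= 2 values each).
#' @return A tibble with `t_stat`, `p_value`, `df`, `degenerate`.
#' @export
welch_t <- function(case_values, control_values) {
  r <- welch_rows(matrix(case_values, nrow = 1),
                  matrix(control_values, nrow = 1))
  tibble::tibble(t_stat = r$t_stat, p_value = r$p_value, df = r$df,
                 degenerate = r$degenerate)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values of the same length.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Apply significance and effect-size thresholds to a DEG table
#'
#' A gene is called `up` when `fdr <= fdr_max` and `log2fc >= min_abs_log2fc`,
#' `down` when `fdr <= fdr_max` and `log2fc <= -min_abs_log2fc`, otherwise
#' `ns`. All thresholds are inclusive.
#'
#' @param deg_tbl Data frame with `log2fc` and `fdr` columns.
#' @param fdr_max Maximum adjusted p-value, in (0, 1]. Default 0.05.
#' @param min_abs_log2fc Minimum absolute log2 fold change. Default 1.
#' @return The input as a tibble with a `direction` column
#'   (`"up"`, `"down"`, `"ns"`).
#' @export
call_degs <- function(deg_tbl, fdr_max = 0.05, min_abs_log2fc = 1) {
  stopifnot(fdr_max > 0, fdr_max <= 1, min_abs_log2fc >= 0)
  dplyr::mutate(
    tibble::as_tibble(deg_tbl),
    direction = dplyr::case_when(
      .data$fdr <= fdr_max & .data$log2fc >= min_abs_log2fc ~ "up",
      .data$fdr <= fdr_max & .data$log2fc <= -min_abs_log2fc ~ "down",
      TRUE ~ "ns"
    )
  )
}

#' Per-dataset differential expression
#'
#' Computes, for every gene of one dataset, the log2 fold change
#' (case minus control means), the Welch t statistic and two-sided p-value,
#' the Benjamini-Hochberg adjusted p-value, and a signed call.
#'
#' @param ds An `expression_dataset`.
#' @inheritParams call_degs
#' @return A tibble with one row per gene: `dataset_id`, `disease_group`,
#'   `gene_id`, `log2fc`, `t_stat`, `p_value`, `fdr`, `direction`.
#' @export
#' @examples
#' cfg <- simulation_config(n_datasets = c(LC = 1, BC = 0, LK = 0),
#'                          n_genes = 50, seed = 1)
#' sim <- simulate_collection(cfg)
#' deg_table(sim$datasets[[1]])
deg_table <- function(ds, fdr_max = 0.05, min_abs_log2fc = 1) {
  case <- ds$values[, ds$sample_class == "case", drop = FALSE]
  ctrl <- ds$values[, ds$sample_class == "control", drop = FALSE]
  w <- welch_rows(case, ctrl)
  tbl <- tibble::tibble(
    dataset_id = ds$dataset_id,
    disease_group = ds$disease_group,
    gene_id = rownames(ds$values),
    log2fc = rowMeans(case) - rowMeans(ctrl),
    t_stat = w$t_stat,
    p_value = w$p_value,
    fdr = bh_adjust(w$p_value)
  )
  call_degs(tbl, fdr_max, min_abs_log2fc)
}
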