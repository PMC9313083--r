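#' Assemble a pipeline configuration
#'
#' Collects everything [run_pipeline()] needs. Datasets can be given either
#' as loaded `expression_dataset` objects or as a manifest data frame with
#' columns `path`, `dataset_id`, `disease_group`, `label_path` (two-column
#' TSV: sample_id, class). Referenced paths are checked at construction.
#'
#' @param datasets List of `expression_dataset` objects, or a manifest data
#'   frame (see Details).
#' @param fdr_max,min_abs_log2fc Per-dataset DEG call thresholds.
#' @param thresholds A [consensus_thresholds()] object.
#' @param keep_fraction Variance-filter fraction; 1 (default) disables it.
#' @param normalize Quantile-normalise each dataset first. Default TRUE.
#' @param tf_list Character vector of TF gene ids, or path to a
#'   one-gene-per-line file, or `NULL` (network stage then uses winners only,
#'   with a warning).
#' @param gene_sets A [gene_set_collection()], a GMT path, or `NULL` to skip
#'   enrichment.
#' @param survival_tbl Data frame of survival records (`subject_id`, `time`,
#'   `event`, one column per gene), or `NULL` to skip survival screening.
#' @param network_grid,network_method Passed to [coexpression_network()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing artifacts.
#' @param seed Integer seed recorded in the report.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(datasets,
                            fdr_max = 0.05, min_abs_log2fc = 1,
                            thresholds = consensus_thresholds(),
                            keep_fraction = 1, normalize = TRUE,
                            tf_list = NULL, gene_sets = NULL,
                            survival_tbl = NULL,
                            network_grid = seq(0.01, 0.99, by = 0.01),
                            network_method = "max_diff",
                            out_dir = NULL, seed = 1L) {
  if (is.data.frame(datasets)) {
    need <- c("path", "dataset_id", "disease_group", "label_path")
    stopifnot(all(need %in% names(datasets)))
    missing_p <- c(datasets$path[!file.exists(datasets$path)],
                   datasets$label_path[!file.exists(datasets$label_path)])
    if (length(missing_p)) {
      stop("missing input files: ", paste(missing_p, collapse = ", "),
           call. = FALSE)
    }
  } else {
    stopifnot(is.list(datasets),
              all(vapply(datasets, inherits, TRUE, "expression_dataset")))
  }
  if (is.character(tf_list) && length(tf_list) == 1 && file.exists(tf_list)) {
    tf_list <- readLines(tf_list, warn = FALSE)
    tf_list <- tf_list[nzchar(tf_list)]
  }
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  structure(list(datasets = datasets, fdr_max = fdr_max,
                 min_abs_log2fc = min_abs_log2fc, thresholds = thresholds,
                 keep_fraction = keep_fraction, normalize = normalize,
                 tf_list = tf_list, gene_sets = gene_sets,
                 survival_tbl = survival_tbl, network_grid = network_grid,
                 network_method = network_method, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [pipeline_config()] arguments,
#' with `datasets` given as a manifest list (each entry: `path`,
#' `dataset_id`, `disease_group`, `label_path`), `tf_list`/`gene_sets` as
#' file paths, and scalar thresholds. Relative paths are resolved against
#' the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  man <- dplyr::bind_rows(lapply(y$datasets, tibble::as_tibble))
  man$path <- resolve(man$path)
  man$label_path <- resolve(man$label_path)
  th <- y$thresholds %||% list()
  pipeline_config(
    datasets = man,
    fdr_max = y$fdr_max %||% 0.05,
    min_abs_log2fc = y$min_abs_log2fc %||% 1,
    thresholds = consensus_thresholds(
      common_lc_min = th$common_lc_min %||% 8,
      unique_lc_min = th$unique_lc_min %||% 7,
      oc_min = th$oc_min %||% 1,
      oc_direction_mode = th$oc_direction_mode %||% "same_sense"
    ),
    keep_fraction = y$keep_fraction %||% 1,
    normalize = y$normalize %||% TRUE,
    tf_list = if (!is.null(y$tf_list)) resolve(y$tf_list),
    gene_sets = if (!is.null(y$gene_sets)) resolve(y$gene_sets),
    out_dir = y$out_dir %||% NULL,
    seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full meta-analysis pipeline
#'
#' Stages, in order: read/validate datasets, per-dataset preprocessing and
#' differential expression, cross-dataset vote tally and winner
#' classification (with TF annotation when a TF list is supplied),
#' per-dataset coexpression networks over the winner + TF gene list,
#' pairwise common connectivity patterns between networks of different
#' disease groups, over-representation analysis of the winner genes, and
#' log-rank survival screening of the winning TFs. Any stage error aborts
#' with the stage name. When `out_dir` is set every table, network and curve
#' is written as TSV/GraphML and the run report as YAML.
#'
#' @param cfg A [pipeline_config()] or a path to a YAML config.
#' @return A run report: list with per-stage record counts, parameters, and
#'   the result tables (`deg`, `tally`, `winners`, `pattern_counts`,
#'   `networks`, `ccps`, `enrichment`, `survival`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- "io"
  report <- list(parameters = list(
    fdr_max = cfg$fdr_max, min_abs_log2fc = cfg$min_abs_log2fc,
    common_lc_min = cfg$thresholds$common_lc_min,
    unique_lc_min = cfg$thresholds$unique_lc_min,
    oc_min = cfg$thresholds$oc_min,
    oc_direction_mode = cfg$thresholds$oc_direction_mode,
    keep_fraction = cfg$keep_fraction, normalize = cfg$normalize,
    network_method = cfg$network_method, seed = cfg$seed
  ))
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  tryCatch({
    datasets <- cfg$datasets
    if (is.data.frame(datasets)) {
      datasets <- purrr::pmap(datasets, function(path, dataset_id,
                                                 disease_group, label_path,
                                                 ...) {
        labs <- utils::read.table(label_path, header = TRUE, sep = "\t",
                                  colClasses = "character")
        read_expression_matrix(path, dataset_id, disease_group, labs)
      })
    }
    report$n_datasets <- length(datasets)

    stage <- "differential_expression"
    deg <- purrr::map_dfr(datasets, function(ds) {
      if (cfg$normalize) ds <- quantile_normalize(ds)
      if (cfg$keep_fraction < 1) ds <- variance_filter(ds, cfg$keep_fraction)
      deg_table(ds, cfg$fdr_max, cfg$min_abs_log2fc)
    })
    report$n_deg_calls <- sum(deg$direction != "ns")

    stage <- "consensus"
    tally <- tally_votes(deg)
    winners <- classify_winner(tally, cfg$thresholds)
    if (!is.null(cfg$tf_list)) {
      winners <- annotate_tf(winners, cfg$tf_list)
    } else {
      warning("no TF list supplied; network stage uses winners only",
              call. = FALSE)
      winners$is_tf <- FALSE
    }
    pattern_counts <- categorize_table(
      dplyr::filter(winners, .data$status != "none"))
    report$n_winners <- sum(winners$status != "none")
    report$n_common_winners <- sum(winners$status == "common_winner")
    report$n_unique_lc_winners <- sum(winners$status == "unique_lc_winner")
    report$n_winner_tfs <- sum(winners$status != "none" & winners$is_tf)

    stage <- "networks"
    winner_genes <- winners$gene_id[winners$status != "none"]
    net_genes <- union(winner_genes, cfg$tf_list %||% character())
    networks <- list()
    if (length(net_genes) >= 3) {
      networks <- purrr::map(datasets, function(ds) {
        g <- intersect(net_genes, gene_ids(ds))
        if (length(g) < 3) return(NULL)
        coexpression_network(ds, g, grid = cfg$network_grid,
                             method = cfg$network_method)
      })
      names(networks) <- purrr::map_chr(datasets, "dataset_id")
      networks <- purrr::compact(networks)
    }
    report$n_networks <- length(networks)

    stage <- "ccp"
    ccps <- tibble::tibble(net_a = character(), net_b = character(),
                           ccp_id = integer(), size = integer(),
                           gene_id = character())
    if (length(networks) >= 2) {
      grp_of <- stats::setNames(purrr::map_chr(datasets, "disease_group"),
                                purrr::map_chr(datasets, "dataset_id"))
      ids <- names(networks)
      pairs <- utils::combn(ids, 2, simplify = FALSE)
      pairs <- purrr::keep(pairs, ~ grp_of[.x[1]] != grp_of[.x[2]])
      ccps <- purrr::map_dfr(pairs, function(p) {
        r <- find_ccps(networks[[p[1]]], networks[[p[2]]])
        if (nrow(r)) dplyr::mutate(r, net_a = p[1], net_b = p[2],
                                   .before = 1) else NULL
      })
    }
    report$n_ccps <- if (nrow(ccps))
      nrow(dplyr::distinct(ccps, .data$net_a, .data$net_b, .data$ccp_id))
    else 0L

    stage <- "enrichment"
    enrichment <- NULL
    if (!is.null(cfg$gene_sets) && length(winner_genes)) {
      q <- intersect(winner_genes, cfg$gene_sets$universe)
      if (length(q)) {
        enrichment <- ora(q, cfg$gene_sets, cfg$fdr_max)
        report$n_enriched <- sum(enrichment$significant)
      }
    }

    stage <- "survival"
    surv <- NULL
    if (!is.null(cfg$survival_tbl)) {
      tf_winners <- winners$gene_id[winners$status != "none" & winners$is_tf]
      avail <- intersect(tf_winners, names(cfg$survival_tbl))
      if (length(avail)) {
        surv <- survival_screen(cfg$survival_tbl, avail)
        report$n_survival_hits <- sum(surv$fdr <= 0.05)
      }
    }

    stage <- "write"
    if (!is.null(out)) {
      readr::write_tsv(deg, file.path(out, "deg_calls.tsv"))
      readr::write_tsv(tally, file.path(out, "vote_tally.tsv"))
      readr::write_tsv(winners, file.path(out, "winners.tsv"))
      readr::write_tsv(pattern_counts, file.path(out, "pattern_counts.tsv"))
      for (nm in names(networks)) {
        write_network_edgelist(networks[[nm]],
                               file.path(out, paste0("network_", nm, ".tsv")))
        write_network_graphml(networks[[nm]],
                              file.path(out,
                                        paste0("network_", nm, ".graphml")))
        write_threshold_curves(networks[[nm]],
                               file.path(out, paste0("curves_", nm, ".tsv")))
      }
      if (nrow(ccps)) readr::write_tsv(ccps, file.path(out, "ccps.tsv"))
      if (!is.null(enrichment)) {
        readr::write_tsv(enrichment, file.path(out, "enrichment.tsv"))
      }
      if (!is.null(surv)) {
        readr::write_tsv(surv, file.path(out, "survival_screen.tsv"))
      }
      yaml::write_yaml(report, file.path(out, "run_report.yaml"))
    }
    c(report, list(deg = deg, tally = tally, winners = winners,
                   pattern_counts = pattern_counts, networks = networks,
                   ccps = ccps, enrichment = enrichment, survival = surv))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Demonstrate the group-pattern partition on the published TF counts
#'
#' Runs [categorize_table()] on the 34 packaged winning-TF count triples and
#' prints the group-pattern histogram together with each row's total.
#'
#' @return Invisibly, a list with `counts` (the histogram tibble) and `rows`
#'   (the per-TF table with recomputed totals).
#' @export
table2_demo <- function() {
  rows <- winning_tf_counts() |>
    dplyr::mutate(total_check = .data$lc + .data$bc + .data$lk,
                  group_pattern = group_pattern_of(.data$lc, .data$bc,
                                                   .data$lk))
  counts <- categorize_table(rows)
  cat("Group-pattern partition of the 34 published winning TFs:\n")
  print(as.data.frame(counts), row.names = FALSE)
  cat("\nPer-TF totals (lc + bc + lk):\n")
  print(as.data.frame(rows[, c("gene_id", "lc", "bc", "lk", "total",
                               "total_check")]), row.names = FALSE)
  invisible(list(counts = counts, rows = rows))
}
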