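#' Consensus vote thresholds
#'
#' Thresholds for classifying winning genes from direction-consistent calls
#' across datasets. Defaults follow the two published rules: a *common
#' winner* is deregulated in the same sense in at least 8 of the 10 lung
#' cancer (LC) datasets and in at least 1 dataset of another cancer type; a
#' *unique LC winner* in at least 7 of the 10 LC datasets and in none of the
#' other types. Thresholds are absolute dataset counts, never rescaled to the
#' collection size.
#'
#' @param common_lc_min Minimum same-direction LC datasets for a common
#'   winner. Default 8.
#' @param unique_lc_min Minimum same-direction LC datasets for a unique LC
#'   winner. Default 7.
#' @param oc_min Minimum other-cancer datasets for a common winner. Default 1.
#' @param oc_direction_mode How other-cancer votes are counted:
#'   `"same_sense"` (only datasets agreeing with the LC direction; default)
#'   or `"any_sense"` (any deregulation).
#' @return A list of class `consensus_thresholds`.
#' @export
consensus_thresholds <- function(common_lc_min = 8, unique_lc_min = 7,
                                 oc_min = 1,
                                 oc_direction_mode = c("same_sense",
                                                       "any_sense")) {
  oc_direction_mode <- match.arg(oc_direction_mode)
  stopifnot(common_lc_min >= 1, unique_lc_min >= 1, oc_min >= 1)
  structure(list(common_lc_min = common_lc_min, unique_lc_min = unique_lc_min,
                 oc_min = oc_min, oc_direction_mode = oc_direction_mode),
            class = "consensus_thresholds")
}

#' Tally direction-consistent DEG calls across datasets
#'
#' Counts, for every gene and disease group, how many of that group's
#' datasets called the gene up and how many down. Genes absent from a
#' dataset contribute nothing there; the gene universe is the union over all
#' datasets.
#'
#' @param deg_tbl A data frame of per-dataset DEG calls (rows from
#'   [deg_table()], possibly `dplyr::bind_rows()` of many datasets), with
#'   columns `dataset_id`, `disease_group`, `gene_id`, `direction`.
#' @return A tibble with one row per gene: `gene_id` plus `up_<g>`,
#'   `down_<g>`, `n_<g>` columns for g in lc, bc, lk (other groups ignored
#'   for the vote but counted in the universe).
#' @export
tally_votes <- function(deg_tbl) {
  deg_tbl <- tibble::as_tibble(deg_tbl)
  need <- c("dataset_id", "disease_group", "gene_id", "direction")
  stopifnot(all(need %in% names(deg_tbl)))
  dup <- deg_tbl |>
    dplyr::count(.data$dataset_id, .data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate dataset_id: gene '", dup$gene_id[[1]],
         "' appears more than once in dataset '", dup$dataset_id[[1]], "'",
         call. = FALSE)
  }
  grp_sizes <- deg_tbl |>
    dplyr::distinct(.data$dataset_id, .data$disease_group) |>
    dplyr::count(.data$disease_group, name = "n_datasets")
  n_of <- function(g) {
    n <- grp_sizes$n_datasets[grp_sizes$disease_group == g]
    if (length(n)) n else 0L
  }
  counts <- deg_tbl |>
    dplyr::filter(.data$disease_group %in% c("LC", "BC", "LK")) |>
    dplyr::group_by(.data$gene_id, .data$disease_group) |>
    dplyr::summarise(up = sum(.data$direction == "up"),
                     down = sum(.data$direction == "down"),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "disease_group",
                       values_from = c("up", "down"),
                       values_fill = 0L,
                       names_glue = "{.value}_{tolower(disease_group)}")
  for (col in c(t(outer(c("up", "down"), c("lc", "bc", "lk"), paste,
                        sep = "_")))) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  all_genes <- unique(deg_tbl$gene_id)
  counts |>
    dplyr::right_join(tibble::tibble(gene_id = all_genes), by = "gene_id") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with(c("up_", "down_")),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::mutate(n_lc = n_of("LC"), n_bc = n_of("BC"), n_lk = n_of("LK")) |>
    dplyr::select("gene_id", "up_lc", "down_lc", "up_bc", "down_bc",
                  "up_lk", "down_lk", "n_lc", "n_bc", "n_lk") |>
    dplyr::arrange(.data$gene_id)
}

#' Classify winning genes from vote tallies
#'
#' Implements the winner rules on a tally table. For each gene the dominant
#' LC direction d* is the one with the larger LC count (a tie gives
#' `direction = "mixed"` and never a winner); `oc` is the other-cancer
#' (BC + LK) vote in mode `oc_direction_mode`. Then
#' `status = "common_winner"` iff the LC count for d* meets `common_lc_min`
#' and `oc >= oc_min`; `status = "unique_lc_winner"` iff it meets
#' `unique_lc_min` and no other-cancer dataset shows deregulation in either
#' direction ("none of the other types of cancer"); otherwise `"none"`. The
#' group-presence
#' pattern (which of LC/BC/LK show any deregulation, in either direction)
#' is reported independently of the thresholds.
#'
#' @param tally Output of [tally_votes()].
#' @param thresholds A [consensus_thresholds()] object.
#' @return A tibble with one row per gene: `gene_id`, `status`, `direction`,
#'   `group_pattern`, `lc`, `bc`, `lk`, `total` (any-direction deregulated
#'   dataset counts per group and their sum).
#' @export
classify_winner <- function(tally, thresholds = consensus_thresholds()) {
  th <- thresholds
  if (any(c(th$common_lc_min, th$unique_lc_min) > max(tally$n_lc, 0))) {
    warning("LC thresholds exceed the number of LC datasets", call. = FALSE)
  }
  tally |>
    tibble::as_tibble() |>
    dplyr::mutate(
      direction = dplyr::case_when(
        .data$up_lc > .data$down_lc ~ "up",
        .data$down_lc > .data$up_lc ~ "down",
        .data$up_lc > 0 ~ "mixed",
        TRUE ~ "none"
      ),
      c_lc = pmax(.data$up_lc, .data$down_lc),
      oc = dplyr::if_else(
        rep(th$oc_direction_mode == "same_sense", dplyr::n()),
        dplyr::case_when(
          .data$direction == "up" ~ .data$up_bc + .data$up_lk,
          .data$direction == "down" ~ .data$down_bc + .data$down_lk,
          TRUE ~ 0L
        ),
        .data$up_bc + .data$down_bc + .data$up_lk + .data$down_lk
      ),
      oc_any = .data$up_bc + .data$down_bc + .data$up_lk + .data$down_lk,
      status = dplyr::case_when(
        .data$direction %in% c("mixed", "none") ~ "none",
        .data$c_lc >= th$common_lc_min & .data$oc >= th$oc_min ~
          "common_winner",
        .data$c_lc >= th$unique_lc_min & .data$oc_any == 0 ~
          "unique_lc_winner",
        TRUE ~ "none"
      ),
      lc = .data$up_lc + .data$down_lc,
      bc = .data$up_bc + .data$down_bc,
      lk = .data$up_lk + .data$down_lk,
      total = .data$lc + .data$bc + .data$lk,
      group_pattern = group_pattern_of(.data$lc, .data$bc, .data$lk)
    ) |>
    dplyr::select("gene_id", "status", "direction", "group_pattern",
                  "lc", "bc", "lk", "total")
}

group_pattern_of <- function(lc, bc, lk) {
  dplyr::case_when(
    lc > 0 & bc > 0 & lk > 0 ~ "LC_BC_LK",
    lc > 0 & bc > 0 ~ "LC_BC",
    lc > 0 & lk > 0 ~ "LC_LK",
    lc > 0 ~ "LC_only",
    TRUE ~ "none"
  )
}

#' Histogram of group-presence patterns
#'
#' Partitions genes by which disease groups show any deregulation: all three
#' (`LC_BC_LK`), lung + breast (`LC_BC`), lung + leukemia (`LC_LK`), lung
#' only (`LC_only`), or `none`. Accepts either [classify_winner()] output
#' (uses its `group_pattern`) or any data frame with `lc`, `bc`, `lk` count
#' columns.
#'
#' @param calls A data frame with a `group_pattern` column, or with `lc`,
#'   `bc`, `lk` columns.
#' @return A tibble with `group_pattern` and `n`, all five levels present.
#' @export
categorize_table <- function(calls) {
  calls <- tibble::as_tibble(calls)
  if (!"group_pattern" %in% names(calls)) {
    stopifnot(all(c("lc", "bc", "lk") %in% names(calls)))
    calls$group_pattern <- group_pattern_of(calls$lc, calls$bc, calls$lk)
  }
  lev <- c("LC_BC_LK", "LC_BC", "LC_LK", "LC_only", "none")
  calls |>
    dplyr::count(group_pattern = factor(.data$group_pattern, levels = lev),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(group_pattern = as.character(.data$group_pattern))
}

#' Flag transcription factors among winner calls
#'
#' @param calls Output of [classify_winner()].
#' @param tf_list Character vector of TF gene ids (non-empty).
#' @return `calls` with a logical `is_tf` column.
#' @export
annotate_tf <- function(calls, tf_list) {
  if (!length(tf_list)) stop("tf_list must be non-empty", call. = FALSE)
  dplyr::mutate(tibble::as_tibble(calls),
                is_tf = .data$gene_id %in% tf_list)
}

#' Published winning-TF dataset counts
#'
#' The 34 winning transcription factors with the number of lung cancer (LC),
#' breast cancer (BC), and leukemia (LK) datasets in which each was
#' deregulated, as printed in the source study, shipped as a plain-text
#' fixture. Useful for demonstrating [categorize_table()].
#'
#' @return A tibble: `gene_id`, `lc`, `bc`, `lk`, `total`.
#' @export
winning_tf_counts <- function() {
  path <- system.file("extdata", "winning_tf_counts.tsv",
                      package = "consensusdeg", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ciiii")
}

#' Published winning-DEG direction counts
#'
#' Printed tallies of common and unique-LC winning DEGs by direction, with
#' the printed totals (296 common, 98 unique LC).
#'
#' @return A tibble: `category`, `direction`, `n`, `printed_total`.
#' @export
winning_deg_counts <- function() {
  path <- system.file("extdata", "winning_deg_counts.tsv",
                      package = "consensusdeg", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ccii")
}
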