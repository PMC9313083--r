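#' Kaplan-Meier product-limit estimate
#'
#' Estimates overall survival from `(time, event)` records: at each distinct
#' event time with `d` events among `n` at risk, the survival steps down by
#' the factor `1 - d/n`. Censored subjects leave the risk set after their
#' time; at tied times, events precede censorings (the standard convention).
#' Backed by [survival::survfit()].
#'
#' @param records Data frame with `time` (> 0) and `event`
#'   (1 = death observed, 0 = censored) columns.
#' @return An object of class `km_curve` wrapping the fit, with a [tidy()]
#'   method giving `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1, all(records$time > 0),
            all(records$event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  structure(list(fit = fit, n = nrow(records)), class = "km_curve")
}

#' @export
tidy.km_curve <- function(x, ...) {
  f <- x$fit
  tibble::tibble(time = f$time, n_risk = f$n.risk, n_event = f$n.event,
                 n_censor = f$n.censor, survival = f$surv)
}

#' Survival probability at given times
#'
#' Step-function evaluation of a [km_estimate()] curve; S = 1 before the
#' first event.
#'
#' @param curve A `km_curve`.
#' @param times Times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  tt <- tidy(curve)
  ev <- tt[tt$n_event > 0, ]
  vapply(times, function(t0) {
    below <- ev$time <= t0
    if (!any(below)) 1 else ev$survival[max(which(below))]
  }, numeric(1))
}

#' Dichotomize subjects by expression
#'
#' Splits records into high/low expression groups. `median` mode assigns
#' `high = expression > median` (ties go to the low group). `best_cutoff`
#' scans the observed expression values between the 25th and 75th quantiles
#' and keeps the cutpoint maximizing the log-rank chi-square; the resulting
#' p-value is cutoff-optimized and flagged as such downstream.
#'
#' @param records Data frame with `time`, `event`, `expression` columns
#'   (>= 4 rows, expression not constant).
#' @param mode `"median"` (default) or `"best_cutoff"`.
#' @return The records as a tibble with a `group` column (`"high"`/`"low"`)
#'   and attributes `cutoff` and `cutoff_optimized`.
#' @export
dichotomize <- function(records, mode = c("median", "best_cutoff")) {
  mode <- match.arg(mode)
  records <- tibble::as_tibble(records)
  stopifnot(nrow(records) >= 4)
  x <- records$expression
  if (stats::var(x) == 0) stop("expression is constant; cannot split",
                               call. = FALSE)
  if (mode == "median") {
    cut <- stats::median(x)
  } else {
    qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    cand <- sort(unique(x[x >= qs[1] & x <= qs[2]]))
    cand <- cand[cand < max(x)]  # both groups must stay non-empty
    if (!length(cand)) cand <- stats::median(x)
    chi2 <- vapply(cand, function(cc) {
      g <- x > cc
      if (!any(g) || all(g)) return(-Inf)
      lr <- logrank_test(records[g, ], records[!g, ])
      if (lr$degenerate) -Inf else lr$chi2
    }, numeric(1))
    cut <- cand[which.max(chi2)]
  }
  out <- dplyr::mutate(records,
                       group = dplyr::if_else(x > cut, "high", "low"))
  attr(out, "cutoff") <- cut
  attr(out, "cutoff_optimized") <- mode == "best_cutoff"
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison over the pooled distinct event times:
#' observed minus expected events for group A with the hypergeometric
#' variance, `chi2 = (sum O - sum E)^2 / sum V`, p from chi-square with 1 df,
#' and a Mantel-Haenszel-style hazard ratio `(O_A/E_A) / (O_B/E_B)`. Backed
#' by [survival::survdiff()]. With no usable event times the result is
#' flagged degenerate (`chi2 = 0`, `p = 1`).
#'
#' @param group_a,group_b Data frames with `time` and `event` columns.
#' @return A one-row tibble: `chi2`, `p_value`, `hazard_ratio` (A vs B),
#'   `n_a`, `n_b`, `degenerate`.
#' @export
logrank_test <- function(group_a, group_b) {
  stopifnot(nrow(group_a) >= 1, nrow(group_b) >= 1)
  df <- rbind(
    data.frame(time = group_a$time, event = group_a$event, g = "A"),
    data.frame(time = group_b$time, event = group_b$event, g = "B")
  )
  if (sum(df$event) == 0) {
    return(tibble::tibble(chi2 = 0, p_value = 1, hazard_ratio = NA_real_,
                          n_a = nrow(group_a), n_b = nrow(group_b),
                          degenerate = TRUE))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  v <- if (is.matrix(sd_$var)) sd_$var[1, 1] else sd_$var[1]
  if (!is.finite(v) || v <= 0) {
    return(tibble::tibble(chi2 = 0, p_value = 1, hazard_ratio = NA_real_,
                          n_a = nrow(group_a), n_b = nrow(group_b),
                          degenerate = TRUE))
  }
  chi2 <- unname(sd_$chisq)
  hr <- (sd_$obs[1] / sd_$exp[1]) / (sd_$obs[2] / sd_$exp[2])
  tibble::tibble(chi2 = chi2,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 hazard_ratio = unname(hr),
                 n_a = nrow(group_a), n_b = nrow(group_b),
                 degenerate = FALSE)
}

#' Screen genes for survival association
#'
#' For each gene: dichotomize subjects by that gene's expression and run the
#' log-rank test between the high and low groups.
#'
#' @param surv_tbl Data frame with `subject_id`, `time`, `event`, and one
#'   numeric column per gene (wide), or `gene_id`/`expression` columns
#'   (long).
#' @param genes Genes to screen; default all gene columns.
#' @param mode Passed to [dichotomize()].
#' @return A tibble with one row per gene: `gene_id`, `cutoff`, `chi2`,
#'   `p_value`, `fdr`, `hazard_ratio` (high vs low), `n_high`, `n_low`,
#'   `cutoff_optimized`.
#' @export
survival_screen <- function(surv_tbl, genes = NULL,
                            mode = c("median", "best_cutoff")) {
  mode <- match.arg(mode)
  surv_tbl <- tibble::as_tibble(surv_tbl)
  if (all(c("gene_id", "expression") %in% names(surv_tbl))) {
    long <- surv_tbl
  } else {
    if (is.null(genes)) {
      genes <- setdiff(names(surv_tbl)[vapply(surv_tbl, is.numeric, TRUE)],
                       c("time", "event"))
    }
    long <- tidyr::pivot_longer(surv_tbl, dplyr::all_of(genes),
                                names_to = "gene_id",
                                values_to = "expression")
  }
  if (!is.null(genes)) long <- dplyr::filter(long, .data$gene_id %in% genes)
  res <- long |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      grp <- dichotomize(d, mode)
      lr <- logrank_test(grp[grp$group == "high", ],
                         grp[grp$group == "low", ])
      tibble::tibble(cutoff = attr(grp, "cutoff"), chi2 = lr$chi2,
                     p_value = lr$p_value, hazard_ratio = lr$hazard_ratio,
                     n_high = lr$n_a, n_low = lr$n_b,
                     cutoff_optimized = attr(grp, "cutoff_optimized"))
    }) |>
    dplyr::ungroup()
  res |>
    dplyr::mutate(fdr = bh_adjust(.data$p_value)) |>
    dplyr::select("gene_id", "cutoff", "chi2", "p_value", "fdr",
                  "hazard_ratio", "n_high", "n_low", "cutoff_optimized") |>
    dplyr::arrange(.data$p_value)
}
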