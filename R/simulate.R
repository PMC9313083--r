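#' Simulation configuration
#'
#' Describes a synthetic multi-cohort collection with the structure the
#' meta-analysis assumes: several datasets per disease group, planted
#' direction-consistent differentially expressed genes, planted coexpression
#' modules driven by latent factors, transcription-factor labels, and
#' (optionally) survival hazards tied to chosen genes. Defaults mirror the
#' study design the pipeline was built for: 10 lung cancer, 5 breast cancer,
#' and 5 leukemia datasets of 20 samples per arm over 2000 genes, with
#' baseline log2 expression Normal(8, 1).
#'
#' @param n_datasets Named integer vector: datasets per group
#'   (`c(LC = 10, BC = 5, LK = 5)`).
#' @param samples_per_arm Samples per arm (case and control) per dataset.
#' @param n_genes Number of genes; ids are `g0001`, `g0002`, ...
#' @param winners Data frame of planted winners: `gene_id`, `direction`
#'   (`"up"`/`"down"`), `effect` (case-minus-control shift in log2 units;
#'   with the default `noise_sd = 1` this equals the effect in SD units),
#'   and per-group dataset fractions `frac_lc`, `frac_bc`, `frac_lk` in
#'   \[0, 1\]. `NULL` for none.
#' @param modules Data frame of planted coexpression modules: `module_id`,
#'   `gene_id`, `rho` (target within-module Pearson correlation). `NULL`
#'   for none.
#' @param tf_fraction Fraction of genes labelled as transcription factors.
#' @param baseline_mean,baseline_sd Per-gene baseline level distribution.
#' @param noise_sd Residual SD per observation (the "SD unit" of `effect`).
#' @param survival_betas Named numeric vector: per-gene log-hazard
#'   coefficients for [simulate_survival()].
#' @param base_rate Baseline exponential event rate per month.
#' @param censoring_rate Target expected fraction of censored subjects.
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_datasets = c(LC = 10, BC = 5, LK = 5),
                              samples_per_arm = 20,
                              n_genes = 2000,
                              winners = NULL,
                              modules = NULL,
                              tf_fraction = 0.05,
                              baseline_mean = 8, baseline_sd = 1,
                              noise_sd = 1,
                              survival_betas = NULL,
                              base_rate = 1 / 36,
                              censoring_rate = 0.3,
                              seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(all(n_datasets >= 0), samples_per_arm >= 2, n_genes >= 1,
            tf_fraction >= 0, tf_fraction <= 1, noise_sd >= 0,
            censoring_rate >= 0, censoring_rate < 1)
  if (!is.null(winners)) {
    stopifnot(all(c("gene_id", "direction", "effect",
                    "frac_lc", "frac_bc", "frac_lk") %in% names(winners)),
              all(winners$effect >= 0),
              all(winners$direction %in% c("up", "down")))
    fr <- c(winners$frac_lc, winners$frac_bc, winners$frac_lk)
    if (any(fr < 0 | fr > 1)) stop("winner fractions must lie in [0, 1]",
                                   call. = FALSE)
  }
  if (!is.null(modules)) {
    stopifnot(all(c("module_id", "gene_id", "rho") %in% names(modules)),
              all(modules$rho > 0 & modules$rho < 1))
  }
  structure(list(n_datasets = n_datasets, samples_per_arm = samples_per_arm,
                 n_genes = n_genes, winners = winners, modules = modules,
                 tf_fraction = tf_fraction, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 survival_betas = survival_betas, base_rate = base_rate,
                 censoring_rate = censoring_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a multi-cohort expression collection with planted truth
#'
#' Per gene a baseline level is drawn once (Normal(`baseline_mean`,
#' `baseline_sd`)) and shared across datasets. Module genes are generated as
#' `sqrt(rho) * latent + sqrt(1 - rho) * noise` around their baseline so the
#' expected within-module Pearson correlation equals `rho`; other genes are
#' baseline plus independent Normal(0, `noise_sd`) noise. Each planted
#' winner's effect (`direction` sign times `effect`, log2 units) is added to
#' the case arm of a seeded random subset of each group's datasets of the
#' configured fraction. All randomness flows from `cfg$seed`, so the same
#' config reproduces the same collection exactly.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `datasets` (list of `expression_dataset`) and `truth`
#'   (tibble: `gene_id`, `is_winner`, `direction`, `effect`, `module_id`,
#'   `is_tf`, `survival_beta`).
#' @export
simulate_collection <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  names(baseline) <- genes

  tf_n <- round(cfg$tf_fraction * cfg$n_genes)
  tfs <- if (tf_n > 0) sample(genes, tf_n) else character()

  mod_id <- stats::setNames(rep(NA_character_, cfg$n_genes), genes)
  mod_rho <- stats::setNames(rep(NA_real_, cfg$n_genes), genes)
  if (!is.null(cfg$modules)) {
    mod_id[cfg$modules$gene_id] <- cfg$modules$module_id
    mod_rho[cfg$modules$gene_id] <- cfg$modules$rho
  }

  # which datasets of each group carry each winner's effect
  groups <- rep(names(cfg$n_datasets), cfg$n_datasets)
  ds_ids <- paste0(groups, "_", stats::ave(seq_along(groups), groups,
                                           FUN = seq_along))
  effect_map <- matrix(0, cfg$n_genes, length(ds_ids),
                       dimnames = list(genes, ds_ids))
  if (!is.null(cfg$winners)) {
    for (i in seq_len(nrow(cfg$winners))) {
      w <- cfg$winners[i, ]
      sgn <- if (w$direction == "up") 1 else -1
      for (g in c("LC", "BC", "LK")) {
        frac <- w[[paste0("frac_", tolower(g))]]
        in_g <- which(groups == g)
        k <- round(frac * length(in_g))
        if (k > 0) {
          chosen <- sample(in_g, k)
          effect_map[w$gene_id, chosen] <- sgn * w$effect
        }
      }
    }
  }

  datasets <- vector("list", length(ds_ids))
  for (d in seq_along(ds_ids)) {
    n_arm <- cfg$samples_per_arm
    n_s <- 2 * n_arm
    cls <- rep(c("control", "case"), each = n_arm)
    vals <- matrix(baseline, cfg$n_genes, n_s) +
      cfg$noise_sd * matrix(stats::rnorm(cfg$n_genes * n_s), cfg$n_genes)
    # overwrite module genes with latent-factor structure
    if (!is.null(cfg$modules)) {
      for (m in unique(cfg$modules$module_id)) {
        mg <- cfg$modules$gene_id[cfg$modules$module_id == m]
        rho <- cfg$modules$rho[cfg$modules$module_id == m][1]
        latent <- stats::rnorm(n_s)
        noise <- matrix(stats::rnorm(length(mg) * n_s), length(mg))
        vals[match(mg, genes), ] <- baseline[mg] + cfg$noise_sd *
          (sqrt(rho) * matrix(latent, length(mg), n_s, byrow = TRUE) +
             sqrt(1 - rho) * noise)
      }
    }
    vals[, cls == "case"] <- vals[, cls == "case"] + effect_map[, d]
    rownames(vals) <- genes
    colnames(vals) <- sprintf("%s_s%02d", ds_ids[d], seq_len(n_s))
    datasets[[d]] <- expression_dataset(vals, cls, ds_ids[d], groups[d])
  }

  betas <- stats::setNames(rep(0, cfg$n_genes), genes)
  if (!is.null(cfg$survival_betas)) {
    betas[names(cfg$survival_betas)] <- cfg$survival_betas
  }
  truth <- tibble::tibble(
    gene_id = genes,
    is_winner = if (is.null(cfg$winners)) FALSE else
      genes %in% cfg$winners$gene_id,
    direction = if (is.null(cfg$winners)) NA_character_ else
      cfg$winners$direction[match(genes, cfg$winners$gene_id)],
    effect = if (is.null(cfg$winners)) 0 else
      dplyr::coalesce(cfg$winners$effect[match(genes, cfg$winners$gene_id)],
                      0),
    module_id = unname(mod_id),
    is_tf = genes %in% tfs,
    survival_beta = unname(betas)
  )
  list(datasets = datasets, truth = truth)
}

#' Simulate survival records with expression-linked hazards
#'
#' Event times are exponential with subject rate
#' `base_rate * exp(sum_g beta_g * z_g)` where `z_g` is the standardized
#' expression of gene g. Censoring times are independent exponentials whose
#' rate is solved numerically so the expected censored fraction equals
#' `censoring_rate` (0 means no censoring). A subject's `event` is 1 when
#' the event time falls at or before the censoring time.
#'
#' @param expr Numeric matrix of expression, genes in rows, subjects in
#'   columns (row names = gene ids).
#' @param betas Named numeric vector of log-hazard coefficients per gene.
#' @param base_rate Baseline event rate per month.
#' @param censoring_rate Target expected censored fraction in \[0, 1).
#' @param seed Integer seed.
#' @return A tibble: `subject_id`, `time` (months), `event`, plus one
#'   `expression` column per beta gene when a single gene is supplied, else
#'   the gene columns.
#' @export
simulate_survival <- function(expr, betas, base_rate = 1 / 36,
                              censoring_rate = 0.3, seed) {
  stopifnot(!missing(seed), all(names(betas) %in% rownames(expr)),
            censoring_rate >= 0, censoring_rate < 1)
  set.seed(as.integer(seed))
  n <- ncol(expr)
  z <- t(scale(t(expr[names(betas), , drop = FALSE])))
  z[is.nan(z)] <- 0
  lp <- as.vector(t(z) %*% betas)
  rate <- base_rate * exp(lp)
  time_event <- stats::rexp(n, rate)
  if (censoring_rate == 0) {
    time <- time_event
    event <- rep(1L, n)
  } else {
    # P(censored | rates) = mean(rc / (rc + rate)); solve for rc
    f <- function(rc) mean(rc / (rc + rate)) - censoring_rate
    rc <- stats::uniroot(f, c(1e-12, 1e6 * base_rate))$root
    time_cens <- stats::rexp(n, rc)
    event <- as.integer(time_event <= time_cens)
    time <- pmin(time_event, time_cens)
  }
  out <- tibble::tibble(
    subject_id = sprintf("p%03d", seq_len(n)),
    time = time,
    event = event
  )
  if (length(betas) == 1) {
    out$expression <- as.vector(expr[names(betas), ])
  } else {
    for (g in names(betas)) out[[g]] <- as.vector(expr[g, ])
  }
  out
}
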