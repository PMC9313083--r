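deg_row <- function(dataset_id, group, gene, direction) {
  tibble::tibble(dataset_id = dataset_id, disease_group = group,
                 gene_id = gene, direction = direction)
}

# a collection of call tables: 10 LC, 5 BC, 5 LK datasets
make_calls <- function(gene, up_lc, down_lc = 0, up_bc = 0, up_lk = 0) {
  ids <- c(paste0("LC", 1:10), paste0("BC", 1:5), paste0("LK", 1:5))
  grp <- rep(c("LC", "BC", "LK"), c(10, 5, 5))
  dir <- rep("ns", 20)
  dir[seq_len(up_lc)] <- "up"
  if (down_lc) dir[(up_lc + 1):(up_lc + down_lc)] <- "down"
  if (up_bc) dir[10 + seq_len(up_bc)] <- "up"
  if (up_lk) dir[15 + seq_len(up_lk)] <- "up"
  deg_row(ids, grp, gene, dir)
}

test_that("vote tally counts direction-consistent calls per group", {
  calls <- dplyr::bind_rows(
    make_calls("ZBTB16", up_lc = 9, up_bc = 4, up_lk = 3),
    make_calls("quiet", up_lc = 0),
    make_calls("split", up_lc = 3, down_lc = 4)
  )
  tally <- tally_votes(calls)
  z <- tally[tally$gene_id == "ZBTB16", ]
  expect_identical(c(z$up_lc, z$up_bc, z$up_lk), c(9L, 4L, 3L))
  q <- tally[tally$gene_id == "quiet", ]
  expect_true(all(c(q$up_lc, q$down_lc, q$up_bc, q$down_bc,
                    q$up_lk, q$down_lk) == 0))
  s <- tally[tally$gene_id == "split", ]
  expect_identical(c(s$up_lc, s$down_lc), c(3L, 4L))
  expect_identical(c(z$n_lc, z$n_bc, z$n_lk), c(10L, 5L, 5L))
})

test_that("a gene duplicated within one dataset errors", {
  calls <- dplyr::bind_rows(
    deg_row("LC1", "LC", "gA", "up"),
    deg_row("LC1", "LC", "gA", "down")
  )
  expect_error(tally_votes(calls), "duplicate dataset_id")
})

test_that("winner classification follows the published rules", {
  calls <- dplyr::bind_rows(
    make_calls("SOX17", up_lc = 10, up_bc = 3),            # common, LC&BC
    make_calls("FOXF1", up_lc = 8),                        # unique LC
    make_calls("quiet", up_lc = 0),                        # none
    make_calls("tied", up_lc = 5, down_lc = 4)             # below thresholds
  )
  w <- classify_winner(tally_votes(calls))
  w <- w[match(c("SOX17", "FOXF1", "quiet", "tied"), w$gene_id), ]
  expect_identical(w$status, c("common_winner", "unique_lc_winner",
                               "none", "none"))
  expect_identical(w$group_pattern, c("LC_BC", "LC_only", "none", "LC_only"))
  expect_identical(w$total, c(13L, 8L, 0L, 9L))

  # an exact LC tie gives direction "mixed" and never a winner
  tie <- classify_winner(tally_votes(make_calls("t", up_lc = 4,
                                                down_lc = 4)))
  expect_identical(tie$direction, "mixed")
  expect_identical(tie$status, "none")
})

test_that("other-cancer vote counting modes differ as documented", {
  # up in 8 LC, down in 2 BC: discordant other-cancer deregulation
  ids <- c(paste0("LC", 1:10), paste0("BC", 1:5))
  grp <- rep(c("LC", "BC"), c(10, 5))
  dir <- c(rep("up", 8), "ns", "ns", "down", "down", "ns", "ns", "ns")
  tally <- tally_votes(deg_row(ids, grp, "gX", dir))
  same <- classify_winner(tally, consensus_thresholds())
  any_ <- classify_winner(tally,
                          consensus_thresholds(oc_direction_mode =
                                                 "any_sense"))
  expect_identical(same$status, "none")  # oc = 0 in same sense, but bc > 0
  expect_identical(any_$status, "common_winner")
  # group pattern always uses any-direction counts
  expect_identical(same$group_pattern, "LC_BC")
})

test_that("common and unique winner statuses are mutually exclusive", {
  set.seed(5)
  for (i in 1:200) {
    tally <- tibble::tibble(
      gene_id = "g", up_lc = sample(0:10, 1), down_lc = 0L,
      up_bc = sample(0:5, 1), down_bc = sample(0:5, 1),
      up_lk = sample(0:5, 1), down_lk = sample(0:5, 1),
      n_lc = 10L, n_bc = 5L, n_lk = 5L
    )
    ch <- 0:(10 - tally$up_lc)
    tally$down_lc <- ch[sample.int(length(ch), 1)]
    w <- classify_winner(tally)
    expect_true(w$status %in% c("common_winner", "unique_lc_winner", "none"))
    # with defaults no gene with max-direction LC count <= 6 ever wins
    if (max(tally$up_lc, tally$down_lc) <= 6) {
      expect_identical(w$status, "none")
    }
    if (w$status == "common_winner") {
      expect_false(w$group_pattern %in% c("LC_only", "none"))
    }
    if (w$status == "unique_lc_winner") {
      expect_identical(w$group_pattern, "LC_only")
    }
  }
})

test_that("group-pattern histogram partitions the published TF counts", {
  counts <- categorize_table(winning_tf_counts())
  expect_identical(counts$n[match(c("LC_BC_LK", "LC_BC", "LC_LK", "LC_only"),
                                  counts$group_pattern)],
                   c(13L, 9L, 6L, 6L))
  empty <- categorize_table(tibble::tibble(lc = integer(), bc = integer(),
                                           lk = integer()))
  expect_true(all(empty$n == 0))
  one <- categorize_table(tibble::tibble(lc = 1, bc = 1, lk = 1))
  expect_identical(one$n[one$group_pattern == "LC_BC_LK"], 1L)
})

test_that("TF annotation flags exactly the listed genes", {
  calls <- classify_winner(tally_votes(dplyr::bind_rows(
    make_calls("gA", up_lc = 9, up_bc = 1),
    make_calls("gB", up_lc = 8)
  )))
  out <- annotate_tf(calls, c("gA", "zzz"))
  expect_identical(out$is_tf[match(c("gA", "gB"), out$gene_id)],
                   c(TRUE, FALSE))
  none <- annotate_tf(calls, "not_present")
  expect_false(any(none$is_tf))
  expect_error(annotate_tf(calls, character()), "non-empty")
})

test_that("planted winners are recovered through the full consensus layer", {
  winners <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:6),
    direction = rep(c("up", "down"), 3),
    effect = 2,
    frac_lc = c(1, 0.9, 0.8, 0.8, 0.7, 0.7),
    frac_bc = c(0.6, 0.4, 0.2, 0, 0, 0),
    frac_lk = c(0.4, 0.2, 0.2, 0, 0, 0)
  )
  expected_status <- c(rep("common_winner", 3), rep("unique_lc_winner", 3))

  run_once <- function(noise_sd, seed, n_genes = 100) {
    cfg <- simulation_config(samples_per_arm = 20, n_genes = n_genes,
                             winners = winners, noise_sd = noise_sd,
                             seed = seed)
    sim <- simulate_collection(cfg)
    deg <- purrr::map_dfr(sim$datasets, deg_table)
    classify_winner(tally_votes(deg))
  }

  # zero noise: exact recovery, no false positives or negatives
  w0 <- run_once(0, seed = 21)
  got <- w0[w0$status != "none", ]
  expect_identical(sort(got$gene_id), winners$gene_id)
  expect_identical(got$status[match(winners$gene_id, got$gene_id)],
                   expected_status)
  expect_identical(got$direction[match(winners$gene_id, got$gene_id)],
                   winners$direction)

  # noise sd = effect / 4: sensitivity >= 0.95 over 10 seeds
  hits <- 0; total <- 0
  for (s in 1:10) {
    w <- run_once(0.5, seed = 300 + s, n_genes = 50)
    found <- w$gene_id[w$status != "none"]
    hits <- hits + sum(winners$gene_id %in% found)
    total <- total + nrow(winners)
  }
  expect_gte(hits / total, 0.95)
})
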