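test_that("absolute Pearson similarity matches the direct formula", {
  set.seed(9)
  m <- matrix(rnorm(12, 8), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  ds <- expression_dataset(m, rep(c("control", "case"), each = 2), "d", "LC")
  S <- pearson_abs_similarity(ds)
  expect_equal(unname(diag(S)), rep(1, 3))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(S[i, j], abs(cor(m[i, ], m[j, ])), tolerance = 1e-10)
    expect_equal(S[i, j], S[j, i], tolerance = 1e-12)
  }

  # perfect anticorrelation has similarity 1
  m2 <- rbind(g1 = c(1, 2, 3, 4), g2 = c(8, 6, 4, 2),
              g3 = c(5, 1, 2, 0.5))
  colnames(m2) <- paste0("s", 1:4)
  ds2 <- expression_dataset(m2, rep(c("control", "case"), each = 2),
                            "d", "LC")
  expect_equal(pearson_abs_similarity(ds2)["g1", "g2"], 1)

  # constant genes get similarity 0, flagged
  m2["g3", ] <- 7
  ds3 <- expression_dataset(m2, rep(c("control", "case"), each = 2),
                            "d", "LC")
  expect_warning(S3 <- pearson_abs_similarity(ds3), "constant")
  expect_equal(unname(S3["g3", c("g1", "g2")]), c(0, 0))
  expect_equal(S3["g3", "g3"], 1)
})

test_that("clustering coefficient matches known graphs and brute force", {
  k3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(clustering_coefficient(k3), 1)
  c4 <- rbind(c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 0, 1, 0))
  expect_equal(clustering_coefficient(c4), 0)
  k4_minus <- matrix(1, 4, 4) - diag(4)
  k4_minus[1, 2] <- k4_minus[2, 1] <- 0
  expect_equal(clustering_coefficient(k4_minus), 5 / 6)
  # no node of degree >= 2
  expect_equal(clustering_coefficient(diag(0, 4)), 0)

  set.seed(13)
  for (i in 1:100) {
    A <- random_adjacency(sample(4:12, 1), runif(1, 0.2, 0.7))
    expect_equal(clustering_coefficient(A), oracle_cc(A))
  }
})

test_that("random-graph expectation is the edge density", {
  expect_equal(random_expected_cc(4, 6), 1)
  expect_equal(random_expected_cc(10, 0), 0)
  expect_equal(random_expected_cc(4, 5), 5 / 6)
})

test_that("edge sets are nested as the threshold rises", {
  set.seed(17)
  m <- matrix(rnorm(80, 8), 10, 8,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:8)))
  ds <- expression_dataset(m, rep(c("control", "case"), each = 4), "d", "LC")
  S <- pearson_abs_similarity(ds)
  taus <- c(0.2, 0.4, 0.6, 0.8)
  adjs <- lapply(taus, function(t) {
    A <- S >= t; diag(A) <- FALSE; A
  })
  for (i in 1:3) {
    expect_true(all(adjs[[i + 1]] <= adjs[[i]]))
  }
  sel <- select_threshold(S)
  expect_true(all(diff(sel$curves$n_edges) <= 0))
})

test_that("threshold selection isolates planted modules at zero noise", {
  ds <- two_module_dataset()
  S <- pearson_abs_similarity(ds)
  sel <- select_threshold(S)
  net <- build_network(S, sel$tau_star, sel$curves)
  el <- tidy(net)
  mod_of <- function(g) sub("_.*", "", g)
  # edges are exactly the within-module pairs
  expect_true(all(mod_of(el$gene_a) == mod_of(el$gene_b)))
  expect_equal(nrow(el), 2 * choose(10, 2))
  # module memberships recovered as connected components
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(net$adjacency * 1,
                                        mode = "undirected"))
  expect_equal(comp$no, 2)

  # constant-D similarity: tie broken at the smallest grid point
  S1 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  class(S1) <- c("similarity_matrix", class(S1))
  expect_equal(select_threshold(S1)$tau_star, 0.01)

  S0 <- diag(4)
  dimnames(S0) <- list(letters[1:4], letters[1:4])
  expect_error(select_threshold(S0), "no threshold")
})

test_that("degree tiers mark hubs and isolated nodes", {
  nodes <- c("hub", paste0("leaf", 1:5), "lonely")
  net <- network_from_edges(nodes,
                            lapply(paste0("leaf", 1:5),
                                   function(l) c("hub", l)))
  tier <- net$degree_tier
  expect_identical(tier$tier[tier$gene_id == "hub"], "most")
  expect_identical(tier$tier[tier$gene_id == "lonely"], "less")
  expect_identical(tier$degree[tier$gene_id == "lonely"], 0)
})

test_that("CCPs are the shared connected components, symmetric in inputs", {
  nodes <- paste0("n", 1:9)
  path_edges <- lapply(1:6, function(i) c(paste0("n", i), paste0("n", i + 1)))
  net_a <- network_from_edges(nodes, c(path_edges, list(c("n8", "n9"))))
  net_b <- network_from_edges(nodes, c(path_edges, list(c("n1", "n9"))))
  ccp <- find_ccps(net_a, net_b)
  # exactly the 7-node path shared by both networks
  expect_identical(unique(ccp$ccp_id), 1L)
  expect_setequal(ccp$gene_id, paste0("n", 1:7))
  expect_identical(unique(ccp$size), 7L)
  expect_identical(find_ccps(net_b, net_a), ccp)

  # identical networks: CCPs are the components of size >= 2
  self <- find_ccps(net_a, net_a)
  expect_identical(unique(self$size), c(7L, 2L))

  # disjoint namespaces share nothing
  net_c <- network_from_edges(c("x1", "x2"), list(c("x1", "x2")))
  expect_identical(nrow(find_ccps(net_a, net_c)), 0L)

  # ordering: largest first, ties by smallest member
  net_d <- network_from_edges(nodes, list(c("n1", "n2"), c("n8", "n9"),
                                          c("n4", "n5")))
  d <- find_ccps(net_d, net_d)
  expect_identical(d$gene_id[!duplicated(d$ccp_id)], c("n1", "n4", "n8"))
})

test_that("planted modules are recovered across datasets (ARI >= 0.95)", {
  skip_if_not_installed("mclust")
  # 20 module genes embedded among 40 background genes, as in pipeline use
  genes <- sprintf("g%04d", 1:60)
  modules <- tibble::tibble(module_id = rep(c("m1", "m2"), each = 10),
                            gene_id = sprintf("g%04d", 21:40), rho = 0.9)
  truth <- setNames(rep(0L, 60), genes)
  truth[modules$gene_id] <- as.integer(factor(modules$module_id))
  aris <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_datasets = c(LC = 2, BC = 0, LK = 0),
                             samples_per_arm = 20, n_genes = 60,
                             modules = modules, seed = 400 + s)
    sim <- simulate_collection(cfg)
    nets <- lapply(sim$datasets, coexpression_network)
    ccp <- find_ccps(nets[[1]], nets[[2]])
    labels <- setNames(rep(0L, 60), genes)
    labels[ccp$gene_id] <- ccp$ccp_id
    c(mclust::adjustedRandIndex(labels, truth),
      oracle_ari(labels, truth))
  }, numeric(2))
  expect_equal(aris[1, ], aris[2, ], tolerance = 1e-12)
  expect_gte(mean(aris[1, ]), 0.95)
})
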