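# build a network directly from a hand-written p matrix
net_from_p <- function(p, alpha = 0.05) {
  dimnames(p) <- list(paste0("t", seq_len(nrow(p))),
                      paste0("t", seq_len(nrow(p))))
  build_network(fake_correlation_result(p), alpha)
}

# p matrix realizing a given edge list on n nodes
p_for_edges <- function(n, edges) {
  p <- matrix(1, n, n)
  for (e in edges) p[e[1], e[2]] <- p[e[2], e[1]] <- 0.01
  p
}

test_that("edges require p strictly below alpha", {
  p <- matrix(1, 3, 3)
  expect_equal(nrow(net_from_p(p)$edges), 0)
  expect_equal(compute_metrics(net_from_p(p))$edge_density, 0)

  p[1, 2] <- p[2, 1] <- 0.05   # boundary: not an edge
  p[1, 3] <- p[3, 1] <- 0.049  # just below: an edge
  net <- net_from_p(p)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$taxon_a, "t1")
  expect_equal(net$edges$taxon_b, "t3")
  # isolated taxa stay in the node set
  expect_length(net$nodes, 3)
})

test_that("a 70-node network with 382 edges has ~16% edge density", {
  set.seed(1)
  pairs <- which(upper.tri(matrix(0, 70, 70)), arr.ind = TRUE)
  chosen <- pairs[sample(nrow(pairs), 382), ]
  p <- matrix(1, 70, 70)
  p[chosen] <- 0.01
  p[chosen[, c(2, 1)]] <- 0.01
  m <- compute_metrics(net_from_p(p))
  expect_equal(m$n_edges, 382)
  expect_equal(m$edge_density, 382 / 2415)
  expect_equal(round(100 * m$edge_density), 16)
})

test_that("metrics match closed forms on canonical graphs", {
  triangle <- compute_metrics(net_from_p(p_for_edges(3, list(c(1, 2), c(1, 3), c(2, 3)))))
  expect_equal(triangle$n_edges, 3)
  expect_equal(triangle$edge_density, 1)
  expect_equal(triangle$avg_clustering, 1)

  star <- compute_metrics(net_from_p(p_for_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))))
  expect_equal(star$avg_clustering, 0)
  expect_equal(star$edge_density, 0.5)

  complete5 <- compute_metrics(net_from_p(matrix(0.01, 5, 5)))
  expect_equal(complete5$edge_density, 1)
  expect_equal(complete5$avg_clustering, 1)
  expect_error(compute_metrics(net_from_p(matrix(1, 1, 1))), "2 nodes")
})

test_that("average clustering matches a brute-force triangle count", {
  brute_clustering <- function(adj) {
    n <- nrow(adj)
    mean(vapply(seq_len(n), function(v) {
      nb <- which(adj[v, ] > 0)
      k <- length(nb)
      if (k < 2) return(0)
      links <- sum(adj[nb, nb]) / 2
      links / (k * (k - 1) / 2)
    }, numeric(1)))
  }
  for (s in 1:5) {
    set.seed(s)
    n <- 12
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.3)
    adj <- adj + t(adj)
    p <- ifelse(adj > 0, 0.01, 1); diag(p) <- 1
    m <- compute_metrics(net_from_p(p))
    expect_equal(m$avg_clustering, brute_clustering(adj))
    expect_equal(m$n_edges, sum(adj) / 2)
  }
})

test_that("alpha extremes give the empty and complete graphs", {
  set.seed(2)
  p <- matrix(runif(100, 0.1, 0.9), 10, 10)
  p <- (p + t(p)) / 2; diag(p) <- 1
  expect_equal(nrow(net_from_p(p, alpha = 0)$edges), 0)
  expect_equal(nrow(net_from_p(p, alpha = 1)$edges), 45)
})

test_that("clustering is invariant under node relabelling", {
  p <- p_for_edges(6, list(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(5, 6)))
  m1 <- compute_metrics(net_from_p(p))
  perm <- c(4, 6, 1, 3, 2, 5)
  m2 <- compute_metrics(net_from_p(p[perm, perm]))
  expect_equal(m1$avg_clustering, m2$avg_clustering)
  expect_equal(m1$n_edges, m2$n_edges)
})

test_that("representative network minimizes z-scored distance to the mean", {
  tuples <- data.frame(
    replicate = 1:5,
    n_nodes = 10,
    n_edges = c(10, 12, 14, 16, 40),
    edge_density = c(0.22, 0.27, 0.31, 0.36, 0.89),
    avg_clustering = c(0.1, 0.2, 0.3, 0.4, 0.9),
    sparcc_seed = 1:5)
  cmp <- structure(list(replicates = tuples,
                        networks = as.list(1:5)),
                   class = "subsample_comparison")
  # brute-force argmin of the z-scored Euclidean distance
  m <- as.matrix(tuples[, c("n_edges", "edge_density", "avg_clustering")])
  z <- scale(m)
  expected <- which.min(rowSums(z^2))
  chosen <- representative_network(cmp)
  expect_equal(attr(chosen, "replicate"), as.integer(expected))

  # all-identical replicates: tie broken to replicate 1
  tuples2 <- tuples
  tuples2[, c("n_edges", "edge_density", "avg_clustering")] <-
    rep(c(5, 0.1, 0.2), each = 5)
  cmp2 <- structure(list(replicates = tuples2, networks = as.list(1:5)),
                    class = "subsample_comparison")
  expect_equal(attr(representative_network(cmp2), "replicate"), 1L)
})

test_that("subsampling is deterministic and redraws singular replicates", {
  # 5 taxa, 20 samples; taxon E non-zero in only 3 samples, so a draw
  # of 5 samples misses it entirely ~40% of the time and must be
  # redrawn
  set.seed(5)
  counts <- matrix(rpois(20 * 5, 100), 20, 5,
                   dimnames = list(paste0("s", 1:20), LETTERS[1:5]))
  counts[, 5] <- 0
  counts[1:3, 5] <- 50
  params <- fast_sparcc(n_bootstraps = 9, seed = NULL)
  cmp1 <- subsample_networks(counts, n_subsample = 5, n_replicates = 20,
                             sparcc_params = params, seed = 99)
  cmp2 <- subsample_networks(counts, n_subsample = 5, n_replicates = 20,
                             sparcc_params = params, seed = 99)
  expect_identical(cmp1$replicates, cmp2$replicates)
  expect_gt(cmp1$n_discarded, 0)
  expect_equal(nrow(cmp1$replicates), 20)
  expect_equal(cmp1$mean_metrics$n_edges, mean(cmp1$replicates$n_edges))
  expect_error(subsample_networks(counts, n_subsample = 21),
               "exceeds group size")
})

test_that("subsampling the whole group with a fixed sparcc seed degenerates", {
  set.seed(6)
  counts <- matrix(rpois(10 * 5, 100), 10, 5)
  cmp <- subsample_networks(counts, n_subsample = 10, n_replicates = 5,
                            sparcc_params = fast_sparcc(n_bootstraps = 9,
                                                        seed = 123),
                            seed = 1)
  mets <- cmp$replicates[, c("n_edges", "edge_density", "avg_clustering")]
  expect_true(all(vapply(mets, function(x) length(unique(x)) == 1,
                         logical(1))))
})

test_that("planted correlation structure yields more edges than the null", {
  cfg_planted <- null_config(n_taxa = 20)
  R <- block_correlation(20, list(1:4, 5:8, 9:12), 0.8)
  lin <- default_lineages()[1:20]
  cfg_planted <- synthetic_config(
    lineages = lin,
    basis_correlations = list(gain_1m = R, gain_6m = R,
                              loss_1m = R, loss_6m = R),
    fold_changes = setNames(rep(1, 20), names(lin)), seed = 2)
  tab_planted <- planted_counts(cfg_planted, 60, seed = 3)
  tab_null <- planted_counts(null_config(n_taxa = 20), 60, seed = 3)
  params <- fast_sparcc(n_bootstraps = 30, seed = 11)
  n_planted <- compute_metrics(build_network(
    sparcc_correlate(tab_planted, params)))$n_edges
  n_null <- compute_metrics(build_network(
    sparcc_correlate(tab_null, params)))$n_edges
  expect_gt(n_planted, n_null)
})

test_that("timepoint comparison reports percent change per metric", {
  set.seed(8)
  c1 <- matrix(rpois(12 * 6, 150), 12, 6,
               dimnames = list(paste0("a", 1:12), paste0("t", 1:6)))
  c6 <- matrix(rpois(12 * 6, 150), 12, 6,
               dimnames = list(paste0("b", 1:12), paste0("t", 1:6)))
  cmp <- compare_timepoints(c1, c6, n_subsample = 8, n_replicates = 4,
                            sparcc_params = fast_sparcc(n_bootstraps = 9),
                            seed = 3)
  expect_equal(cmp$mode, "subsampled")
  expect_s3_class(cmp$full_sample, "data.frame")
  m <- cmp$metrics
  for (k in seq_len(nrow(m))) {
    if (m$value_1m[k] == 0) {
      expect_true(is.na(m$percent_change[k]))
    } else {
      expect_equal(m$percent_change[k],
                   round(100 * (m$value_6m[k] - m$value_1m[k]) / m$value_1m[k], 2))
    }
  }
  # identical timepoints, direct mode, fixed sparcc seed: 0% change
  cmp2 <- compare_timepoints(c1, c1, n_subsample = 12,
                             sparcc_params = fast_sparcc(n_bootstraps = 9,
                                                         seed = 5),
                             seed = 4)
  expect_equal(cmp2$mode, "direct")
  nonzero <- cmp2$metrics$value_1m != 0
  expect_true(all(cmp2$metrics$percent_change[nonzero] == 0))
  expect_error(compare_timepoints(c1, c6[, c(2:6, 1)]), "same")
})
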