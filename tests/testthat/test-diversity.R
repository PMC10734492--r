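test_that("richness counts taxa with non-zero counts", {
  expect_equal(richness(c(5, 0, 3, 0)), 2)
  expect_equal(richness(rep(0, 4)), 0)
  # 10,000 uniform reads over 70 taxa: all observed almost surely
  set.seed(1)
  x <- as.numeric(rmultinom(1, 10000, rep(1 / 70, 70)))
  expect_equal(richness(x), 70)
})

test_that("Shannon entropy matches closed forms in bits", {
  expect_equal(shannon(rep(25, 4)), 2)
  expect_equal(shannon(c(100, 0, 0)), 0)
  expect_equal(shannon(c(2, 1, 1)), 1.5)
  # natural-log option
  expect_equal(shannon(rep(1, 4), base = exp(1)), log(4))
  # uniform maximizes: log2(richness)
  set.seed(2)
  x <- rmultinom(1, 1000, runif(8))[, 1]
  expect_lte(shannon(x), log2(8))
  expect_error(shannon(c(0, 0)), "reads")
})

test_that("Faith's PD matches a brute-force union of root paths", {
  tree <- ape::read.tree(text = "((A:1,B:2):0.5,(C:3,D:1):0.25):0;")
  total <- sum(tree$edge.length)
  full <- setNames(rep(1, 4), c("A", "B", "C", "D"))
  expect_equal(faiths_pd(full, tree), total)
  expect_equal(faiths_pd(full * 0, tree), 0)

  # brute force: union of edges on each observed tip's root path
  brute_pd <- function(tree, tips) {
    if (length(tips) == 0) return(0)
    root <- ape::Ntip(tree) + 1
    edges <- integer(0)
    for (tip in match(tips, tree$tip.label)) {
      node <- tip
      while (node != root) {
        e <- which(tree$edge[, 2] == node)
        edges <- union(edges, e)
        node <- tree$edge[e, 1]
      }
    }
    sum(tree$edge.length[edges])
  }
  # A and C observed: 1 + 0.5 + 3 + 0.25 = 4.75 by hand
  ac <- setNames(c(1, 0, 5, 0), c("A", "B", "C", "D"))
  expect_equal(faiths_pd(ac, tree), 4.75)
  expect_equal(faiths_pd(ac, tree), brute_pd(tree, c("A", "C")))
  # every subset agrees with the brute force
  for (k in 1:4) {
    tips <- c("A", "B", "C", "D")[1:k]
    obs <- setNames(as.numeric(c("A", "B", "C", "D") %in% tips),
                    c("A", "B", "C", "D"))
    expect_equal(faiths_pd(obs, tree), brute_pd(tree, tips))
  }
  expect_error(faiths_pd(setNames(1, "Z"), tree), "missing from the tree")
})

test_that("Faith's PD is monotone in the observed set", {
  set.seed(3)
  tree <- random_taxon_tree(paste0("t", 1:12), seed = 3)
  obs <- setNames(rep(0, 12), paste0("t", 1:12))
  pd_prev <- 0
  for (tip in sample(paste0("t", 1:12))) {
    obs[tip] <- 1
    pd_now <- faiths_pd(obs, tree)
    expect_gte(pd_now, pd_prev)
    pd_prev <- pd_now
  }
  expect_equal(pd_prev, sum(tree$edge.length))
})

test_that("paired t-test matches the closed form and guards degeneracy", {
  # textbook 5-pair example, hand-computed t
  x1 <- c(200, 174, 198, 170, 182)
  x6 <- c(191, 170, 177, 167, 159)
  d <- x6 - x1
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  res <- paired_ttest(setNames(x1, letters[1:5]), setNames(x6, letters[1:5]))
  expect_equal(res$t, t_hand)
  expect_equal(res$p, p_hand)
  expect_equal(res$df, 4)

  # symmetric differences: t = 0, p = 1
  sym <- paired_ttest(setNames(c(1, 2), c("a", "b")),
                      setNames(c(2, 1), c("a", "b")))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)

  expect_error(paired_ttest(setNames(1:3, c("a", "b", "c")),
                            setNames(2:4, c("a", "b", "c"))),
               "zero variance")
  expect_error(paired_ttest(setNames(1:3, c("a", "b", "c")),
                            setNames(1:2, c("a", "b"))),
               "without both timepoints.*c")
})

test_that("Bray-Curtis matches its definition and bounds", {
  m <- rbind(u = c(6, 2), v = c(2, 2), w = c(6, 2), x = c(0, 4))
  d <- bray_curtis(m)
  expect_equal(d["u", "v"], 1 / 3)
  expect_equal(d["u", "w"], 0)          # identical composition
  expect_equal(unname(d["u", "x"]), (6 + 2) / (6 + 2 + 4), tolerance = 1e-12)
  disjoint <- rbind(a = c(5, 0), b = c(0, 9))
  expect_equal(bray_curtis(disjoint)["a", "b"], 1)  # no shared taxa
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_error(bray_curtis(rbind(c(1, 1), c(0, 0))), "zero-total")
})

test_that("PERMANOVA R2 equals the brute-force SS decomposition", {
  set.seed(4)
  pts <- rbind(matrix(rnorm(6, 0), 3, 2), matrix(rnorm(6, 2), 3, 2))
  d <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 3)
  res <- permanova(d, g, n_permutations = 199, seed = 1)
  # brute-force double loops
  n <- 6
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (lev in c("a", "b")) {
    idx <- which(g == lev)
    sub <- d[idx, idx]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  expect_equal(res$r_squared, (ss_total - ss_within) / ss_total)
  f_brute <- ((ss_total - ss_within) / 1) / (ss_within / 4)
  expect_equal(res$pseudo_f, f_brute)

  # cross-check against the reference implementation
  set.seed(9)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 199)
  expect_equal(res$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_equal(res$pseudo_f, ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA separates clusters and is invariant to scaling", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
               matrix(rnorm(20, 5, 0.1), 10, 2))
  d <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 10)
  res <- permanova(d, g, n_permutations = 199, seed = 2)
  expect_equal(res$p_value, 1 / 200)
  expect_gt(res$r_squared, 0.9)

  res_scaled <- permanova(d * 7, g, n_permutations = 199, seed = 2)
  expect_equal(res_scaled$r_squared, res$r_squared)
  expect_equal(res_scaled$pseudo_f, res$pseudo_f)
  expect_equal(res_scaled$p_value, res$p_value)

  g2 <- ifelse(g == "a", "x", "y")  # relabeled groups
  res_rel <- permanova(d, g2, n_permutations = 199, seed = 2)
  expect_equal(res_rel$r_squared, res$r_squared)

  expect_error(permanova(d, rep("a", 20)), "2 levels")
})

test_that("mean within-group dissimilarity averages unordered pairs", {
  d <- matrix(0, 5, 5)
  d[1, 2] <- d[2, 1] <- 0.2
  d[1, 3] <- d[3, 1] <- 0.4
  d[2, 3] <- d[3, 2] <- 0.6
  d[4, 5] <- d[5, 4] <- 0.9
  g <- c("a", "a", "a", "b", "b")
  res <- mean_within_group_dissimilarity(d, g)
  expect_equal(res[["a"]], 0.4)
  expect_equal(res[["b"]], 0.9)
  # brute-force pair enumeration
  idx <- which(g == "a")
  brute <- mean(c(d[1, 2], d[1, 3], d[2, 3]))
  expect_equal(res[["a"]], brute)
  expect_equal(mean_within_group_dissimilarity(matrix(0, 4, 4),
                                               rep("a", 4))[["a"]], 0)
  expect_error(mean_within_group_dissimilarity(d, c(g[-5], "c")), "fewer than 2")
})
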