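#' Observed richness of a sample
#'
#' @param sample numeric vector of counts for one (rarefied) sample.
#' @return number of taxa with count > 0.
#' @export
richness <- function(sample) {
  sum(sample > 0)
}

#' Shannon entropy of a sample
#'
#' \eqn{-\sum_j p_j \log p_j} over taxa with \eqn{p_j > 0}, where
#' \eqn{p_j} is the taxon's proportion of the sample's reads. Reported
#' in bits (base 2) by default, where a uniform spread over \eqn{2^k}
#' taxa scores exactly \eqn{k}.
#'
#' @param sample numeric vector of counts (total > 0).
#' @param base logarithm base (2 for bits, \code{exp(1)} for nats).
#' @return entropy, in \code{[0, log_base(n_taxa)]}.
#' @export
shannon <- function(sample, base = 2) {
  total <- sum(sample)
  if (total <= 0) stop("Shannon entropy needs a sample with reads")
  p <- sample[sample > 0] / total
  -sum(p * log(p, base = base))
}

#' Faith's phylogenetic diversity of a sample
#'
#' Total branch length of the minimal subtree connecting the sample's
#' observed taxa; under the rooted convention (the default) the subtree
#' is anchored at the tree's root, so a single observed taxon scores
#' its root-to-tip path length.
#'
#' @param sample named numeric vector of counts; names must be tree
#'   tip labels.
#' @param tree rooted \code{ape::phylo} tree with branch lengths.
#' @param include_root anchor the subtree at the root (default TRUE).
#' @return summed branch length; 0 when no taxon is observed.
#' @export
faiths_pd <- function(sample, tree, include_root = TRUE) {
  if (is.null(names(sample)))
    stop("sample must be named by taxon id to match tree tips")
  observed <- names(sample)[sample > 0]
  missing <- setdiff(observed, tree$tip.label)
  if (length(missing))
    stop("observed taxa missing from the tree: ",
         paste(missing, collapse = ", "))
  if (length(observed) == 0) return(0)
  comm <- matrix(as.numeric(sample), nrow = 1,
                 dimnames = list("s", names(sample)))
  # tips absent from the sample vector are treated as unobserved
  extra <- setdiff(tree$tip.label, names(sample))
  if (length(extra)) {
    comm <- cbind(comm, matrix(0, 1, length(extra),
                               dimnames = list("s", extra)))
  }
  comm <- comm[, tree$tip.label, drop = FALSE]
  pd <- picante::pd(comm, tree, include.root = include_root)
  pd$PD[1]
}

#' Per-sample alpha-diversity table
#'
#' @param table a rarefied \code{count_table}.
#' @param tree optional rooted tree for Faith's PD.
#' @param base Shannon logarithm base.
#' @return data.frame with columns \code{sample_id}, \code{richness},
#'   \code{shannon} and (when a tree is given) \code{faith_pd}.
#' @export
alpha_diversity <- function(table, tree = NULL, base = 2) {
  counts <- table$counts
  out <- data.frame(
    sample_id = rownames(counts),
    richness = apply(counts, 1, richness),
    shannon = apply(counts, 1, shannon, base = base),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(tree)) {
    missing <- setdiff(colnames(counts), tree$tip.label)
    if (length(missing))
      stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
    comm <- counts[, tree$tip.label[tree$tip.label %in% colnames(counts)],
                   drop = FALSE]
    pd <- picante::pd(comm, tree, include.root = TRUE)
    out$faith_pd <- pd$PD[match(out$sample_id, rownames(pd))]
  }
  out
}

#' Two-sided paired t-test across timepoints
#'
#' Classical paired t on per-subject differences (6 months minus
#' 1 month), with explicit pairing by subject id.
#'
#' @param values_1m,values_6m numeric vectors named by subject id (or
#'   aligned with \code{subjects}).
#' @param subjects optional subject ids common to both vectors; by
#'   default the names of \code{values_1m}.
#' @return list with \code{t}, \code{p}, \code{df},
#'   \code{mean_difference}, \code{n_pairs}.
#' @export
paired_ttest <- function(values_1m, values_6m, subjects = NULL) {
  if (is.null(subjects)) {
    if (is.null(names(values_1m)) || is.null(names(values_6m)))
      stop("values must be named by subject id (or pass `subjects`)")
    subjects <- names(values_1m)
    unpaired <- c(setdiff(names(values_1m), names(values_6m)),
                  setdiff(names(values_6m), names(values_1m)))
    if (length(unpaired))
      stop("subjects without both timepoints: ",
           paste(unique(unpaired), collapse = ", "))
    values_6m <- values_6m[subjects]
  }
  if (length(values_1m) != length(values_6m))
    stop("paired vectors have different lengths")
  n <- length(subjects)
  if (n < 2) stop("paired t-test needs at least 2 pairs")
  d <- values_6m - values_1m
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences; t statistic is undefined")
  ht <- stats::t.test(values_6m, values_1m, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_difference = mean(d), n_pairs = n)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(u, v) = \sum_j |u_j - v_j| / \sum_j (u_j + v_j)}: 0 for an
#' identical composition, 1 when no taxon is shared.
#'
#' @param abundance_matrix non-negative matrix, samples in rows (counts
#'   or relative abundances).
#' @return symmetric dissimilarity matrix with zero diagonal and
#'   entries in \[0, 1\].
#' @export
bray_curtis <- function(abundance_matrix) {
  if (any(abundance_matrix < 0)) stop("abundances must be non-negative")
  if (any(rowSums(abundance_matrix) == 0))
    stop("zero-total sample(s): ",
         paste(rownames(abundance_matrix)[rowSums(abundance_matrix) == 0],
               collapse = ", "))
  as.matrix(vegan::vegdist(abundance_matrix, method = "bray"))
}

#' Distance-based PERMANOVA
#'
#' One-factor permutational multivariate analysis of variance on a
#' dissimilarity matrix. Sums of squares follow the distance-based
#' decomposition: \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / n},
#' \eqn{SS_{within}} from within-group pairs with each group's own
#' size as denominator, \eqn{SS_{between} = SS_{total} - SS_{within}};
#' pseudo-F is tested against free random relabelings and
#' \eqn{p = (1 + \#\{F^{perm} \ge F^{obs}\}) / (1 + n_{perm})}.
#' A restricted mode permutes timepoint labels within subject instead
#' (for paired designs).
#'
#' @param distance_matrix symmetric dissimilarity matrix.
#' @param grouping factor-like vector, one level per sample (>= 2
#'   levels, each with >= 2 samples).
#' @param n_permutations permutation count (default 999).
#' @param seed optional integer seed.
#' @param strata optional vector (e.g. subject ids); when given, labels
#'   are permuted only within each stratum.
#' @return object of class \code{permanova_result}: list with
#'   \code{r_squared}, \code{p_value}, \code{pseudo_f},
#'   \code{n_permutations}, \code{df_between}, \code{df_within}.
#' @export
permanova <- function(distance_matrix, grouping, n_permutations = 999,
                      seed = NULL, strata = NULL) {
  d <- as.matrix(distance_matrix)
  n <- nrow(d)
  grouping <- as.factor(grouping)
  if (length(grouping) != n)
    stop("grouping length does not match the distance matrix")
  if (nlevels(droplevels(grouping)) < 2 ||
      any(table(grouping) < 2))
    stop("grouping needs >= 2 levels with >= 2 samples each")
  if (!is.null(seed)) set.seed(seed)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  ss_within <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    s
  }
  a <- nlevels(droplevels(grouping))
  df_b <- a - 1
  df_w <- n - a
  f_stat <- function(g) {
    ssw <- ss_within(g)
    ssb <- ss_total - ssw
    (ssb / df_b) / (ssw / df_w)
  }
  f_obs <- f_stat(grouping)
  ssb_obs <- ss_total - ss_within(grouping)

  perm_labels <- function() {
    if (is.null(strata)) return(sample(grouping))
    g <- grouping
    for (s in unique(strata)) {
      idx <- which(strata == s)
      g[idx] <- g[idx][sample(length(idx))]
    }
    g
  }
  exceed <- 0
  for (b in seq_len(n_permutations)) {
    if (f_stat(perm_labels()) >= f_obs) exceed <- exceed + 1
  }
  structure(list(r_squared = ssb_obs / ss_total,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 pseudo_f = f_obs,
                 n_permutations = n_permutations,
                 df_between = df_b, df_within = df_w),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d, %d) = %.3f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_f, x$r_squared,
              x$p_value, x$n_permutations))
  invisible(x)
}

#' Mean within-group dissimilarity
#'
#' Arithmetic mean of the dissimilarity over unordered within-group
#' sample pairs, per group -- the "average beta-diversity" of a group
#' at a timepoint.
#'
#' @param distance_matrix symmetric dissimilarity matrix.
#' @param grouping factor-like vector, one level per sample; every
#'   group needs >= 2 samples.
#' @return named numeric vector of per-group means.
#' @export
mean_within_group_dissimilarity <- function(distance_matrix, grouping) {
  d <- as.matrix(distance_matrix)
  grouping <- as.factor(grouping)
  if (length(grouping) != nrow(d))
    stop("grouping length does not match the distance matrix")
  vapply(levels(grouping), function(lev) {
    idx <- which(grouping == lev)
    if (length(idx) < 2)
      stop("group '", lev, "' has fewer than 2 samples")
    sub <- d[idx, idx]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
}

#' Principal-coordinate ordination of a dissimilarity matrix
#'
#' Classical multidimensional scaling coordinates (for ordination
#' plots of beta diversity).
#'
#' @param distance_matrix symmetric dissimilarity matrix.
#' @param k number of coordinate axes.
#' @return data.frame with \code{sample_id} and \code{PC1..PCk}.
#' @export
principal_coordinates <- function(distance_matrix, k = 2) {
  d <- as.matrix(distance_matrix)
  co <- stats::cmdscale(stats::as.dist(d), k = k)
  out <- data.frame(sample_id = rownames(d), co, row.names = NULL)
  names(out)[-1] <- paste0("PC", seq_len(k))
  out
}
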