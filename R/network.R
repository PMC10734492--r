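#' Build a co-occurrence network from a correlation result
#'
#' Taxa become nodes; an (undirected) edge joins taxa i and j iff the
#' permutation p-value of their SparCC correlation is strictly below
#' \code{alpha}. All taxa are kept as nodes whether or not they gain an
#' edge, so edge density is always relative to the full filtered taxon
#' set.
#'
#' @param correlation_result a \code{correlation_result} (or a list
#'   with matrices \code{r} and \code{p}).
#' @param alpha edge-inclusion threshold on the p-value (strict "<").
#' @return object of class \code{cooccurrence_network}: list with
#'   \code{nodes} (taxon labels), \code{edges} (data.frame taxon_a,
#'   taxon_b, r, p), \code{alpha}.
#' @export
build_network <- function(correlation_result, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha <= 1)
  p <- correlation_result$p
  r <- correlation_result$r
  taxa <- rownames(p)
  if (is.null(taxa)) taxa <- paste0("taxon", seq_len(nrow(p)))
  idx <- which(upper.tri(p) & p < alpha, arr.ind = TRUE)
  edges <- data.frame(taxon_a = taxa[idx[, 1]],
                      taxon_b = taxa[idx[, 2]],
                      r = r[idx],
                      p = p[idx],
                      stringsAsFactors = FALSE)
  structure(list(nodes = taxa, edges = edges, alpha = alpha),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  m <- compute_metrics(x)
  cat("cooccurrence_network: ", m$n_nodes, " nodes, ", m$n_edges,
      " edges (alpha = ", x$alpha, ")\n", sep = "")
  cat("  edge density ", round(m$edge_density, 3),
      ", average clustering ", round(m$avg_clustering, 3), "\n", sep = "")
  invisible(x)
}

as_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = length(network$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = network$nodes)
  if (nrow(network$edges) > 0)
    g <- igraph::add_edges(g, rbind(match(network$edges$taxon_a, network$nodes),
                                    match(network$edges$taxon_b, network$nodes)))
  g
}

#' Summary metrics of a co-occurrence network
#'
#' Edge count, edge density (realized edges over all unordered node
#' pairs), and average clustering coefficient (mean over nodes of the
#' fraction of a node's neighbour pairs that are themselves connected;
#' nodes of degree < 2 contribute 0).
#'
#' @param network a \code{cooccurrence_network}.
#' @return list of class \code{network_metrics} with \code{n_nodes},
#'   \code{n_edges}, \code{edge_density}, \code{avg_clustering}.
#' @export
compute_metrics <- function(network) {
  n_nodes <- length(network$nodes)
  if (n_nodes < 2) stop("network metrics need at least 2 nodes")
  n_edges <- nrow(network$edges)
  density <- 2 * n_edges / (n_nodes * (n_nodes - 1))
  g <- as_igraph(network)
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  structure(list(n_nodes = n_nodes, n_edges = n_edges,
                 edge_density = density,
                 avg_clustering = mean(local_cc)),
            class = "network_metrics")
}

metrics_row <- function(m) {
  data.frame(n_nodes = m$n_nodes, n_edges = m$n_edges,
             edge_density = m$edge_density,
             avg_clustering = m$avg_clustering)
}

# run the sparcc -> network -> metrics chain on one sample subset
network_from_counts <- function(counts, sparcc_params, alpha) {
  res <- sparcc_correlate(counts, sparcc_params)
  build_network(res, alpha)
}

#' Subsample-equalized network comparison
#'
#' Equalizes group sizes for network comparison: draws
#' \code{n_subsample} samples without replacement from the group,
#' \code{n_replicates} times (replicates are independent draws), runs
#' the SparCC / network / metrics chain on each draw, and reports the
#' per-replicate and mean metrics. A replicate whose network cannot be
#' constructed (a \code{singular_basis_error}, e.g. a taxon with no
#' reads across the drawn samples) is discarded and redrawn, up to a
#' retry budget of 10 x \code{n_replicates}; the retained replicate
#' count always equals \code{n_replicates}.
#'
#' @param counts a \code{count_table} (network-filtered absolute
#'   counts) or count matrix containing only the group's samples.
#' @param n_subsample samples drawn per replicate (must not exceed the
#'   group size).
#' @param n_replicates number of subsample networks (250 by default).
#' @param sparcc_params a \code{sparcc_params}; the per-replicate
#'   SparCC seed is re-randomized from the master seed sequence, so
#'   replicate variability includes estimator noise.
#' @param alpha edge-inclusion threshold.
#' @param seed master seed for the subsample draws.
#' @return object of class \code{subsample_comparison}: list with
#'   \code{replicates} (data.frame of per-replicate metrics),
#'   \code{mean_metrics}, \code{networks} (list of
#'   \code{cooccurrence_network}), \code{n_discarded}, \code{seed}.
#' @export
subsample_networks <- function(counts, n_subsample, n_replicates = 250,
                               sparcc_params = sparcc_params(),
                               alpha = 0.05, seed = NULL) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  if (n_subsample > nrow(counts))
    stop("n_subsample (", n_subsample, ") exceeds group size (",
         nrow(counts), ")")
  if (!is.null(seed)) set.seed(seed)
  networks <- vector("list", n_replicates)
  rows <- vector("list", n_replicates)
  n_discarded <- 0
  max_retries <- 10 * n_replicates
  k <- 0
  while (k < n_replicates) {
    draw <- sample(nrow(counts), n_subsample, replace = FALSE)
    # a fixed sparcc seed is honoured (replicates then differ only by
    # their sample draw); otherwise each replicate gets a fresh seed
    # from the master sequence, so estimator noise is part of the
    # replicate variability
    rep_seed <- if (is.null(sparcc_params$seed))
      sample.int(.Machine$integer.max - 1, 1) else sparcc_params$seed
    sp <- sparcc_params
    sp$seed <- rep_seed
    net <- tryCatch(
      network_from_counts(counts[draw, , drop = FALSE], sp, alpha),
      singular_basis_error = function(e) NULL)
    if (is.null(net)) {
      n_discarded <- n_discarded + 1
      if (n_discarded > max_retries)
        stop("subsample retry budget exhausted after ", k,
             " successful replicates (", n_discarded, " discarded)")
      next
    }
    k <- k + 1
    networks[[k]] <- net
    rows[[k]] <- cbind(replicate = k, metrics_row(compute_metrics(net)),
                       sparcc_seed = rep_seed)
  }
  replicates <- do.call(rbind, rows)
  mean_metrics <- list(
    n_nodes = mean(replicates$n_nodes),
    n_edges = mean(replicates$n_edges),
    edge_density = mean(replicates$edge_density),
    avg_clustering = mean(replicates$avg_clustering))
  structure(list(replicates = replicates, mean_metrics = mean_metrics,
                 networks = networks, n_discarded = n_discarded,
                 seed = seed),
            class = "subsample_comparison")
}

#' @export
print.subsample_comparison <- function(x, ...) {
  cat("subsample_comparison: ", nrow(x$replicates), " replicates (",
      x$n_discarded, " discarded)\n", sep = "")
  cat(sprintf("  mean edges %.1f, density %.3f, clustering %.3f\n",
              x$mean_metrics$n_edges, x$mean_metrics$edge_density,
              x$mean_metrics$avg_clustering))
  invisible(x)
}

#' Representative network of a subsample comparison
#'
#' Returns the replicate network whose (n_edges, edge_density,
#' avg_clustering) tuple is closest -- in Euclidean distance after
#' z-scoring each metric across replicates -- to the replicate means.
#' Ties (including the all-identical case, where every z-score is 0)
#' break to the lowest replicate index.
#'
#' @param comparison a \code{subsample_comparison}.
#' @return the selected \code{cooccurrence_network}, with attribute
#'   \code{"replicate"} holding its index.
#' @export
representative_network <- function(comparison) {
  reps <- comparison$replicates
  if (nrow(reps) == 0) stop("no replicates to select from")
  m <- as.matrix(reps[, c("n_edges", "edge_density", "avg_clustering")])
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1  # constant metric carries no distance
  z <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  dist2 <- rowSums(z^2)
  best <- which.min(dist2)  # which.min takes the first minimum: lowest index
  net <- comparison$networks[[best]]
  attr(net, "replicate") <- best
  net
}

percent_change_value <- function(from, to, digits = 2) {
  if (is.na(from) || from == 0) return(NA_real_)
  round(100 * (to - from) / from, digits)
}

#' Compare network metrics between two timepoints
#'
#' Runs the network chain per timepoint for one group and reports each
#' metric at both timepoints with its percent change
#' \eqn{100 (m_{6m} - m_{1m}) / m_{1m}} (two decimals; undefined -- NA
#' -- when the baseline metric is zero). When \code{n_subsample} is
#' below the group size, subsampled replicate means are reported and a
#' full-sample (no subsampling) variant is run alongside for
#' comparison; when it equals the group size a single direct network
#' per timepoint is used.
#'
#' @param counts_1m,counts_6m network-filtered absolute counts for the
#'   group at each timepoint (same taxon set; \code{count_table} or
#'   matrix).
#' @param n_subsample samples per replicate (defaults to the smaller
#'   timepoint's size, i.e. no subsampling).
#' @param n_replicates replicates when subsampling.
#' @param sparcc_params a \code{sparcc_params}.
#' @param alpha edge-inclusion threshold.
#' @param seed master seed.
#' @return object of class \code{timepoint_comparison}: list with
#'   \code{metrics} (data.frame: metric, value_1m, value_6m,
#'   percent_change), \code{mode} ("subsampled" or "direct"),
#'   \code{full_sample} (same-shape data.frame from the unsubsampled
#'   run, when subsampling was used), and the per-timepoint result
#'   objects.
#' @export
compare_timepoints <- function(counts_1m, counts_6m,
                               n_subsample = NULL, n_replicates = 250,
                               sparcc_params = sparcc_params(),
                               alpha = 0.05, seed = NULL) {
  c1 <- if (inherits(counts_1m, "count_table")) counts_1m$counts else counts_1m
  c6 <- if (inherits(counts_6m, "count_table")) counts_6m$counts else counts_6m
  if (!identical(colnames(c1), colnames(c6)))
    stop("both timepoints must share the same (network-filtered) taxon set")
  n_min <- min(nrow(c1), nrow(c6))
  if (is.null(n_subsample)) n_subsample <- n_min
  subsampled <- n_subsample < max(nrow(c1), nrow(c6))
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 4)

  run_tp <- function(counts, seed_pair) {
    if (subsampled && n_subsample < nrow(counts)) {
      cmp <- subsample_networks(counts, n_subsample, n_replicates,
                                sparcc_params, alpha, seed = seed_pair[1])
      list(mode = "subsampled", result = cmp,
           metrics = cmp$mean_metrics)
    } else {
      sp <- sparcc_params
      sp$seed <- seed_pair[1]
      net <- network_from_counts(counts, sp, alpha)
      list(mode = "direct", result = net,
           metrics = compute_metrics(net))
    }
  }

  tp1 <- run_tp(c1, seeds[1:2])
  tp6 <- run_tp(c6, seeds[3:4])

  tab <- function(m1, m6) {
    metric <- c("n_edges", "edge_density", "avg_clustering")
    data.frame(
      metric = metric,
      value_1m = unlist(m1[metric]),
      value_6m = unlist(m6[metric]),
      percent_change = vapply(metric, function(nm)
        percent_change_value(m1[[nm]], m6[[nm]]), numeric(1)),
      row.names = NULL)
  }
  metrics <- tab(tp1$metrics, tp6$metrics)

  full_sample <- NULL
  if (subsampled) {
    sp1 <- sparcc_params; sp1$seed <- seeds[2]
    sp6 <- sparcc_params; sp6$seed <- seeds[4]
    f1 <- compute_metrics(network_from_counts(c1, sp1, alpha))
    f6 <- compute_metrics(network_from_counts(c6, sp6, alpha))
    full_sample <- tab(f1, f6)
  }

  structure(list(metrics = metrics,
                 mode = if (subsampled) "subsampled" else "direct",
                 full_sample = full_sample,
                 timepoint_1m = tp1$result, timepoint_6m = tp6$result),
            class = "timepoint_comparison")
}

#' Write a network as an edge-list TSV
#'
#' @param network a \code{cooccurrence_network}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
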