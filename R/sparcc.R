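#' SparCC estimation parameters
#'
#' Controls for compositionally aware correlation inference. Defaults
#' follow the algorithm's reference description: the correlation matrix
#' is the element-wise median over \code{n_estimation_iterations}
#' Dirichlet resamplings of the counts, strongly correlated pairs are
#' iteratively excluded from the basis-variance system while the
#' largest absolute correlation exceeds \code{exclusion_threshold} (up
#' to \code{max_exclusion_rounds} pairs), and significance comes from
#' \code{n_bootstraps} permutations of each taxon's counts.
#'
#' @param n_estimation_iterations Dirichlet resampling draws.
#' @param exclusion_threshold absolute correlation above which the
#'   most-correlated pair is excluded from basis estimation.
#' @param max_exclusion_rounds maximum excluded pairs per estimate.
#' @param n_bootstraps permutation count for p-values.
#' @param variance_floor smallest admissible basis variance.
#' @param seed optional integer seed.
#' @return list of class \code{sparcc_params}.
#' @export
sparcc_params <- function(n_estimation_iterations = 20,
                          exclusion_threshold = 0.1,
                          max_exclusion_rounds = 10,
                          n_bootstraps = 1000,
                          variance_floor = 1e-8,
                          seed = NULL) {
  stopifnot(n_estimation_iterations >= 1,
            exclusion_threshold > 0, exclusion_threshold < 1,
            max_exclusion_rounds >= 0,
            variance_floor > 0)
  structure(list(n_estimation_iterations = as.integer(n_estimation_iterations),
                 exclusion_threshold = exclusion_threshold,
                 max_exclusion_rounds = as.integer(max_exclusion_rounds),
                 n_bootstraps = as.integer(n_bootstraps),
                 variance_floor = variance_floor,
                 seed = seed),
            class = "sparcc_params")
}

#' Typed condition for a degenerate basis system
#'
#' Raised when the basis-variance linear system cannot be solved (too
#' many exclusions, too few taxa) or a taxon carries no information
#' (all-zero counts across the sample set). The subsampling scheme in
#' \code{\link{subsample_networks}} catches this condition and redraws
#' the replicate.
#'
#' @param message condition message.
#' @param call calling context.
#' @return condition of class \code{singular_basis_error}.
#' @export
singular_basis_error <- function(message, call = sys.call(-1)) {
  structure(class = c("singular_basis_error", "error", "condition"),
            list(message = message, call = call))
}

#' Dirichlet resampling of count compositions
#'
#' Draws, for each sample, one composition from Dirichlet(counts + 1):
#' the posterior of the underlying fractions under a uniform prior.
#' Rows sum to one and are strictly positive, so log-ratios are always
#' defined even for zero counts.
#'
#' @param counts non-negative integer matrix (samples x taxa) or a
#'   \code{count_table}.
#' @param seed optional integer seed.
#' @return matrix of fractions with the dimensions of \code{counts}.
#' @export
draw_fractions <- function(counts, seed = NULL) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
              nrow(counts), ncol(counts), dimnames = dimnames(counts))
  g / rowSums(g)
}

#' Log-ratio variance matrix
#'
#' The SparCC core statistic: \eqn{t_{ij} = Var[\log(x_i / x_j)]} over
#' samples, computed for all taxon pairs from the log-fraction
#' covariance matrix.
#'
#' @param fractions strictly positive matrix (samples x taxa).
#' @return symmetric taxa x taxa matrix with zero diagonal.
#' @export
log_ratio_variances <- function(fractions) {
  if (nrow(fractions) < 2)
    stop("log-ratio variances need at least 2 samples")
  if (any(fractions <= 0)) stop("fractions must be strictly positive")
  L <- log(fractions)
  C <- stats::cov(L)
  v <- diag(C)
  T_mat <- outer(v, v, "+") - 2 * C
  T_mat <- (T_mat + t(T_mat)) / 2
  diag(T_mat) <- 0
  T_mat
}

#' Solve the SparCC basis-variance system
#'
#' Under the sparsity assumption the row sums of the log-ratio variance
#' matrix satisfy a linear system in the basis variances
#' \eqn{\omega_i^2}; pairs flagged in \code{excluded} are dropped from
#' the sums. Correlations follow as
#' \eqn{r_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij}) / (2\omega_i\omega_j)},
#' clamped to \[-1, 1\].
#'
#' @param T_mat log-ratio variance matrix.
#' @param excluded symmetric logical matrix of excluded pairs (or NULL).
#' @param variance_floor smallest admissible basis variance.
#' @return list with \code{variances} (\eqn{\omega^2}) and
#'   \code{correlations}.
#' @export
estimate_basis <- function(T_mat, excluded = NULL, variance_floor = 1e-8) {
  d <- nrow(T_mat)
  if (is.null(excluded)) excluded <- matrix(FALSE, d, d)
  include <- !excluded
  diag(include) <- FALSE
  M <- matrix(0, d, d)
  M[include] <- 1
  diag(M) <- rowSums(include)
  t_vec <- rowSums(T_mat * include)
  w2 <- tryCatch(solve(M, t_vec), error = function(e) {
    stop(singular_basis_error(paste0(
      "basis-variance system is singular (", d, " taxa, ",
      sum(excluded) / 2, " excluded pairs): ", conditionMessage(e))))
  })
  if (any(!is.finite(w2)))
    stop(singular_basis_error("basis-variance solution is not finite"))
  w2 <- pmax(w2, variance_floor)
  omega <- sqrt(w2)
  r <- (outer(w2, w2, "+") - T_mat) / (2 * outer(omega, omega))
  r <- pmin(pmax(r, -1), 1)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- dimnames(T_mat)
  list(variances = w2, correlations = r)
}

# one exclusion-iterated correlation estimate from a T matrix
exclusion_iterated_estimate <- function(T_mat, params) {
  d <- nrow(T_mat)
  excluded <- matrix(FALSE, d, d)
  rounds <- 0
  repeat {
    est <- estimate_basis(T_mat, excluded, params$variance_floor)
    r <- est$correlations
    if (rounds >= params$max_exclusion_rounds) return(r)
    a <- abs(r)
    a[excluded] <- 0
    diag(a) <- 0
    m <- max(a)
    if (m <= params$exclusion_threshold) return(r)
    hit <- which(a == m, arr.ind = TRUE)[1, ]
    excluded[hit[1], hit[2]] <- TRUE
    excluded[hit[2], hit[1]] <- TRUE
    rounds <- rounds + 1
  }
}

#' SparCC correlation estimate
#'
#' Estimates basis correlations from compositional counts: counts are
#' Dirichlet-resampled \code{n_estimation_iterations} times; for each
#' resampling the log-ratio variance matrix is reduced to basis
#' variances with iterative exclusion of the most-correlated pair; the
#' reported matrix is the element-wise median over resamplings.
#'
#' @param counts non-negative integer matrix (samples x taxa) or a
#'   \code{count_table}; at least 4 taxa and 2 samples.
#' @param params a \code{sparcc_params}; \code{params$seed} makes the
#'   estimate reproducible.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sparcc <- function(counts, params = sparcc_params()) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  if (ncol(counts) < 4)
    stop("SparCC needs at least 4 taxa (the basis system is not ",
         "well-posed below that)")
  if (nrow(counts) < 2) stop("SparCC needs at least 2 samples")
  zero_taxa <- colSums(counts) == 0
  if (any(zero_taxa))
    stop(singular_basis_error(paste0(
      "taxa with all-zero counts across the sample set: ",
      paste(colnames(counts)[zero_taxa], collapse = ", "))))
  if (!is.null(params$seed)) set.seed(params$seed)
  d <- ncol(counts)
  draws <- array(NA_real_, c(d, d, params$n_estimation_iterations))
  for (k in seq_len(params$n_estimation_iterations)) {
    fr <- draw_fractions(counts)
    T_mat <- log_ratio_variances(fr)
    draws[, , k] <- exclusion_iterated_estimate(T_mat, params)
  }
  r <- apply(draws, c(1, 2), stats::median)
  r <- pmin(pmax((r + t(r)) / 2, -1), 1)
  diag(r) <- 1
  dimnames(r) <- list(colnames(counts), colnames(counts))
  r
}

#' Permutation p-values for SparCC correlations
#'
#' Each bootstrap replicate permutes every taxon's counts across
#' samples independently (destroying co-occurrence while preserving
#' marginal count distributions), re-estimates the correlation matrix,
#' and the two-sided p-value for pair (i, j) is
#' \eqn{(1 + \#\{|r^{boot}_{ij}| \ge |r^{obs}_{ij}|\}) / (1 + B)}.
#' A replicate raising \code{singular_basis_error} is redrawn, with a
#' bounded retry budget.
#'
#' @param counts the counts \code{r_observed} was estimated from.
#' @param r_observed correlation matrix from \code{\link{sparcc}}.
#' @param params a \code{sparcc_params} (\code{n_bootstraps} >= 1).
#' @return symmetric matrix of p-values in \[1/(B+1), 1\], diagonal 1.
#' @export
bootstrap_pvalues <- function(counts, r_observed, params = sparcc_params()) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  if (params$n_bootstraps < 1)
    stop("n_bootstraps must be at least 1")
  if (!is.null(params$seed)) set.seed(params$seed)
  d <- ncol(counts)
  exceed <- matrix(0, d, d)
  obs <- abs(r_observed)
  b <- 0
  retries <- 0
  max_retries <- 10 * params$n_bootstraps
  while (b < params$n_bootstraps) {
    perm <- apply(counts, 2, sample)
    r_b <- tryCatch(
      sparcc(perm, sparcc_params(
        n_estimation_iterations = params$n_estimation_iterations,
        exclusion_threshold = params$exclusion_threshold,
        max_exclusion_rounds = params$max_exclusion_rounds,
        n_bootstraps = params$n_bootstraps,
        variance_floor = params$variance_floor,
        seed = NULL)),
      singular_basis_error = function(e) NULL)
    if (is.null(r_b)) {
      retries <- retries + 1
      if (retries > max_retries)
        stop("bootstrap retry budget exhausted after ", b,
             " successful replicates")
      next
    }
    exceed <- exceed + (abs(r_b) >= obs)
    b <- b + 1
  }
  p <- (1 + exceed) / (1 + params$n_bootstraps)
  p <- (p + t(p)) / 2
  diag(p) <- 1
  dimnames(p) <- dimnames(r_observed)
  p
}

#' SparCC correlations with permutation p-values
#'
#' Convenience wrapper running \code{\link{sparcc}} and
#' \code{\link{bootstrap_pvalues}} on the same counts.
#'
#' @param counts count matrix or \code{count_table}.
#' @param params a \code{sparcc_params}.
#' @return object of class \code{correlation_result}: list with
#'   \code{r}, \code{p}, \code{taxa}, \code{params}.
#' @export
sparcc_correlate <- function(counts, params = sparcc_params()) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  r <- sparcc(counts, params)
  p <- bootstrap_pvalues(counts, r, params)
  structure(list(r = r, p = p, taxa = colnames(counts), params = params),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("SparCC correlation_result: ", length(x$taxa), " taxa, ",
      x$params$n_bootstraps, " bootstraps\n", sep = "")
  off <- x$r[upper.tri(x$r)]
  cat("  |r| range: ", signif(min(abs(off)), 3), " - ",
      signif(max(abs(off)), 3), "; pairs with p < 0.05: ",
      sum(x$p[upper.tri(x$p)] < 0.05), "\n", sep = "")
  invisible(x)
}

#' Write a square labelled matrix as TSV
#'
#' @param m square matrix with dimnames.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_square_tsv <- function(m, path) {
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
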