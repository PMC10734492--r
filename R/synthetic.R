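#' Default genus-level taxonomy for synthetic studies
#'
#' Seventy genus-level taxa spanning eight bacterial phyla commonly
#' observed in the adult human gut, written as 7-rank GREENGENES-style
#' lineage strings. Taxa whose genus is unresolved carry an empty
#' \code{g__} rank under a named family, so taxonomic aggregation and
#' "Family X - unknown genus" labelling are exercised by default.
#'
#' @return named character vector of 70 lineage strings; names are the
#'   taxon ids used throughout the synthetic study.
#' @export
default_lineages <- function() {
  lin <- function(p, c, o, f, g) {
    sprintf("k__Bacteria; p__%s; c__%s; o__%s; f__%s; g__%s; s__", p, c, o, f, g)
  }
  out <- c(
    # Actinobacteria
    Bifidobacterium = lin("Actinobacteria", "Actinobacteria", "Bifidobacteriales", "Bifidobacteriaceae", "Bifidobacterium"),
    Collinsella = lin("Actinobacteria", "Coriobacteriia", "Coriobacteriales", "Coriobacteriaceae", "Collinsella"),
    Adlercreutzia = lin("Actinobacteria", "Coriobacteriia", "Coriobacteriales", "Coriobacteriaceae", "Adlercreutzia"),
    Eggerthella = lin("Actinobacteria", "Coriobacteriia", "Coriobacteriales", "Coriobacteriaceae", "Eggerthella"),
    Actinomyces = lin("Actinobacteria", "Actinobacteria", "Actinomycetales", "Actinomycetaceae", "Actinomyces"),
    Coriobacteriaceae_unknown = lin("Actinobacteria", "Coriobacteriia", "Coriobacteriales", "Coriobacteriaceae", ""),
    # Bacteroidetes
    Bacteroides = lin("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Bacteroidaceae", "Bacteroides"),
    Prevotella = lin("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae", "Prevotella"),
    Parabacteroides = lin("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Porphyromonadaceae", "Parabacteroides"),
    Alistipes = lin("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Rikenellaceae", "Alistipes"),
    Odoribacter = lin("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Odoribacteraceae", "Odoribacter"),
    Butyricimonas = lin("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Odoribacteraceae", "Butyricimonas"),
    Paraprevotella = lin("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae", "Paraprevotella"),
    Barnesiella = lin("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Barnesiellaceae", "Barnesiella"),
    Porphyromonas = lin("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Porphyromonadaceae", "Porphyromonas"),
    Rikenellaceae_unknown = lin("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Rikenellaceae", ""),
    S24_7_unknown = lin("Bacteroidetes", "Bacteroidia", "Bacteroidales", "S24-7", ""),
    Paludibacter = lin("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Porphyromonadaceae", "Paludibacter"),
    # Firmicutes
    Lactobacillus = lin("Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae", "Lactobacillus"),
    Streptococcus = lin("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae", "Streptococcus"),
    Lactococcus = lin("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae", "Lactococcus"),
    Enterococcus = lin("Firmicutes", "Bacilli", "Lactobacillales", "Enterococcaceae", "Enterococcus"),
    Gemella = lin("Firmicutes", "Bacilli", "Gemellales", "Gemellaceae", "Gemella"),
    Turicibacter = lin("Firmicutes", "Bacilli", "Turicibacterales", "Turicibacteraceae", "Turicibacter"),
    Veillonella = lin("Firmicutes", "Clostridia", "Clostridiales", "Veillonellaceae", "Veillonella"),
    Dialister = lin("Firmicutes", "Clostridia", "Clostridiales", "Veillonellaceae", "Dialister"),
    Megasphaera = lin("Firmicutes", "Clostridia", "Clostridiales", "Veillonellaceae", "Megasphaera"),
    Phascolarctobacterium = lin("Firmicutes", "Clostridia", "Clostridiales", "Veillonellaceae", "Phascolarctobacterium"),
    Acidaminococcus = lin("Firmicutes", "Clostridia", "Clostridiales", "Acidaminococcaceae", "Acidaminococcus"),
    Faecalibacterium = lin("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae", "Faecalibacterium"),
    Oscillospira = lin("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae", "Oscillospira"),
    Ruminococcus = lin("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae", "Ruminococcus"),
    Anaerotruncus = lin("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae", "Anaerotruncus"),
    Ruminococcaceae_unknown = lin("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae", ""),
    Blautia = lin("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Blautia"),
    Coprococcus = lin("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Coprococcus"),
    Dorea = lin("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Dorea"),
    Lachnospira = lin("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Lachnospira"),
    Roseburia = lin("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Roseburia"),
    Anaerostipes = lin("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Anaerostipes"),
    Lachnospiraceae_unknown = lin("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", ""),
    Clostridium = lin("Firmicutes", "Clostridia", "Clostridiales", "Clostridiaceae", "Clostridium"),
    SMB53 = lin("Firmicutes", "Clostridia", "Clostridiales", "Clostridiaceae", "SMB53"),
    Eubacterium = lin("Firmicutes", "Clostridia", "Clostridiales", "Eubacteriaceae", "Eubacterium"),
    Christensenellaceae_unknown = lin("Firmicutes", "Clostridia", "Clostridiales", "Christensenellaceae", ""),
    Mogibacteriaceae_unknown = lin("Firmicutes", "Clostridia", "Clostridiales", "Mogibacteriaceae", ""),
    Peptococcaceae_unknown = lin("Firmicutes", "Clostridia", "Clostridiales", "Peptococcaceae", ""),
    Catenibacterium = lin("Firmicutes", "Erysipelotrichi", "Erysipelotrichales", "Erysipelotrichaceae", "Catenibacterium"),
    Holdemania = lin("Firmicutes", "Erysipelotrichi", "Erysipelotrichales", "Erysipelotrichaceae", "Holdemania"),
    Coprobacillus = lin("Firmicutes", "Erysipelotrichi", "Erysipelotrichales", "Erysipelotrichaceae", "Coprobacillus"),
    Bulleidia = lin("Firmicutes", "Erysipelotrichi", "Erysipelotrichales", "Erysipelotrichaceae", "Bulleidia"),
    Erysipelotrichaceae_unknown = lin("Firmicutes", "Erysipelotrichi", "Erysipelotrichales", "Erysipelotrichaceae", ""),
    # Proteobacteria
    Haemophilus = lin("Proteobacteria", "Gammaproteobacteria", "Pasteurellales", "Pasteurellaceae", "Haemophilus"),
    Pasteurellaceae_unknown = lin("Proteobacteria", "Gammaproteobacteria", "Pasteurellales", "Pasteurellaceae", ""),
    Escherichia = lin("Proteobacteria", "Gammaproteobacteria", "Enterobacteriales", "Enterobacteriaceae", "Escherichia"),
    Klebsiella = lin("Proteobacteria", "Gammaproteobacteria", "Enterobacteriales", "Enterobacteriaceae", "Klebsiella"),
    Citrobacter = lin("Proteobacteria", "Gammaproteobacteria", "Enterobacteriales", "Enterobacteriaceae", "Citrobacter"),
    Succinivibrio = lin("Proteobacteria", "Gammaproteobacteria", "Aeromonadales", "Succinivibrionaceae", "Succinivibrio"),
    Sutterella = lin("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Alcaligenaceae", "Sutterella"),
    Oxalobacter = lin("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Oxalobacteraceae", "Oxalobacter"),
    Campylobacter = lin("Proteobacteria", "Epsilonproteobacteria", "Campylobacterales", "Campylobacteraceae", "Campylobacter"),
    # Verrucomicrobia
    Akkermansia = lin("Verrucomicrobia", "Verrucomicrobiae", "Verrucomicrobiales", "Verrucomicrobiaceae", "Akkermansia"),
    Cerasicoccaceae_unknown = lin("Verrucomicrobia", "Opitutae", "Cerasicoccales", "Cerasicoccaceae", ""),
    Prosthecobacter = lin("Verrucomicrobia", "Verrucomicrobiae", "Verrucomicrobiales", "Verrucomicrobiaceae", "Prosthecobacter"),
    # Lentisphaerae
    Victivallaceae_unknown = lin("Lentisphaerae", "Lentisphaeria", "Victivallales", "Victivallaceae", ""),
    Victivallis = lin("Lentisphaerae", "Lentisphaeria", "Victivallales", "Victivallaceae", "Victivallis"),
    # Thermodesulfobacteriota
    Desulfovibrio = lin("Thermodesulfobacteriota", "Desulfovibrionia", "Desulfovibrionales", "Desulfovibrionaceae", "Desulfovibrio"),
    Bilophila = lin("Thermodesulfobacteriota", "Desulfovibrionia", "Desulfovibrionales", "Desulfovibrionaceae", "Bilophila"),
    # Fusobacteria
    Fusobacterium = lin("Fusobacteria", "Fusobacteriia", "Fusobacteriales", "Fusobacteriaceae", "Fusobacterium"),
    Leptotrichia = lin("Fusobacteria", "Fusobacteriia", "Fusobacteriales", "Leptotrichiaceae", "Leptotrichia")
  )
  stopifnot(length(out) == 70)
  out
}

#' Default planted fold changes
#'
#' Multiplicative per-taxon effects applied to the gain group's 6-month
#' basis abundances. Magnitudes follow the percent changes reported for
#' weight-gain-associated taxa in the motivating cohort (e.g. +85\% for
#' the Pasteurellaceae family group, -50\% for Akkermansia); all other
#' taxa get a multiplier of 1.
#'
#' @param taxon_ids taxon ids the vector should cover.
#' @return named numeric vector of strictly positive multipliers.
#' @export
default_fold_changes <- function(taxon_ids = names(default_lineages())) {
  fc <- stats::setNames(rep(1, length(taxon_ids)), taxon_ids)
  planted <- c(
    Coriobacteriaceae_unknown = 0.81,   # -19%
    Mogibacteriaceae_unknown = 0.76,    # -24%
    Rikenellaceae_unknown = 0.80,       # -20%
    Prevotella = 1.09,
    Christensenellaceae_unknown = 0.75, # -25%
    Peptococcaceae_unknown = 0.63,      # -37%
    Faecalibacterium = 1.08,
    Oscillospira = 0.92,                # -8%
    Streptococcus = 1.65,
    Veillonella = 1.51,
    Victivallaceae_unknown = 0.64,      # -36%
    Pasteurellaceae_unknown = 1.85,
    Haemophilus = 1.84,
    Desulfovibrio = 0.75,               # -25%
    Cerasicoccaceae_unknown = 0.53,     # -47%
    Akkermansia = 0.50
  )
  hit <- intersect(names(planted), taxon_ids)
  fc[hit] <- planted[hit]
  fc
}

#' Build a block-structured correlation target
#'
#' @param n_taxa matrix dimension.
#' @param blocks list of integer index vectors; within each block every
#'   pair gets correlation \code{rho}.
#' @param rho within-block correlation (scalar or one value per block).
#' @return \code{n_taxa x n_taxa} correlation matrix.
#' @export
block_correlation <- function(n_taxa, blocks, rho) {
  R <- diag(n_taxa)
  rho <- rep_len(rho, length(blocks))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    R[idx, idx] <- rho[b]
    diag(R)[idx] <- 1
  }
  R
}

#' Default per-cell correlation targets
#'
#' One target matrix per (weight group, timepoint) cell. The gain group
#' starts with more correlated blocks at 1 month than remain at 6 months
#' (a planted loss of co-occurrence structure); the loss group keeps the
#' same blocks at both timepoints but with stronger within-block
#' correlation at 6 months (a planted gain in clustering).
#'
#' @param n_taxa number of taxa (>= 40 for the default block layout).
#' @return named list with elements \code{gain_1m}, \code{gain_6m},
#'   \code{loss_1m}, \code{loss_6m}.
#' @export
default_basis_correlations <- function(n_taxa = 70) {
  stopifnot(n_taxa >= 40)
  block5 <- function(k) lapply(seq_len(k), function(b) ((b - 1) * 5 + 1):(b * 5))
  list(
    gain_1m = block_correlation(n_taxa, block5(8), 0.65),
    gain_6m = block_correlation(n_taxa, block5(3), 0.65),
    loss_1m = block_correlation(n_taxa, block5(5), 0.45),
    loss_6m = block_correlation(n_taxa, block5(5), 0.70)
  )
}

#' Repair a nearly positive semi-definite correlation matrix
#'
#' Clips negative eigenvalues to a small floor and rescales to unit
#' diagonal. Hand-written block targets are often slightly indefinite;
#' this restores a valid correlation matrix with a warning.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param tol eigenvalues below \code{-tol} trigger repair.
#' @return positive semi-definite correlation matrix.
#' @export
nearest_psd <- function(R, tol = 1e-8) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) >= -tol) return((R + t(R)) / 2)
  warning("correlation target is not positive semi-definite (min eigenvalue ",
          signif(min(e$values), 3), "); clipping eigenvalues")
  vals <- pmax(e$values, tol)
  R2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  (R2 + t(R2)) / 2
}

check_correlation_target <- function(R, name, n_taxa) {
  if (!is.matrix(R) || nrow(R) != n_taxa || ncol(R) != n_taxa)
    stop("basis_correlations[['", name, "']] must be a ", n_taxa, " x ",
         n_taxa, " matrix")
  if (max(abs(R - t(R))) > 1e-8)
    stop("basis_correlations[['", name, "']] is not symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop("basis_correlations[['", name, "']] does not have a unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6)
    stop("basis_correlations[['", name, "']] is not positive semi-definite ",
         "(min eigenvalue ", signif(min(ev), 3), "); repair it with nearest_psd()")
  R
}

#' Configuration for a synthetic paired two-timepoint study
#'
#' Defaults emulate the motivating cohort: 65 weight-gain and 40
#' weight-loss subjects sampled at 1 and 6 months postpartum, 70
#' genus-level taxa in 8 phyla, library sizes following a truncated
#' log-normal targeting the printed range \[12, 64069\] and median
#' ~30,785 reads, planted correlation blocks that differ by group and
#' timepoint, and planted fold changes of the reported magnitudes
#' applied at 6 months in the gain group.
#'
#' @param n_gain,n_loss subjects per weight-change group.
#' @param lineages named character vector of lineage strings (taxon ids
#'   taken from its names); defines \code{n_taxa}.
#' @param library_size_law list with \code{meanlog}, \code{sdlog},
#'   \code{min}, \code{max} for the truncated log-normal read-depth law.
#' @param basis_correlations named list of correlation targets, one per
#'   \code{group_timepoint} cell (\code{gain_1m}, \code{gain_6m},
#'   \code{loss_1m}, \code{loss_6m}).
#' @param fold_changes strictly positive named multipliers applied to
#'   the gain group's 6-month basis abundances.
#' @param log_sd marginal standard deviation of log basis abundances.
#' @param subject_effect proportion of log-abundance variance shared
#'   between a subject's two timepoints (within-subject correlation).
#' @param evenness_decay factor (> 1 flattens nothing, widens the
#'   spread of mean log abundances) applied to the gain group's 6-month
#'   mean profile; values above 1 increase dominance and so lower
#'   Shannon entropy at 6 months.
#' @param dropout probability that a (sample, taxon) basis abundance is
#'   suppressed to near zero before closure (zero-inflation knob).
#' @param seed integer master seed.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_gain = 65, n_loss = 40,
                             lineages = default_lineages(),
                             library_size_law = list(meanlog = log(30785),
                                                     sdlog = 0.65,
                                                     min = 12, max = 64069),
                             basis_correlations =
                               default_basis_correlations(length(lineages)),
                             fold_changes = default_fold_changes(names(lineages)),
                             log_sd = 1,
                             subject_effect = 0.4,
                             evenness_decay = 1.35,
                             dropout = 0,
                             seed = 1L) {
  n_taxa <- length(lineages)
  if (is.null(names(lineages))) stop("lineages must be named by taxon id")
  stopifnot(n_gain >= 1, n_loss >= 1, n_taxa >= 2,
            log_sd > 0, subject_effect >= 0, subject_effect < 1,
            dropout >= 0, dropout < 1)
  cells <- c("gain_1m", "gain_6m", "loss_1m", "loss_6m")
  miss <- setdiff(cells, names(basis_correlations))
  if (length(miss))
    stop("basis_correlations is missing cells: ", paste(miss, collapse = ", "))
  for (nm in cells)
    check_correlation_target(basis_correlations[[nm]], nm, n_taxa)
  if (length(fold_changes) != n_taxa) {
    if (is.null(names(fold_changes)))
      stop("fold_changes must be named or cover all taxa")
    fc <- stats::setNames(rep(1, n_taxa), names(lineages))
    fc[names(fold_changes)] <- fold_changes
    fold_changes <- fc
  } else if (is.null(names(fold_changes))) {
    names(fold_changes) <- names(lineages)
  }
  if (any(fold_changes <= 0)) stop("fold_changes must be strictly positive")
  structure(list(
    n_gain = as.integer(n_gain), n_loss = as.integer(n_loss),
    n_taxa = n_taxa, lineages = lineages,
    library_size_law = library_size_law,
    basis_correlations = basis_correlations[cells],
    fold_changes = fold_changes[names(lineages)],
    log_sd = log_sd, subject_effect = subject_effect,
    evenness_decay = evenness_decay, dropout = dropout,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Baseline mean log abundances: a fixed geometric rank-abundance profile
# interleaved across the taxon list (stride permutation) so phyla mix.
# Planted fold-change taxa are floored at a detectable abundance so the
# planted effects are recoverable at realistic sequencing depth.
baseline_log_means <- function(config) {
  n <- config$n_taxa
  ranks <- (seq_len(n) * 29L) %% n  # fixed stride permutation, 0 = most abundant
  mu <- 3.1 - 6.2 * ranks / max(ranks, 1)
  names(mu) <- names(config$lineages)
  planted <- names(config$fold_changes)[config$fold_changes != 1]
  mu[planted] <- pmax(mu[planted], -1.2)
  mu
}

cell_log_means <- function(config, group, timepoint) {
  mu <- baseline_log_means(config)
  if (group == "gain" && timepoint == "6m") {
    fc <- config$fold_changes
    plain <- fc == 1
    s2 <- config$log_sd^2 / 2
    mu2 <- mu
    # widen the spread of the unplanted taxa (more dominance, lower
    # Shannon entropy), then rescale them so their expected basis mass
    # is unchanged: planted fold changes then carry through closure as
    # matching relative-abundance changes
    mu2[plain] <- mean(mu[plain]) +
      config$evenness_decay * (mu[plain] - mean(mu[plain]))
    mu2[plain] <- mu2[plain] +
      log(sum(exp(mu[plain] + s2)) / sum(exp(mu2[plain] + s2)))
    mu <- mu2 + log(fc)
  }
  mu
}

#' Generate latent (basis) abundances for one study cell
#'
#' Draws strictly positive abundances from a multivariate log-normal
#' whose log-scale correlation matrix is the configured target for the
#' requested (group, timepoint) cell and whose marginal log standard
#' deviation is \code{config$log_sd}. The gain group's 6-month cell has
#' the configured fold changes and evenness decay folded into its mean
#' profile.
#'
#' @param config a \code{synthetic_config}.
#' @param group \code{"gain"} or \code{"loss"}.
#' @param timepoint \code{"1m"} or \code{"6m"}.
#' @param n_samples number of rows to draw.
#' @param subject_z optional \code{n_samples x n_taxa} matrix of
#'   standard-normal subject scores shared across a subject's
#'   timepoints; mixed in with weight \code{sqrt(subject_effect)}.
#' @return \code{n_samples x n_taxa} positive matrix.
#' @export
generate_basis <- function(config, group, timepoint, n_samples,
                           subject_z = NULL) {
  group <- match.arg(group, c("gain", "loss"))
  timepoint <- match.arg(timepoint, c("1m", "6m"))
  cell <- paste(group, timepoint, sep = "_")
  R <- config$basis_correlations[[cell]]
  if (is.null(R)) stop("no basis correlation target for cell ", cell)
  check_correlation_target(R, cell, config$n_taxa)
  d <- config$n_taxa
  if (n_samples == 0)
    return(matrix(numeric(0), nrow = 0, ncol = d,
                  dimnames = list(NULL, names(config$lineages))))
  # chol of a PSD (possibly rank-deficient) target via eigen factor
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), d)
  z <- matrix(stats::rnorm(n_samples * d), n_samples, d)
  if (!is.null(subject_z)) {
    stopifnot(nrow(subject_z) == n_samples, ncol(subject_z) == d)
    w <- config$subject_effect
    z <- sqrt(w) * subject_z + sqrt(1 - w) * z
  }
  logx <- z %*% t(L) * config$log_sd
  mu <- cell_log_means(config, group, timepoint)
  logx <- sweep(logx, 2, mu, "+")
  x <- exp(logx)
  if (config$dropout > 0) {
    drop_mask <- matrix(stats::runif(n_samples * d) < config$dropout,
                        n_samples, d)
    x[drop_mask] <- x[drop_mask] * 1e-8
  }
  colnames(x) <- names(config$lineages)
  x
}

#' Multinomial read sampling under closure
#'
#' Converts latent abundances to sequencing counts: each sample's reads
#' are drawn multinomially with probabilities proportional to its basis
#' abundances, so row i sums exactly to \code{library_sizes[i]}.
#'
#' @param basis_matrix \code{n_samples x n_taxa} non-negative matrix.
#' @param library_sizes one non-negative integer per sample.
#' @param seed optional integer seed.
#' @return \code{count_table} with the basis matrix's column names.
#' @export
sample_counts <- function(basis_matrix, library_sizes, seed = NULL) {
  if (any(basis_matrix < 0)) stop("basis abundances must be non-negative")
  if (length(library_sizes) != nrow(basis_matrix))
    stop("need one library size per sample")
  if (any(library_sizes < 0) || any(library_sizes != round(library_sizes)))
    stop("library sizes must be non-negative integers")
  if (!is.null(seed)) set.seed(seed)
  counts <- t(vapply(seq_len(nrow(basis_matrix)), function(i) {
    p <- basis_matrix[i, ]
    if (sum(p) <= 0) stop("sample ", i, " has zero total basis abundance")
    as.numeric(stats::rmultinom(1, size = library_sizes[i], prob = p))
  }, numeric(ncol(basis_matrix))))
  if (nrow(basis_matrix) == 1) counts <- matrix(counts, nrow = 1)
  colnames(counts) <- colnames(basis_matrix)
  rownames(counts) <- rownames(basis_matrix)
  count_table(counts)
}

#' Draw library sizes from the configured truncated log-normal
#'
#' @param n number of samples.
#' @param law list with \code{meanlog}, \code{sdlog}, \code{min}, \code{max}.
#' @return integer vector of read depths within \code{[law$min, law$max]}.
#' @export
generate_library_sizes <- function(n, law) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * (n - length(out)) + 10, law$meanlog, law$sdlog)
    out <- c(out, x[x >= law$min & x <= law$max])
  }
  as.integer(round(out[seq_len(n)]))
}

#' Random rooted taxon tree
#'
#' Random bifurcating topology with exponential branch lengths; one leaf
#' per taxon. Faith's phylogenetic diversity only requires a valid
#' rooted tree with positive branch lengths, which this provides.
#'
#' @param taxon_ids tip labels.
#' @param seed optional integer seed.
#' @return rooted \code{ape::phylo} object.
#' @export
random_taxon_tree <- function(taxon_ids, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(length(taxon_ids), rooted = TRUE,
                     br = function(k) stats::rexp(k, rate = 10))
  tree$tip.label <- sample(taxon_ids)  # decouple topology from list order
  tree
}

#' Generate a complete synthetic paired study
#'
#' Produces counts, metadata, a rooted taxon tree, and the planted
#' ground truth for one simulated cohort: every subject is sampled at
#' both timepoints, gain-group 6-month samples carry the configured
#' fold changes and evenness decay, and library sizes follow the
#' truncated log-normal law. Identical seeds give bit-identical output.
#'
#' @param config a \code{synthetic_config}.
#' @return list with elements \code{counts} (a \code{count_table}),
#'   \code{metadata} (data.frame: sample_id, subject_id, timepoint,
#'   weight_group, weight_kg, prepregnancy_weight_kg), \code{tree}
#'   (rooted \code{phylo}), and \code{truth} (planted correlations,
#'   fold changes, and per-group effective-taxa diversity shift).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  groups <- c(rep("gain", config$n_gain), rep("loss", config$n_loss))
  subjects <- sprintf("subj%03d", seq_along(groups))
  d <- config$n_taxa

  md <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    data.frame(sample_id = paste0(subjects[i], c("_1m", "_6m")),
               subject_id = subjects[i],
               timepoint = c("1m", "6m"),
               weight_group = groups[i],
               stringsAsFactors = FALSE)
  }))

  # anthropometrics: planted weight trajectories matching the cohort's
  # group means (gain +4.11 kg, loss -3.36 kg on average)
  w1 <- ifelse(groups == "gain",
               stats::rnorm(length(groups), 74.57, 13.40),
               stats::rnorm(length(groups), 71.50, 12.33))
  w1 <- pmax(w1, 45)
  delta <- ifelse(groups == "gain",
                  pmax(stats::rnorm(length(groups), 4.11, 2.5), 0.1),
                  -pmax(stats::rnorm(length(groups), 3.36, 2.0), 0.1))
  w6 <- w1 + delta
  prepreg <- w6 + stats::rnorm(length(groups), 0, 7.5)
  md$weight_kg <- as.numeric(rbind(w1, w6))
  md$prepregnancy_weight_kg <- rep(prepreg, each = 2)

  lib <- generate_library_sizes(nrow(md), config$library_size_law)

  counts <- matrix(0, nrow(md), d,
                   dimnames = list(md$sample_id, names(config$lineages)))
  for (grp in c("gain", "loss")) {
    in_grp <- groups == grp
    n_grp <- sum(in_grp)
    subject_z <- matrix(stats::rnorm(n_grp * d), n_grp, d)
    for (tp in c("1m", "6m")) {
      idx <- which(md$weight_group == grp & md$timepoint == tp)
      basis <- generate_basis(config, grp, tp, n_grp, subject_z = subject_z)
      rownames(basis) <- md$sample_id[idx]
      tab <- sample_counts(basis, lib[idx])
      counts[idx, ] <- tab$counts
    }
  }

  tree <- random_taxon_tree(names(config$lineages))

  eff <- function(mu) {
    p <- exp(mu + config$log_sd^2 / 2)
    p <- p / sum(p)
    exp(-sum(p * log(p)))
  }
  truth <- list(
    true_correlations = config$basis_correlations,
    true_fold_changes = config$fold_changes,
    true_diversity_shift = c(
      gain = eff(cell_log_means(config, "gain", "6m")) -
             eff(cell_log_means(config, "gain", "1m")),
      loss = eff(cell_log_means(config, "loss", "6m")) -
             eff(cell_log_means(config, "loss", "1m"))
    )
  )

  list(counts = count_table(counts, config$lineages),
       metadata = md, tree = tree, truth = truth)
}
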