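# Small fixtures built in code; all randomness is explicitly seeded.

# toy count table: 4 samples x 3 taxa with lineages exercising
# aggregation and unknown-genus labelling
toy_table <- function() {
  counts <- rbind(S1 = c(3, 4, 10),
                  S2 = c(0, 2, 5),
                  S3 = c(1, 0, 7),
                  S4 = c(6, 1, 0))
  colnames(counts) <- c("A", "B", "C")
  lineages <- c(
    A = "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__Rikenellaceae; g__Alistipes; s__",
    B = "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__Rikenellaceae; g__; s__",
    C = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Ruminococcaceae; g__Faecalibacterium; s__")
  count_table(counts, lineages)
}

# fully null synthetic config: identity correlations everywhere, all
# fold changes 1, no evenness decay -- no planted effect of any kind
null_config <- function(n_taxa = 70, seed = 1, ...) {
  lin <- default_lineages()[seq_len(n_taxa)]
  R <- diag(n_taxa)
  synthetic_config(
    lineages = lin,
    basis_correlations = list(gain_1m = R, gain_6m = R,
                              loss_1m = R, loss_6m = R),
    fold_changes = stats::setNames(rep(1, n_taxa), names(lin)),
    evenness_decay = 1,
    seed = seed, ...)
}

# config with one planted correlated pair (among abundant taxa so the
# correlation survives sequencing noise)
planted_pair_config <- function(rho = 0.8, n_taxa = 70, seed = 1) {
  idx <- abundant_taxa(n_taxa)[2:3]
  lin <- default_lineages()[seq_len(n_taxa)]
  R <- diag(n_taxa)
  R[idx[1], idx[2]] <- R[idx[2], idx[1]] <- rho
  cfg <- synthetic_config(
    lineages = lin,
    basis_correlations = list(gain_1m = R, gain_6m = R,
                              loss_1m = R, loss_6m = R),
    fold_changes = stats::setNames(rep(1, n_taxa), names(lin)),
    seed = seed)
  attr(cfg, "pair") <- idx
  cfg
}

# indices of the most abundant taxa under the generator's fixed
# stride-permutation rank-abundance profile
abundant_taxa <- function(n_taxa = 70) {
  order((seq_len(n_taxa) * 29) %% n_taxa)
}

# counts with planted structure for direct sparcc tests
planted_counts <- function(cfg, n_samples, seed = 1) {
  set.seed(seed)
  basis <- generate_basis(cfg, "gain", "1m", n_samples)
  libs <- generate_library_sizes(n_samples, cfg$library_size_law)
  sample_counts(basis, libs)
}

# reduced-cost params for toy-scale fixtures; the exclusion threshold
# is relaxed because with < ~15 taxa and few samples the compositional
# null correlation (~ -1/(D-1)) plus sampling noise sits above the
# default 0.1, and aggressive exclusion makes the basis system
# singular by design
fast_sparcc <- function(n_bootstraps = 50, seed = 1, ...) {
  sparcc_params(n_estimation_iterations = 5, exclusion_threshold = 0.3,
                max_exclusion_rounds = 3, n_bootstraps = n_bootstraps,
                seed = seed, ...)
}

# hand-built correlation_result from a p matrix (r defaults to 0)
fake_correlation_result <- function(p, r = NULL) {
  if (is.null(r)) { r <- p * 0; diag(r) <- 1 }
  structure(list(r = r, p = p, taxa = rownames(p),
                 params = sparcc_params()),
            class = "correlation_result")
}
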