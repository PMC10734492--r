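#' Filtering and transform parameters
#'
#' Thresholds used by the abundance/diversity filtering branch and the
#' network filtering branch. Defaults follow the motivating study: taxa
#' with total count <= 420 are removed (420 = an average of two reads
#' per sample over 210 samples), taxa seen in fewer than 10\% of samples
#' are removed, and the diversity branch rarefies to 10,000 reads.
#'
#' @param min_total_count taxa with total count less than or equal to
#'   this are removed.
#' @param min_prevalence_fraction minimum fraction of samples in which a
#'   taxon must be non-zero (strictly-below removes; exactly at the
#'   threshold retains).
#' @param min_mean_reads_per_sample network-branch threshold on mean
#'   reads per sample.
#' @param rarefaction_depth target read depth for rarefaction.
#' @return list of class \code{filter_params}.
#' @export
filter_params <- function(min_total_count = 420,
                          min_prevalence_fraction = 0.10,
                          min_mean_reads_per_sample = 2,
                          rarefaction_depth = 10000) {
  stopifnot(min_total_count >= 0, min_mean_reads_per_sample >= 0,
            min_prevalence_fraction >= 0, min_prevalence_fraction <= 1,
            rarefaction_depth > 0)
  structure(list(min_total_count = min_total_count,
                 min_prevalence_fraction = min_prevalence_fraction,
                 min_mean_reads_per_sample = min_mean_reads_per_sample,
                 rarefaction_depth = rarefaction_depth),
            class = "filter_params")
}

#' Abundance-branch taxon filtering
#'
#' Removes taxa whose total count over all samples is less than or equal
#' to \code{min_total_count}, then taxa observed (non-zero) in fewer
#' than \code{ceiling(min_prevalence_fraction * n_samples)} samples.
#' The sample set and retained counts are unchanged.
#'
#' @param table a \code{count_table}.
#' @param params a \code{filter_params}.
#' @return filtered \code{count_table}.
#' @export
filter_taxa <- function(table, params = filter_params()) {
  counts <- table$counts
  keep <- colSums(counts) > params$min_total_count
  min_prev <- ceiling(params$min_prevalence_fraction * nrow(counts))
  keep <- keep & (colSums(counts > 0) >= min_prev)
  if (!any(keep))
    stop("filtering removed every taxon (", ncol(counts), " taxa, ",
         nrow(counts), " samples); thresholds are too strict for this table")
  subset_table(table, taxa = which(keep))
}

#' Network-branch taxon filtering
#'
#' Retains taxa with total count >= 420 and a mean of at least two reads
#' per sample, keeping absolute counts (no rarefaction or transform):
#' this branch feeds SparCC directly. Over 210 samples the two criteria
#' coincide at a total of 420 reads.
#'
#' @param table a \code{count_table}.
#' @param min_total_count,min_mean_reads_per_sample thresholds.
#' @return filtered \code{count_table}.
#' @export
filter_for_network <- function(table, min_total_count = 420,
                               min_mean_reads_per_sample = 2) {
  counts <- table$counts
  keep <- colSums(counts) >= min_total_count &
    colMeans(counts) >= min_mean_reads_per_sample
  if (!any(keep))
    stop("network filtering removed every taxon")
  subset_table(table, taxa = which(keep))
}

#' Rarefy samples to a common read depth
#'
#' Subsamples each sample's reads without replacement down to
#' \code{depth}; samples with fewer reads than \code{depth} are dropped
#' (their ids are reported in the \code{"dropped_samples"} attribute and
#' via a message). A sample with exactly \code{depth} reads is retained
#' unchanged.
#'
#' @param table a \code{count_table}.
#' @param depth target reads per sample.
#' @param seed optional integer seed.
#' @return rarefied \code{count_table}; every row sums to \code{depth}.
#' @export
rarefy <- function(table, depth = 10000, seed = NULL) {
  stopifnot(depth > 0)
  if (!is.null(seed)) set.seed(seed)
  counts <- table$counts
  totals <- rowSums(counts)
  drop <- totals < depth
  if (all(drop))
    stop("every sample has fewer than ", depth, " reads; cannot rarefy")
  if (any(drop))
    message("rarefy: dropping ", sum(drop), " sample(s) below depth ",
            depth, ": ", paste(rownames(counts)[drop], collapse = ", "))
  counts <- counts[!drop, , drop = FALSE]
  totals <- totals[!drop]
  out <- counts
  for (i in seq_len(nrow(counts))) {
    if (totals[i] == depth) next
    # draw `depth` reads without replacement from the sample's read pool
    reads <- rep.int(seq_len(ncol(counts)), counts[i, ])
    picked <- sample(reads, depth, replace = FALSE)
    out[i, ] <- tabulate(picked, nbins = ncol(counts))
  }
  res <- count_table(out, table$lineages)
  attr(res, "dropped_samples") <- rownames(table$counts)[drop]
  res
}

#' Aggregate counts to a taxonomic level
#'
#' Sums counts over all features sharing the lineage prefix down to
#' \code{level}. Features with an unnamed rank at \code{level} under a
#' named parent rank are grouped as \code{"Family X - unknown <level>"}
#' (so e.g. unknown-genus members of Rikenellaceae aggregate to
#' \code{"Family Rikenellaceae - unknown genus"}). Per-sample totals are
#' conserved.
#'
#' @param table a \code{count_table} with lineage strings.
#' @param level \code{"phylum"}, \code{"class"}, \code{"order"},
#'   \code{"family"} or \code{"genus"}.
#' @return aggregated \code{count_table}; lineages hold the truncated
#'   lineage prefix of each group.
#' @export
aggregate_taxa <- function(table, level) {
  level <- match.arg(level, c("phylum", "class", "order", "family", "genus"))
  lineages <- table$lineages
  if (any(is.na(lineages)))
    stop("count table has no lineages; cannot aggregate")
  ranks <- names(rank_prefixes)
  level_i <- match(level, ranks)
  name_at <- lineage_rank(lineages, level)
  labels <- name_at
  prefix <- character(length(lineages))
  for (j in seq_along(lineages)) {
    parts <- trimws(strsplit(lineages[[j]], ";")[[1]])
    prefix[j] <- paste(parts[seq_len(min(level_i, length(parts)))],
                       collapse = "; ")
    if (labels[j] == "") {
      # fall back to the nearest named ancestor rank
      anc <- rev(ranks[seq_len(level_i - 1)])
      for (a in anc) {
        nm <- lineage_rank(lineages[j], a)
        if (nzchar(nm)) {
          labels[j] <- sprintf("%s %s - unknown %s",
                               tools::toTitleCase(a), nm, level)
          break
        }
      }
      if (labels[j] == "") labels[j] <- paste("unclassified", level)
    }
  }
  groups <- split(seq_along(lineages), labels)
  counts <- vapply(groups, function(idx)
    rowSums(table$counts[, idx, drop = FALSE]),
    numeric(nrow(table$counts)))
  if (nrow(table$counts) == 1)
    counts <- matrix(counts, nrow = 1,
                     dimnames = list(rownames(table$counts), names(groups)))
  new_lineages <- vapply(groups, function(idx) prefix[idx[1]], character(1))
  count_table(counts, new_lineages)
}

#' Parameters of the log relative-abundance transform
#'
#' @param average_sequences_per_sample scaling constant; if \code{NULL}
#'   (default) it is recomputed as the mean library size of the table
#'   being transformed.
#' @param pseudocount added inside the log (default 1, so zero counts
#'   map to exactly 0).
#' @return list of class \code{transform_params}.
#' @export
transform_params <- function(average_sequences_per_sample = NULL,
                             pseudocount = 1) {
  if (!is.null(average_sequences_per_sample))
    stopifnot(average_sequences_per_sample > 0)
  structure(list(average_sequences_per_sample = average_sequences_per_sample,
                 pseudocount = pseudocount),
            class = "transform_params")
}

#' Log-transformed relative abundance
#'
#' Computes, per sample i and taxon j,
#' \deqn{\log_{10}\left(\frac{c_{ij}}{N_i} \bar{N} + 1\right)}
#' where \eqn{N_i} is the sample's total reads and \eqn{\bar{N}} the
#' average number of sequences per sample. Zero counts map to exactly 0
#' and the transform is strictly monotone in the count for a fixed
#' sample total.
#'
#' @param table a \code{count_table}.
#' @param params a \code{transform_params}.
#' @return numeric matrix (samples x taxa) of non-negative values.
#' @export
log_relative_abundance <- function(table, params = transform_params()) {
  counts <- table$counts
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero total reads: ",
         paste(rownames(counts)[totals == 0], collapse = ", "))
  avg <- params$average_sequences_per_sample
  if (is.null(avg)) avg <- mean(totals)
  log10(counts / totals * avg + params$pseudocount)
}

#' Relative abundances (per-sample proportions)
#'
#' @param table a \code{count_table}.
#' @return numeric matrix (samples x taxa); rows sum to 1.
#' @export
relative_abundance <- function(table) {
  totals <- rowSums(table$counts)
  if (any(totals == 0))
    stop("sample(s) with zero total reads: ",
         paste(rownames(table$counts)[totals == 0], collapse = ", "))
  table$counts / totals
}
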