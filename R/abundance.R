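#' Percent change between two group means
#'
#' \eqn{100 (m_{6m} - m_{1m}) / m_{1m}}, the change in group-mean
#' relative abundance from 1 to 6 months.
#'
#' @param mean_1m,mean_6m group-mean values (baseline must be > 0 for a
#'   defined change).
#' @param digits rounding for reporting (default 2; use 0 for the
#'   integer convention of published abundance tables, NULL for no
#'   rounding).
#' @return percent change; \code{NA} when the baseline is zero.
#' @export
percent_change <- function(mean_1m, mean_6m, digits = 2) {
  if (is.na(mean_1m) || mean_1m == 0) return(NA_real_)
  pc <- 100 * (mean_6m - mean_1m) / mean_1m
  if (is.null(digits)) pc else round(pc, digits)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} (m \, p_{(j)} / j)}, capped at 1 and
#' mapped back to the input order.
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return adjusted q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-taxon paired abundance-change tests
#'
#' For each taxon at one taxonomic level within one weight group:
#' a two-sided paired t-test on the per-subject change (6 months minus
#' 1 month) of log-transformed relative abundance, Benjamini-Hochberg
#' correction across the taxa tested, and the percent change of the
#' group-mean raw relative abundance. The test runs on the log scale
#' (to satisfy its distributional assumptions) while the reported
#' percent change stays on the linear relative-abundance scale.
#'
#' Rows are sorted by phylum alphabetically, family-level "unknown
#' genus" groups before named genera within a phylum, and
#' alphabetically within those.
#'
#' @param table a filtered \code{count_table}, aggregated to the level
#'   under test.
#' @param metadata data.frame with \code{sample_id}, \code{subject_id},
#'   \code{timepoint} (\code{"1m"}/\code{"6m"}) and
#'   \code{weight_group}.
#' @param group weight group to test (\code{"gain"} or \code{"loss"});
#'   NULL tests all samples as one group.
#' @param transform a \code{transform_params} for the log transform.
#' @param alpha significance threshold on the adjusted q-value.
#' @param percent_change_mode \code{"ratio_of_means"} (percent change
#'   of the group-mean relative abundance; default) or
#'   \code{"mean_of_ratios"} (mean per-subject percent change).
#' @return data.frame of class \code{taxon_test_result} with columns
#'   \code{taxon}, \code{phylum}, \code{percent_change}, \code{p_raw},
#'   \code{q_bh}, \code{significant}.
#' @export
test_taxa <- function(table, metadata, group = NULL,
                      transform = transform_params(), alpha = 0.05,
                      percent_change_mode = c("ratio_of_means",
                                              "mean_of_ratios")) {
  percent_change_mode <- match.arg(percent_change_mode)
  md <- metadata
  if (!is.null(group)) md <- md[md$weight_group == group, , drop = FALSE]
  md <- md[md$sample_id %in% rownames(table$counts), , drop = FALSE]
  complete <- intersect(md$subject_id[md$timepoint == "1m"],
                        md$subject_id[md$timepoint == "6m"])
  if (length(complete) < 2)
    stop("fewer than 2 subjects with both timepoints")
  incomplete <- setdiff(unique(md$subject_id), complete)
  if (length(incomplete))
    message("test_taxa: dropping ", length(incomplete),
            " subject(s) without both timepoints")
  md <- md[md$subject_id %in% complete, , drop = FALSE]
  sub <- subset_table(table, samples = md$sample_id)

  logm <- log_relative_abundance(sub, transform)
  rel <- relative_abundance(sub)
  id1 <- md$sample_id[md$timepoint == "1m"][order(md$subject_id[md$timepoint == "1m"])]
  id6 <- md$sample_id[md$timepoint == "6m"][order(md$subject_id[md$timepoint == "6m"])]

  taxa <- colnames(sub$counts)
  phylum <- lineage_rank(sub$lineages, "phylum")
  res <- lapply(seq_along(taxa), function(j) {
    l1 <- logm[id1, j]; l6 <- logm[id6, j]
    p <- if (stats::sd(l6 - l1) == 0) NA_real_ else
      stats::t.test(l6, l1, paired = TRUE)$p.value
    m1 <- mean(rel[id1, j]); m6 <- mean(rel[id6, j])
    pc <- if (percent_change_mode == "ratio_of_means") {
      percent_change(m1, m6)
    } else {
      r1 <- rel[id1, j]
      if (any(r1 == 0)) NA_real_ else
        round(mean(100 * (rel[id6, j] - r1) / r1), 2)
    }
    data.frame(taxon = taxa[j], phylum = phylum[j],
               mean_relabund_1m = m1, mean_relabund_6m = m6,
               percent_change = pc, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  testable <- !is.na(out$p_raw)
  out$q_bh <- NA_real_
  out$q_bh[testable] <- bh_adjust(out$p_raw[testable])
  out$significant <- !is.na(out$q_bh) & out$q_bh < alpha

  unknown <- grepl("unknown", out$taxon)
  ord <- order(out$phylum, !unknown, out$taxon)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("taxon_test_result", class(out))
  out
}

#' Stratify subjects by return to pre-pregnancy weight
#'
#' Flags each subject as having returned to within
#' \code{threshold_kg} of pre-pregnancy weight by 6 months (inclusive
#' boundary: a difference of exactly the threshold counts as within).
#' Subjects with missing weights are excluded with a warning.
#'
#' @param metadata data.frame with \code{subject_id},
#'   \code{timepoint}, \code{weight_kg},
#'   \code{prepregnancy_weight_kg}.
#' @param threshold_kg the window half-width (default 5 kg).
#' @return data.frame with \code{subject_id},
#'   \code{weight_difference_kg} (6-month minus pre-pregnancy) and
#'   logical \code{within_threshold}.
#' @export
stratify_by_weight_return <- function(metadata, threshold_kg = 5) {
  md6 <- metadata[metadata$timepoint == "6m", , drop = FALSE]
  ok <- !is.na(md6$weight_kg) & !is.na(md6$prepregnancy_weight_kg)
  if (any(!ok))
    warning(sum(!ok), " subject(s) excluded for missing weights")
  md6 <- md6[ok, , drop = FALSE]
  diff_kg <- md6$weight_kg - md6$prepregnancy_weight_kg
  data.frame(subject_id = md6$subject_id,
             weight_difference_kg = diff_kg,
             within_threshold = abs(diff_kg) <= threshold_kg,
             stringsAsFactors = FALSE)
}
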