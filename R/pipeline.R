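#' Pipeline configuration
#'
#' Bundles every stage's settings. Exactly one data source must be
#' given: a \code{synthetic_config}, or \code{input} paths to a count
#' table TSV, metadata TSV and newick tree. The \code{"fast"} preset
#' (default) uses reduced bootstrap/replicate counts suitable for
#' interactive use and testing; \code{"full"} uses the study-scale
#' 250 subsample replicates, 1000 bootstraps and 999 permutations.
#'
#' @param synthetic a \code{synthetic_config}, or NULL when reading
#'   from files.
#' @param input NULL, or list with paths \code{counts},
#'   \code{metadata}, \code{tree}.
#' @param preset \code{"fast"} or \code{"full"}.
#' @param filter a \code{filter_params}.
#' @param sparcc a \code{sparcc_params} (built from the preset when
#'   NULL).
#' @param network list: \code{alpha}, \code{n_subsample},
#'   \code{n_replicates} (replicates default from the preset;
#'   \code{n_subsample} defaults to the smaller group's size at run
#'   time).
#' @param diversity list: \code{rarefaction_depth},
#'   \code{n_permutations}, \code{shannon_base}.
#' @param abundance list: \code{levels} (taxonomic levels to test),
#'   \code{alpha}.
#' @param seed master seed for every stage.
#' @param output_dir optional directory for the report bundle.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input = NULL,
                            preset = c("fast", "full"),
                            filter = filter_params(),
                            sparcc = NULL,
                            network = list(alpha = 0.05,
                                           n_subsample = NULL,
                                           n_replicates = NULL),
                            diversity = list(rarefaction_depth = 10000,
                                             n_permutations = NULL,
                                             shannon_base = 2),
                            abundance = list(levels = c("phylum", "genus"),
                                             alpha = 0.05),
                            seed = 1L,
                            output_dir = NULL) {
  preset <- match.arg(preset)
  if (is.null(synthetic) == is.null(input))
    stop("exactly one of `synthetic` and `input` must be given")
  if (!is.null(input)) {
    miss <- setdiff(c("counts", "metadata", "tree"), names(input))
    if (length(miss))
      stop("input paths missing: ", paste(miss, collapse = ", "))
  }
  fast <- preset == "fast"
  if (is.null(sparcc))
    sparcc <- sparcc_params(n_estimation_iterations = if (fast) 10 else 20,
                            n_bootstraps = if (fast) 100 else 1000)
  if (is.null(network$n_replicates))
    network$n_replicates <- if (fast) 25 else 250
  if (is.null(network$alpha)) network$alpha <- 0.05
  if (is.null(diversity$n_permutations))
    diversity$n_permutations <- if (fast) 199 else 999
  if (is.null(diversity$shannon_base)) diversity$shannon_base <- 2
  if (is.null(diversity$rarefaction_depth)) diversity$rarefaction_depth <- 10000
  structure(list(synthetic = synthetic, input = input, preset = preset,
                 filter = filter, sparcc = sparcc, network = network,
                 diversity = diversity, abundance = abundance,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full paired-cohort analysis
#'
#' Orchestrates simulate-or-ingest, preprocessing, per-group network
#' comparison (subsample-equalized for the larger group, plus the
#' full-sample variant), alpha diversity with paired tests, Bray-Curtis
#' beta diversity with PERMANOVA and within-timepoint means, per-level
#' abundance-change tests, the weight-return stratified sensitivity
#' re-analysis, a cohort descriptives table, and a run manifest.
#' Deterministic under a fixed master seed.
#'
#' @param config a \code{pipeline_config}.
#' @return list of class \code{pipeline_result} with elements
#'   \code{data}, \code{network}, \code{diversity}, \code{abundance},
#'   \code{cohort}, \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1, 8)

  data <- stage("data", {
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      syn$seed <- seeds[1]
      generate_study(syn)
    } else {
      list(counts = read_count_table(config$input$counts),
           metadata = read_sample_metadata(config$input$metadata),
           tree = ape::read.tree(config$input$tree),
           truth = NULL)
    }
  })
  md <- data$metadata

  pre <- stage("preprocess", {
    filtered <- filter_taxa(data$counts, config$filter)
    network_table <- filter_for_network(
      data$counts, config$filter$min_total_count,
      config$filter$min_mean_reads_per_sample)
    rarefied <- rarefy(filtered, config$diversity$rarefaction_depth,
                       seed = seeds[2])
    list(filtered = filtered, network_table = network_table,
         rarefied = rarefied)
  })

  net <- stage("network", {
    groups <- sort(unique(md$weight_group))
    group_sizes <- vapply(groups, function(g)
      length(unique(md$subject_id[md$weight_group == g])), integer(1))
    n_sub <- config$network$n_subsample
    if (is.null(n_sub)) n_sub <- min(group_sizes)
    out <- list()
    for (g in groups) {
      ids1 <- md$sample_id[md$weight_group == g & md$timepoint == "1m"]
      ids6 <- md$sample_id[md$weight_group == g & md$timepoint == "6m"]
      out[[g]] <- compare_timepoints(
        subset_table(pre$network_table, samples = ids1),
        subset_table(pre$network_table, samples = ids6),
        n_subsample = n_sub,
        n_replicates = config$network$n_replicates,
        sparcc_params = config$sparcc,
        alpha = config$network$alpha,
        seed = seeds[3] + match(g, groups))
    }
    out
  })

  div <- stage("diversity", {
    alpha_tab <- alpha_diversity(pre$rarefied, data$tree,
                                 base = config$diversity$shannon_base)
    alpha_tab <- merge(alpha_tab, md, by = "sample_id")
    rel <- relative_abundance(pre$rarefied)

    paired_tests <- list()
    beta <- list()
    for (g in sort(unique(md$weight_group))) {
      gt <- alpha_tab[alpha_tab$weight_group == g, , drop = FALSE]
      complete <- intersect(gt$subject_id[gt$timepoint == "1m"],
                            gt$subject_id[gt$timepoint == "6m"])
      gt <- gt[gt$subject_id %in% complete, , drop = FALSE]
      tests <- lapply(c("richness", "shannon", "faith_pd"), function(v) {
        if (!v %in% names(gt)) return(NULL)
        v1 <- stats::setNames(gt[[v]][gt$timepoint == "1m"],
                              gt$subject_id[gt$timepoint == "1m"])
        v6 <- stats::setNames(gt[[v]][gt$timepoint == "6m"],
                              gt$subject_id[gt$timepoint == "6m"])
        c(list(metric = v, group = g,
               mean_1m = mean(v1), mean_6m = mean(v6[names(v1)])),
          paired_ttest(v1, v6))
      })
      paired_tests[[g]] <- do.call(rbind, lapply(tests, function(x)
        as.data.frame(x[c("metric", "group", "mean_1m", "mean_6m",
                          "t", "p", "n_pairs")])))

      ids <- alpha_tab$sample_id[alpha_tab$weight_group == g]
      ids <- ids[ids %in% rownames(rel)]
      dmat <- bray_curtis(rel[ids, , drop = FALSE])
      tp <- md$timepoint[match(ids, md$sample_id)]
      beta[[g]] <- list(
        permanova = permanova(dmat, tp,
                              config$diversity$n_permutations,
                              seed = seeds[4] +
                                match(g, sort(unique(md$weight_group)))),
        mean_within_timepoint = mean_within_group_dissimilarity(dmat, tp))
    }
    list(alpha = alpha_tab,
         alpha_tests = do.call(rbind, paired_tests),
         beta = beta)
  })

  ab <- stage("abundance", {
    out <- list()
    for (level in config$abundance$levels) {
      agg <- aggregate_taxa(pre$filtered, level)
      for (g in sort(unique(md$weight_group))) {
        out[[paste(level, g, sep = "_")]] <-
          test_taxa(agg, md, group = g,
                    alpha = config$abundance$alpha)
      }
    }
    out
  })

  sens <- stage("sensitivity", {
    if (!"prepregnancy_weight_kg" %in% names(md)) return(NULL)
    strat <- stratify_by_weight_return(md)
    loss_subj <- unique(md$subject_id[md$weight_group == "loss"])
    strat <- strat[strat$subject_id %in% loss_subj, , drop = FALSE]
    per_stratum <- lapply(c(within = TRUE, outside = FALSE), function(w) {
      subj <- strat$subject_id[strat$within_threshold == w]
      gt <- div$alpha[div$alpha$subject_id %in% subj, , drop = FALSE]
      complete <- intersect(gt$subject_id[gt$timepoint == "1m"],
                            gt$subject_id[gt$timepoint == "6m"])
      if (length(complete) < 3) return(NULL)
      gt <- gt[gt$subject_id %in% complete, , drop = FALSE]
      v1 <- stats::setNames(gt$shannon[gt$timepoint == "1m"],
                            gt$subject_id[gt$timepoint == "1m"])
      v6 <- stats::setNames(gt$shannon[gt$timepoint == "6m"],
                            gt$subject_id[gt$timepoint == "6m"])
      c(list(n_subjects = length(complete)), paired_ttest(v1, v6))
    })
    list(stratification = strat, shannon_tests = per_stratum)
  })

  cohort <- stage("cohort", describe_cohort(md))

  manifest <- list(
    package_version = as.character(utils::packageVersion("micronet")),
    r_version = R.version.string,
    master_seed = config$seed,
    stage_seeds = seeds,
    preset = config$preset,
    n_samples = nrow(md),
    n_taxa_input = n_taxa(data$counts),
    n_taxa_filtered = n_taxa(pre$filtered),
    n_taxa_network = n_taxa(pre$network_table),
    rarefaction_depth = config$diversity$rarefaction_depth,
    samples_dropped_by_rarefaction =
      length(attr(pre$rarefied, "dropped_samples") %||% character(0)),
    sparcc = config$sparcc[c("n_estimation_iterations",
                             "exclusion_threshold",
                             "max_exclusion_rounds", "n_bootstraps")],
    network = config$network,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  result <- structure(list(data = data, preprocess = pre, network = net,
                           diversity = div, abundance = ab,
                           sensitivity = sens, cohort = cohort,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$output_dir))
    write_report_bundle(result, config$output_dir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline result as a report bundle
#'
#' TSV tables for networks, diversity and abundance plus a JSON
#' manifest. If writing fails partway, a \code{FAILED} marker file is
#' left in the directory alongside whatever was written.
#'
#' @param result a \code{pipeline_result}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) writeLines("pipeline write failed",
                              file.path(dir, "FAILED")))
  for (g in names(result$network)) {
    utils::write.table(result$network[[g]]$metrics,
                       file.path(dir, paste0("network_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(result$diversity$alpha,
                     file.path(dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$diversity$alpha_tests,
                     file.path(dir, "alpha_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(result$abundance)) {
    utils::write.table(result$abundance[[nm]],
                       file.path(dir, paste0("abundance_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(result$cohort$table,
                     file.path(dir, "cohort_descriptives.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ok <- TRUE
  invisible(dir)
}

#' Cohort descriptives with significance letters
#'
#' Means and standard deviations per weight group and timepoint for
#' continuous metadata variables, with paired two-sided t-tests within
#' group across timepoints and unpaired two-sided t-tests between
#' groups at each timepoint. Cells that differ significantly
#' (p < 0.05) in a compared pair never share a letter; letters are
#' assigned greedily in cell order (gain 1m, gain 6m, loss 1m,
#' loss 6m), and a variable with no significant comparison gets no
#' letters. Between-group comparisons use unpaired tests because the
#' groups contain disjoint subjects.
#'
#' @param metadata per-sample metadata with \code{subject_id},
#'   \code{timepoint}, \code{weight_group} and numeric variables.
#' @param variables names of numeric columns to describe (default: all
#'   numeric columns except identifiers).
#' @return list of class \code{cohort_table} with \code{table}
#'   (data.frame: variable, cell, mean, sd, letter) and \code{tests}
#'   (data.frame of the pairwise comparisons).
#' @export
describe_cohort <- function(metadata, variables = NULL) {
  md <- metadata
  if (is.null(variables)) {
    num <- vapply(md, is.numeric, logical(1))
    variables <- setdiff(names(md)[num], c("sample_id", "subject_id"))
  }
  cells <- list(gain_1m = c("gain", "1m"), gain_6m = c("gain", "6m"),
                loss_1m = c("loss", "1m"), loss_6m = c("loss", "6m"))
  cells <- Filter(function(cl) any(md$weight_group == cl[1] &
                                     md$timepoint == cl[2]), cells)
  # the four comparisons made: within each group across timepoints
  # (paired), and between groups at each timepoint (unpaired)
  comparisons <- list(c("gain_1m", "gain_6m"), c("loss_1m", "loss_6m"),
                      c("gain_1m", "loss_1m"), c("gain_6m", "loss_6m"))
  comparisons <- Filter(function(cp) all(cp %in% names(cells)), comparisons)

  rows <- list(); tests <- list()
  for (v in variables) {
    vals <- lapply(cells, function(cl) {
      sel <- md$weight_group == cl[1] & md$timepoint == cl[2]
      stats::setNames(md[[v]][sel], md$subject_id[sel])
    })
    sig <- matrix(FALSE, length(cells), length(cells),
                  dimnames = list(names(cells), names(cells)))
    for (cp in comparisons) {
      a <- vals[[cp[1]]]; b <- vals[[cp[2]]]
      paired <- strsplit(cp[1], "_")[[1]][1] == strsplit(cp[2], "_")[[1]][1]
      p <- tryCatch({
        if (paired) {
          common <- intersect(names(a), names(b))
          if (stats::sd(a[common] - b[common]) == 0) NA_real_
          else stats::t.test(a[common], b[common], paired = TRUE)$p.value
        } else {
          if (stats::sd(c(a, b)) == 0) NA_real_
          else stats::t.test(a, b)$p.value
        }
      }, error = function(e) NA_real_)
      tests[[length(tests) + 1]] <- data.frame(
        variable = v, cell_a = cp[1], cell_b = cp[2],
        paired = paired, p = p, stringsAsFactors = FALSE)
      if (!is.na(p) && p < 0.05) sig[cp[1], cp[2]] <- sig[cp[2], cp[1]] <- TRUE
    }
    letters_out <- stats::setNames(rep("", length(cells)), names(cells))
    if (any(sig)) {
      for (i in seq_along(cells)) {
        used <- letters_out[sig[i, ]]
        letters_out[i] <- LETTERS[which.min(LETTERS[1:8] %in% used)]
      }
    }
    for (nm in names(cells)) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, cell = nm,
        mean = mean(vals[[nm]]), sd = stats::sd(vals[[nm]]),
        letter = letters_out[[nm]], stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows),
                 tests = do.call(rbind, tests)),
            class = "cohort_table")
}
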