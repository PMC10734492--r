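#' Construct a feature count table
#'
#' The universal currency of the pipeline: a samples x taxa matrix of
#' non-negative integer counts, with taxon lineage strings attached.
#' Lineages follow the 7-rank GREENGENES convention
#' (\code{"k__...; p__...; c__...; o__...; f__...; g__...; s__..."});
#' unknown ranks may be left empty after the rank prefix.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns.
#'   Row names are sample ids, column names taxon ids; both must be
#'   unique and non-empty.
#' @param lineages character vector of lineage strings, one per taxon,
#'   named by taxon id (or unnamed, in which case column order is used).
#' @return An object of class \code{count_table}: a list with elements
#'   \code{counts} (integer matrix) and \code{lineages} (named character).
#' @export
count_table <- function(counts, lineages = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in count table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids in count table")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in totals
  if (is.null(lineages)) {
    lineages <- stats::setNames(rep(NA_character_, ncol(counts)), colnames(counts))
  } else {
    if (length(lineages) != ncol(counts))
      stop("lineages length (", length(lineages),
           ") does not match taxon count (", ncol(counts), ")")
    if (is.null(names(lineages))) names(lineages) <- colnames(counts)
    lineages <- lineages[colnames(counts)]
  }
  structure(list(counts = counts, lineages = lineages), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " taxa\n", sep = "")
  cat("  total reads: ", format(sum(x$counts), big.mark = ","),
      "; median library size: ",
      format(stats::median(rowSums(x$counts)), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Number of samples / taxa in a count table
#' @param x a \code{count_table}
#' @return integer count
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname n_samples
#' @export
n_taxa <- function(x) ncol(x$counts)

#' Subset a count table by samples and/or taxa
#'
#' @param x a \code{count_table}
#' @param samples,taxa index vectors (logical, integer or character)
#' @return a \code{count_table}
#' @export
subset_table <- function(x, samples = NULL, taxa = NULL) {
  counts <- x$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(taxa)) counts <- counts[, taxa, drop = FALSE]
  count_table(counts, x$lineages[colnames(counts)])
}

rank_prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")

#' Extract one taxonomic rank from lineage strings
#'
#' @param lineages character vector of GREENGENES-style lineage strings.
#' @param level one of \code{"kingdom"}, \code{"phylum"}, \code{"class"},
#'   \code{"order"}, \code{"family"}, \code{"genus"}, \code{"species"}.
#' @return character vector of rank names, \code{""} where the rank is
#'   unnamed or missing.
#' @export
lineage_rank <- function(lineages, level) {
  level <- match.arg(level, names(rank_prefixes))
  pref <- rank_prefixes[[level]]
  vapply(strsplit(lineages, ";"), function(parts) {
    parts <- trimws(parts)
    hit <- parts[startsWith(parts, pref)]
    if (length(hit) == 0) return("")
    sub(pref, "", hit[1], fixed = TRUE)
  }, character(1))
}

#' Read a count table from TSV
#'
#' Expects taxa in rows and samples in columns (the common feature-table
#' export layout), with the first column holding taxon ids and an optional
#' \code{lineage} column. A leading \code{"# Constructed from biom file"}
#' comment line is tolerated.
#'
#' @param path TSV file path.
#' @return a \code{count_table} (samples x taxa).
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  taxon_ids <- as.character(df[[1]])
  df <- df[-1]
  lineages <- NULL
  lin_col <- which(tolower(names(df)) %in% c("lineage", "taxonomy"))
  if (length(lin_col)) {
    lineages <- stats::setNames(as.character(df[[lin_col[1]]]), taxon_ids)
    df <- df[-lin_col]
  }
  m <- t(as.matrix(df))
  colnames(m) <- taxon_ids
  count_table(m, lineages)
}

#' Write a count table to TSV (taxa rows, samples columns)
#'
#' @param x a \code{count_table}
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(taxon_id = colnames(x$counts),
                   t(x$counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$lineage <- unname(x$lineages)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns \code{sample_id}, \code{subject_id}, \code{timepoint}
#' and \code{weight_group}; further columns (weights, covariates) are
#' carried through.
#'
#' @param path TSV file path.
#' @return data.frame of per-sample metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "subject_id", "timepoint", "weight_group")
  miss <- setdiff(req, names(md))
  if (length(miss))
    stop("metadata is missing required columns: ", paste(miss, collapse = ", "))
  md
}

#' Write sample metadata to TSV
#' @param metadata data.frame of per-sample metadata.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
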