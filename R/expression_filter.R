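#' Read a gene-level count matrix from TSV/CSV
#'
#' Genes in rows (first column = gene id), samples in columns, header row.
#' @param path TSV or CSV file.
#' @return integer matrix with gene ids as rownames, sample ids as
#'   colnames.
#' @export
read_counts_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d)
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0L))
    stop("count matrix must be non-negative integers")
  m
}

#' Counts per million total library counts
#'
#' `cpm[g, s] = counts[g, s] / library_size[s] * 1e6`, where library
#' sizes are the raw column sums.
#'
#' @param counts non-negative gene x sample matrix.
#' @return matrix of CPM values; every column sums to 1e6.
#' @export
compute_cpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  lib <- colSums(counts)
  zero <- which(lib == 0)
  if (length(zero))
    stop("zero library size for sample '",
         if (!is.null(colnames(counts))) colnames(counts)[zero[1L]]
         else zero[1L], "'")
  sweep(counts, 2L, lib, "/") * 1e6
}

#' Minimum-expression filter on a count matrix
#'
#' Retains a gene when its CPM reaches `min_cpm` in at least
#' `ceiling(min_sample_frac * n_samples)` samples (the "at least 1 CPM in
#' 25% of the samples" floor commonly applied before differential
#' expression). Set `comparator = "more_than"` for a strict-majority
#' reading of the sample fraction
#' (`floor(min_sample_frac * n_samples) + 1`).
#'
#' @param counts non-negative gene x sample matrix (genes in rows).
#' @param min_cpm CPM threshold (default 1).
#' @param min_sample_frac required fraction of samples (default 0.25).
#' @param comparator `"at_least"` (default) or `"more_than"`, the
#'   reading of "in \code{min_sample_frac} of the samples".
#' @return character vector of retained gene ids (row indices as
#'   characters when the matrix has no rownames).
#' @export
filter_expressed <- function(counts, min_cpm = 1, min_sample_frac = 0.25,
                             comparator = c("at_least", "more_than")) {
  comparator <- match.arg(comparator)
  stopifnot(min_sample_frac > 0, min_sample_frac <= 1)
  counts <- as.matrix(counts)
  cpm <- compute_cpm(counts)
  n <- ncol(counts)
  need <- if (comparator == "at_least") ceiling(min_sample_frac * n)
          else floor(min_sample_frac * n) + 1
  keep <- rowSums(cpm >= min_cpm) >= need
  ids <- rownames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  ids[keep]
}
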