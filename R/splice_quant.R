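#' Classify a spliced read against the junctions of an exon of interest
#'
#' The read's N-gapped alignment is split into aligned blocks and splice
#' gaps; each gap is compared, with zero tolerance, against three
#' annotated junctions of the exon of interest (Eoi): the intron joining
#' the adjacent upstream exon to the Eoi (`up_eoi`), the intron joining
#' the Eoi to the adjacent downstream exon (`eoi_down`), and the fused
#' gap joining the upstream exon directly to the downstream exon while
#' skipping the Eoi (`skip`). A gap supports a junction only when the
#' read has at least `min_anchor` aligned bases immediately on each side
#' of it. A read spanning both Eoi junctions supports both.
#'
#' @param read one-row alignment `data.frame` (columns `pos`, `cigar`).
#' @param t a [transcript_model].
#' @param eoi_index exon ordinal (transcript orientation) of the exon of
#'   interest; must be internal.
#' @param min_anchor minimum aligned bases on each side of a junction
#'   (default 8).
#' @return character vector of supported categories, or `"uninformative"`.
#' @export
classify_junction_read <- function(read, t, eoi_index, min_anchor = 8L) {
  jd <- .eoi_junctions(t, eoi_index)
  bg <- .cigar_blocks(read$pos, read$cigar)
  if (!nrow(bg$gaps)) return("uninformative")
  supports <- character()
  for (gi in seq_len(nrow(bg$gaps))) {
    gap <- bg$gaps[gi, ]
    left  <- bg$blocks[bg$blocks[, "end"] == gap[["start"]] - 1L, , drop = FALSE]
    right <- bg$blocks[bg$blocks[, "start"] == gap[["end"]] + 1L, , drop = FALSE]
    if (!nrow(left) || !nrow(right)) next
    anchored <- (left[1L, "end"] - left[1L, "start"] + 1L) >= min_anchor &&
      (right[1L, "end"] - right[1L, "start"] + 1L) >= min_anchor
    if (!anchored) next
    for (cat in names(jd))
      if (gap[["start"]] == jd[[cat]][1L] && gap[["end"]] == jd[[cat]][2L])
        supports <- c(supports, cat)
  }
  if (length(supports)) unique(supports) else "uninformative"
}

## Genomic gap intervals (1-based closed) of the three Eoi junctions.
## Categories are labelled in transcript orientation; the coordinates are
## strand-symmetric.
.eoi_junctions <- function(t, eoi_index) {
  n <- n_exons(t)
  if (eoi_index <= 1L || eoi_index >= n)
    stop("exon of interest must be internal (2..", n - 1L,
         "); got ", eoi_index)
  g <- genomic_exon_index(t, eoi_index)
  es <- GenomicRanges::start(t$exons); ee <- GenomicRanges::end(t$exons)
  left  <- c(ee[g - 1L] + 1L, es[g] - 1L)       # intron left of Eoi
  right <- c(ee[g] + 1L, es[g + 1L] - 1L)       # intron right of Eoi
  fused <- c(ee[g - 1L] + 1L, es[g + 1L] - 1L)  # Eoi skipped
  if (t$strand == "+")
    list(up_eoi = left, eoi_down = right, skip = fused)
  else
    list(up_eoi = right, eoi_down = left, skip = fused)
}

#' Count junction-spanning reads around an exon of interest
#'
#' Tallies [classify_junction_read()] over a set of alignments; each read
#' contributes at most one count per category (a read spanning both Eoi
#' junctions increments both inclusion counters). Unmapped, secondary,
#' supplementary and duplicate-marked records are skipped.
#'
#' @param reads alignment `data.frame` as from [read_alignments()].
#' @inheritParams classify_junction_read
#' @return object of class `"junction_counts"`: list with
#'   `individual_id`, `transcript_id`, `eoi_index`, `n_up_eoi`,
#'   `n_eoi_down`, `n_skip`.
#' @export
count_junctions <- function(reads, t, eoi_index, min_anchor = 8L) {
  .eoi_junctions(t, eoi_index)          # validate eoi up front
  reads <- .primary_records(reads, drop_dup = TRUE)
  reads <- reads[reads$chrom == t$chrom, , drop = FALSE]
  tall <- c(up_eoi = 0L, eoi_down = 0L, skip = 0L)
  for (i in seq_len(nrow(reads))) {
    cats <- classify_junction_read(reads[i, ], t, eoi_index, min_anchor)
    for (cat in setdiff(cats, "uninformative"))
      tall[[cat]] <- tall[[cat]] + 1L
  }
  structure(list(
    individual_id = if (nrow(reads)) reads$individual_id[1L] else NA_character_,
    transcript_id = t$transcript_id,
    eoi_index = as.integer(eoi_index),
    n_up_eoi = tall[["up_eoi"]],
    n_eoi_down = tall[["eoi_down"]],
    n_skip = tall[["skip"]]
  ), class = "junction_counts")
}

#' Build a junction_counts object from raw tallies
#' @param n_up_eoi,n_eoi_down,n_skip non-negative junction-read counts.
#' @param individual_id,transcript_id,eoi_index optional labels.
#' @return a `"junction_counts"` object.
#' @export
junction_counts <- function(n_up_eoi, n_eoi_down, n_skip,
                            individual_id = NA_character_,
                            transcript_id = NA_character_,
                            eoi_index = NA_integer_) {
  stopifnot(n_up_eoi >= 0, n_eoi_down >= 0, n_skip >= 0)
  structure(list(individual_id = individual_id,
                 transcript_id = transcript_id,
                 eoi_index = as.integer(eoi_index),
                 n_up_eoi = as.integer(n_up_eoi),
                 n_eoi_down = as.integer(n_eoi_down),
                 n_skip = as.integer(n_skip)),
            class = "junction_counts")
}

#' @export
print.junction_counts <- function(x, ...) {
  cat("Junction counts (exon ", x$eoi_index, "): up-Eoi ", x$n_up_eoi,
      ", Eoi-down ", x$n_eoi_down, ", skip ", x$n_skip, "\n", sep = "")
  invisible(x)
}

#' Percentage exon retention from junction counts
#'
#' Inclusion averages the two junction-read counts flanking the exon of
#' interest, `inclusion = (n_up_eoi + n_eoi_down) / 2` (possibly
#' half-integral); exclusion is the count of reads splicing directly
#' between the flanking exons. Then
#' `PIR = 100 * inclusion / (inclusion + exclusion)`, or `NA` when no
#' informative read was seen.
#'
#' @param jc a `"junction_counts"` object.
#' @return object of class `"pir_record"`: list with `individual_id`,
#'   `eoi_index`, `inclusion`, `exclusion`, `pir` (percentage in
#'   `[0, 100]` or `NA`).
#' @examples
#' compute_pir(junction_counts(4, 6, 5))   # inclusion 5, exclusion 5, PIR 50
#' @export
compute_pir <- function(jc) {
  stopifnot(inherits(jc, "junction_counts"))
  inclusion <- (jc$n_up_eoi + jc$n_eoi_down) / 2
  exclusion <- jc$n_skip
  pir <- if (inclusion + exclusion > 0)
    100 * inclusion / (inclusion + exclusion) else NA_real_
  structure(list(individual_id = jc$individual_id,
                 eoi_index = jc$eoi_index,
                 inclusion = inclusion, exclusion = exclusion, pir = pir),
            class = "pir_record")
}

#' @export
print.pir_record <- function(x, ...) {
  cat("PIR (exon ", x$eoi_index, "): inclusion ", x$inclusion,
      ", exclusion ", x$exclusion, " -> ",
      if (is.na(x$pir)) "NA (no informative reads)"
      else sprintf("%.1f%%", x$pir), "\n", sep = "")
  invisible(x)
}

#' Per-individual, per-exon PIR table
#'
#' Runs [count_junctions()] and [compute_pir()] for every combination of
#' individual and exon of interest — the per-individual exon-retention
#' table behind group-level missplicing comparisons.
#'
#' @param alignments_by_individual named list: individual id ->
#'   alignment `data.frame` (or SAM/BAM path, read on the fly).
#' @param t a [transcript_model].
#' @param eoi_indices internal exon ordinals to quantify.
#' @param min_anchor minimum junction anchor (bp).
#' @return `data.frame`: `individual_id`, `eoi_index`, `n_up_eoi`,
#'   `n_eoi_down`, `n_skip`, `inclusion`, `exclusion`, `pir`.
#' @export
pir_table <- function(alignments_by_individual, t, eoi_indices,
                      min_anchor = 8L) {
  ids <- names(alignments_by_individual)
  if (is.null(ids)) stop("alignments_by_individual must be a named list")
  rows <- list()
  for (id in ids) {
    reads <- alignments_by_individual[[id]]
    if (is.character(reads)) reads <- read_alignments(reads, id)
    for (eoi in eoi_indices) {
      jc <- count_junctions(reads, t, eoi, min_anchor)
      pr <- compute_pir(jc)
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = id, eoi_index = as.integer(eoi),
        n_up_eoi = jc$n_up_eoi, n_eoi_down = jc$n_eoi_down,
        n_skip = jc$n_skip, inclusion = pr$inclusion,
        exclusion = pr$exclusion, pir = pr$pir, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
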