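#' Construct a transcript model
#'
#' A transcript model holds the exon and CDS intervals of one transcript,
#' in genomic order, together with the introns derived as the gaps between
#' consecutive exons. All coordinates are 1-based, fully closed (the
#' IRanges/GFF convention). Exon ordinals used elsewhere in the package
#' (splice boundaries, exon-of-interest indices) are counted in transcript
#' orientation: exon 1 is the 5'-most exon of the mRNA, so on the minus
#' strand it is the genomically rightmost exon.
#'
#' @param transcript_id transcript identifier.
#' @param gene_id gene identifier (may be `NA`).
#' @param chrom reference sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column `data.frame` (or matrix) of 1-based closed
#'   `start`/`end` exon coordinates, any order.
#' @param cds like `exons`, for the coding intervals; may be empty.
#' @return An object of class `"transcript_model"`: a list with elements
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, and `GRanges` slots
#'   `exons`, `cds`, `introns` (all sorted in genomic order), plus the
#'   precomputed `cds_length`.
#' @examples
#' tx <- transcript_model("t1", "g1", "chr1", "+",
#'                        exons = data.frame(start = c(1, 201, 401),
#'                                           end   = c(100, 300, 500)),
#'                        cds   = data.frame(start = c(11, 201, 401),
#'                                           end   = c(100, 300, 460)))
#' tx
#' @export
transcript_model <- function(transcript_id, gene_id = NA_character_,
                             chrom, strand = c("+", "-"),
                             exons, cds = NULL) {
  strand <- match.arg(strand)
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            nzchar(chrom))
  exons <- .as_interval_df(exons, "exon")
  if (nrow(exons) == 0L)
    stop("transcript '", transcript_id, "' has no exons")
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L) {
    ov <- which(exons$start[-1L] <= exons$end[-nrow(exons)])
    if (length(ov))
      stop("overlapping exons in transcript '", transcript_id, "': exon [",
           exons$start[ov[1L]], "-", exons$end[ov[1L]], "] overlaps exon [",
           exons$start[ov[1L] + 1L], "-", exons$end[ov[1L] + 1L], "]")
  }
  cds <- if (is.null(cds)) data.frame(start = integer(), end = integer())
         else .as_interval_df(cds, "CDS")
  cds <- cds[order(cds$start), , drop = FALSE]
  exon_ir <- IRanges::IRanges(exons$start, exons$end)
  if (nrow(cds)) {
    cds_ir <- IRanges::IRanges(cds$start, cds$end)
    within <- IRanges::countOverlaps(cds_ir, exon_ir, type = "within")
    if (any(within == 0L))
      stop("CDS interval [", cds$start[within == 0L][1L], "-",
           cds$end[within == 0L][1L], "] not contained in any exon of '",
           transcript_id, "'")
  }
  introns <- if (nrow(exons) > 1L)
    data.frame(start = exons$end[-nrow(exons)] + 1L,
               end   = exons$start[-1L] - 1L)
  else data.frame(start = integer(), end = integer())

  gr <- function(df) GenomicRanges::GRanges(
    rep(chrom, nrow(df)), IRanges::IRanges(df$start, df$end),
    strand = rep(strand, nrow(df)))
  structure(list(
    transcript_id = transcript_id,
    gene_id       = gene_id,
    chrom         = chrom,
    strand        = strand,
    exons         = gr(exons),
    cds           = gr(cds),
    introns       = gr(introns),
    cds_length    = if (nrow(cds)) sum(cds$end - cds$start + 1L) else 0L
  ), class = "transcript_model")
}

.as_interval_df <- function(x, what) {
  x <- as.data.frame(x)
  if (!all(c("start", "end") %in% names(x)))
    names(x)[1:2] <- c("start", "end")
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  if (any(is.na(x$start) | is.na(x$end)) || any(x$start < 1L) ||
      any(x$end < x$start))
    stop("invalid ", what, " interval: start must be >= 1 and <= end")
  x[c("start", "end")]
}

#' @export
print.transcript_model <- function(x, ...) {
  n <- length(x$exons)
  cat("Transcript model '", x$transcript_id, "' (", x$chrom, x$strand,
      "): ", n, " exon", if (n != 1L) "s", ", span ",
      min(GenomicRanges::start(x$exons)), "-",
      max(GenomicRanges::end(x$exons)),
      ", CDS ", x$cds_length, " bp\n", sep = "")
  invisible(x)
}

#' Number of exons of a transcript model
#' @param t a [transcript_model].
#' @return integer exon count.
#' @export
n_exons <- function(t) length(t$exons)

#' Map a transcript-orientation exon ordinal to the genomic exon index
#'
#' Exon 1 is the 5'-most exon of the mRNA; on the minus strand that is the
#' last exon in genomic order.
#' @param t a [transcript_model].
#' @param exon_index 1-based exon ordinal in transcript orientation.
#' @return 1-based index into `t$exons` (genomic order).
#' @export
genomic_exon_index <- function(t, exon_index) {
  n <- n_exons(t)
  if (any(exon_index < 1L) || any(exon_index > n))
    stop("exon_index out of range 1..", n)
  if (t$strand == "+") as.integer(exon_index) else n - as.integer(exon_index) + 1L
}

#' Load one transcript from a GFF3/GTF gene annotation
#'
#' Reads exon (and, when present, CDS) features belonging to
#' `transcript_id` and assembles a [transcript_model]. GFF3 files are
#' matched on the `Parent` attribute (with or without a `transcript:`
#' prefix) or the feature `ID`; GTF files on the `transcript_id`
#' attribute. GFF3 `phase` attributes, when present on CDS features, are
#' validated against the frame implied by the CDS interval lengths.
#'
#' @param path GFF3 or GTF file.
#' @param transcript_id the transcript to extract.
#' @return a [transcript_model].
#' @export
load_gene_model <- function(path, transcript_id) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  fmt <- if (grepl("\\.(gtf)(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  g <- rtracklayer::import(path, format = fmt)
  m <- S4Vectors::mcols(g)
  belongs <- if (fmt == "gtf") {
    !is.na(m$transcript_id) & m$transcript_id == transcript_id
  } else {
    pa <- if ("Parent" %in% names(m))
      vapply(m$Parent, function(p)
        any(sub("^transcript:", "", p) == transcript_id), logical(1L))
    else rep(FALSE, length(g))
    id <- if ("ID" %in% names(m))
      !is.na(m$ID) & sub("^transcript:", "", m$ID) == transcript_id
    else rep(FALSE, length(g))
    pa | id
  }
  sel <- g[belongs]
  ex <- sel[tolower(m$type[belongs]) == "exon"]
  cd <- sel[toupper(as.character(m$type[belongs])) == "CDS"]
  if (length(ex) == 0L)
    stop("transcript '", transcript_id, "' not found in ", path)
  gene_id <- {
    mm <- S4Vectors::mcols(ex)
    if ("gene_id" %in% names(mm) && !all(is.na(mm$gene_id)))
      mm$gene_id[[1L]] else NA_character_
  }
  tm <- transcript_model(
    transcript_id = transcript_id,
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(ex))[1L],
    strand = as.character(GenomicRanges::strand(ex))[1L],
    exons = data.frame(start = GenomicRanges::start(ex),
                       end = GenomicRanges::end(ex)),
    cds = if (length(cd))
      data.frame(start = GenomicRanges::start(cd),
                 end = GenomicRanges::end(cd)) else NULL)
  .validate_phase(tm, cd)
  tm
}

## phase, when annotated, must equal the frame carried into each CDS piece
.validate_phase <- function(tm, cd) {
  if (!length(cd)) return(invisible(tm))
  ph <- S4Vectors::mcols(cd)$phase
  if (is.null(ph) || all(is.na(ph))) return(invisible(tm))
  ph <- suppressWarnings(as.integer(as.character(ph)))
  o <- order(GenomicRanges::start(cd))
  if (tm$strand == "-") o <- rev(o)
  len <- (GenomicRanges::end(cd) - GenomicRanges::start(cd) + 1L)[o]
  expected <- c(0L, cumsum(len)[-length(len)]) %% 3L
  expected <- (3L - expected) %% 3L
  got <- ph[o]
  bad <- which(!is.na(got) & got != expected)
  if (length(bad))
    stop("GFF3 phase mismatch for CDS piece ", bad[1L], " of '",
         tm$transcript_id, "': annotated ", got[bad[1L]],
         ", implied ", expected[bad[1L]])
  invisible(tm)
}

#' Write a transcript model to GFF3
#'
#' Emits gene, mRNA, exon and CDS features so that
#' [load_gene_model()] on the output reproduces the same intervals.
#'
#' @param t a [transcript_model].
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(t, path) {
  gid <- if (is.na(t$gene_id)) paste0(t$transcript_id, "_gene") else t$gene_id
  span <- c(min(GenomicRanges::start(t$exons)),
            max(GenomicRanges::end(t$exons)))
  ln <- function(start, end, type, attrs)
    paste(t$chrom, "spliceko", type, start, end, ".", t$strand, ".",
          attrs, sep = "\t")
  lines <- c(
    "##gff-version 3",
    ln(span[1L], span[2L], "gene", paste0("ID=", gid)),
    ln(span[1L], span[2L], "mRNA",
       paste0("ID=", t$transcript_id, ";Parent=", gid)),
    mapply(ln, GenomicRanges::start(t$exons), GenomicRanges::end(t$exons),
           "exon", paste0("Parent=", t$transcript_id)),
    if (length(t$cds))
      mapply(ln, GenomicRanges::start(t$cds), GenomicRanges::end(t$cds),
             "CDS", paste0("Parent=", t$transcript_id)))
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Splice boundaries of a transcript
#'
#' Every intron contributes one donor (the exon/intron junction at the
#' transcription-downstream end of the preceding exon) and one acceptor.
#' Positions are the genomic coordinates of the terminal exonic base
#' adjacent to the intron. Exon ordinals are in transcript orientation,
#' so the first exon carries only a donor and the last only an acceptor.
#'
#' @param t a [transcript_model].
#' @return `data.frame` with columns `transcript_id`, `exon_index`
#'   (transcript-orientation ordinal of the exon owning the boundary),
#'   `side` (`"donor"`/`"acceptor"`), `position`. Empty for single-exon
#'   transcripts.
#' @export
splice_boundaries <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  n <- n_exons(t)
  empty <- data.frame(transcript_id = character(), exon_index = integer(),
                      side = character(), position = integer())
  if (n < 2L) return(empty)
  es <- GenomicRanges::start(t$exons); ee <- GenomicRanges::end(t$exons)
  ## genomic intron j sits between genomic exons j and j+1
  j <- seq_len(n - 1L)
  if (t$strand == "+") {
    out <- rbind(
      data.frame(exon_index = j,      side = "donor",    position = ee[j]),
      data.frame(exon_index = j + 1L, side = "acceptor", position = es[j + 1L]))
  } else {
    ## transcription runs right to left: genomic exon j+1 donates into intron j
    ord <- n - seq_len(n) + 1L   # genomic index -> transcript ordinal
    out <- rbind(
      data.frame(exon_index = ord[j + 1L], side = "donor",
                 position = es[j + 1L]),
      data.frame(exon_index = ord[j], side = "acceptor", position = ee[j]))
  }
  out <- data.frame(transcript_id = t$transcript_id, out)
  out[order(out$exon_index, out$side), , drop = FALSE]
}

#' Fraction of the coding sequence removed by a deletion
#'
#' @param t a [transcript_model] with a non-empty CDS.
#' @param del_start,del_end 1-based closed genomic interval of the
#'   deleted bases.
#' @return the deleted-CDS base count divided by the CDS length, in
#'   `[0, 1]`; `0` when the deletion misses the CDS entirely.
#' @export
cds_fraction_removed <- function(t, del_start, del_end) {
  stopifnot(inherits(t, "transcript_model"), del_start <= del_end)
  if (t$cds_length == 0L)
    stop("transcript '", t$transcript_id, "' has no annotated CDS")
  .cds_overlap_bp(t, del_start, del_end) / t$cds_length
}

.cds_overlap_bp <- function(t, start, end) {
  if (!length(t$cds)) return(0L)
  s <- pmax(GenomicRanges::start(t$cds), start)
  e <- pmin(GenomicRanges::end(t$cds), end)
  sum(pmax(0L, e - s + 1L))
}
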