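#' Read alignments from a SAM or BAM file
#'
#' Thin wrapper around Rsamtools. Plain-text SAM input is converted to a
#' temporary BAM first (the file must carry `@SQ` header lines). Returns
#' one row per alignment record.
#'
#' @param path SAM or BAM file.
#' @param individual_id optional label attached to every record (the
#'   package's per-individual summaries group on this column).
#' @return `data.frame` with columns `read_id`, `flag`, `chrom`, `pos`
#'   (1-based leftmost aligned reference position), `cigar`, `seq`,
#'   `individual_id`.
#' @export
read_alignments <- function(path, individual_id = NA_character_) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"))
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(res$pos)
  data.frame(
    read_id = res$qname[keep],
    flag = res$flag[keep],
    chrom = as.character(res$rname)[keep],
    pos = res$pos[keep],
    cigar = res$cigar[keep],
    seq = as.character(res$seq)[keep],
    individual_id = rep(individual_id, sum(keep)),
    stringsAsFactors = FALSE)
}

## Split a CIGAR string into (length, op) pairs; error names the bad token.
.cigar_ops <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar) || cigar == "*")
    stop("read has no usable CIGAR ('", cigar, "')")
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]|[^0-9MIDNSHP=X]+|[0-9]+$",
                                     cigar))[[1L]]
  bad <- toks[!grepl("^[0-9]+[MIDNSH=X]$", toks)]
  if (length(bad) || sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR token '",
         if (length(bad)) bad[1L] else cigar, "' in '", cigar, "'")
  list(len = as.integer(sub("[MIDNSH=X]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

## Reference bases consumed by an alignment (M/=/X/D/N).
.cigar_ref_width <- function(cigar) {
  co <- .cigar_ops(cigar)
  sum(co$len[co$op %in% c("M", "=", "X", "D", "N")])
}

#' Reference span of alignment records
#' @param reads alignment `data.frame` as from [read_alignments()].
#' @return `data.frame` with 1-based closed `start`, `end` per record.
#' @keywords internal
alignment_span <- function(reads) {
  w <- vapply(reads$cigar, .cigar_ref_width, integer(1L), USE.NAMES = FALSE)
  data.frame(start = reads$pos, end = reads$pos + w - 1L)
}

## Aligned reference blocks and N gaps of one record.
## Blocks are maximal runs of reference-consuming, non-N operations
## (M/=/X/D); each N op closes the current block and records a gap.
.cigar_blocks <- function(pos, cigar) {
  co <- .cigar_ops(cigar)
  ref <- pos
  bstart <- pos
  blocks <- matrix(integer(), ncol = 2L)
  gaps <- matrix(integer(), ncol = 2L)
  open <- FALSE
  for (i in seq_along(co$op)) {
    op <- co$op[i]; len <- co$len[i]
    if (op %in% c("M", "=", "X", "D")) {
      if (!open) { bstart <- ref; open <- TRUE }
      ref <- ref + len
    } else if (op == "N") {
      if (open) { blocks <- rbind(blocks, c(bstart, ref - 1L)); open <- FALSE }
      gaps <- rbind(gaps, c(ref, ref + len - 1L))
      ref <- ref + len
    }
    ## I/S/H consume no reference
  }
  if (open) blocks <- rbind(blocks, c(bstart, ref - 1L))
  colnames(blocks) <- colnames(gaps) <- c("start", "end")
  list(blocks = blocks, gaps = gaps)
}

## Drop unmapped / secondary / supplementary (and optionally duplicate)
## records so each clone or fragment votes once.
.primary_records <- function(reads, drop_dup = FALSE) {
  if (is.null(reads$flag)) return(reads)
  f <- reads$flag
  bad <- bitwAnd(f, 0x4L) > 0L | bitwAnd(f, 0x100L) > 0L |
    bitwAnd(f, 0x800L) > 0L
  if (drop_dup) bad <- bad | bitwAnd(f, 0x400L) > 0L
  reads[!bad, , drop = FALSE]
}
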