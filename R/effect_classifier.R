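#' Splice-site windows of a transcript
#'
#' For every exon/intron junction, the window extends `intronic_bp` bases
#' into the intron and `exonic_bp` bases into the exon. The canonical
#' 2-bp donor (GT) and acceptor (AG) dinucleotides are always included,
#' even when `intronic_bp < 2`. Windows are labelled `splice_donor` /
#' `splice_acceptor` for their intronic part (which contains the
#' canonical dinucleotide) and `splice_region` for the exonic part.
#'
#' @param t a [transcript_model].
#' @param intronic_bp,exonic_bp window half-widths (bp); defaults 8 and 3.
#' @return `data.frame` with columns `start`, `end` (1-based closed),
#'   `reason`, `exon_index`.
#' @export
splice_windows <- function(t, intronic_bp = 8L, exonic_bp = 3L) {
  sb <- splice_boundaries(t)
  ib <- max(as.integer(intronic_bp), 2L)
  eb <- as.integer(exonic_bp)
  if (!nrow(sb))
    return(data.frame(start = integer(), end = integer(),
                      reason = character(), exon_index = integer()))
  rows <- lapply(seq_len(nrow(sb)), function(i) {
    p <- sb$position[i]           # terminal exonic base at the junction
    ## which side of p the intron lies on depends on side and strand
    intron_right <- (sb$side[i] == "donor") == (t$strand == "+")
    if (intron_right) {
      intronic <- c(p + 1L, p + ib)
      exonic   <- c(p - eb + 1L, p)
    } else {
      intronic <- c(p - ib, p - 1L)
      exonic   <- c(p, p + eb - 1L)
    }
    out <- data.frame(start = intronic[1L], end = intronic[2L],
                      reason = paste0("splice_", sb$side[i]),
                      exon_index = sb$exon_index[i])
    if (eb > 0L)
      out <- rbind(out, data.frame(start = exonic[1L], end = exonic[2L],
                                   reason = "splice_region",
                                   exon_index = sb$exon_index[i]))
    out
  })
  do.call(rbind, rows)
}

#' Classify an indel into loss-of-function, splice-site or in-frame
#'
#' Deterministic three-way consequence call with precedence
#' SS > LOF > IF:
#' \enumerate{
#'   \item \strong{SS} when the indel's reference footprint (for an
#'     insertion: its anchor base) lies within or overlaps a splice-site
#'     window (see [splice_windows()]); the reason records whether the
#'     canonical donor/acceptor dinucleotide itself or only the flanking
#'     splice region is hit.
#'   \item \strong{LOF} when the net coding-length change is not a
#'     multiple of 3 (frameshift) or the deletion removes more than half
#'     of the coding sequence.
#'   \item \strong{IF} otherwise. Indels touching neither the transcript
#'     span nor any splice window are additionally flagged `noncoding`.
#' }
#' The net coding-length change of a deletion is minus its overlap with
#' the CDS; an insertion adds its full length when its anchor base lies
#' inside a CDS interval, else 0.
#'
#' @param indel one-row `data.frame` (or list) with `pos`, `kind`,
#'   `length` as produced by [parse_cigar_indels()].
#' @param t a [transcript_model].
#' @param intronic_bp,exonic_bp splice-window half-widths, see
#'   [splice_windows()].
#' @return `data.frame` row: `pos`, `kind`, `length`, `category`
#'   (`LOF`/`SS`/`IF`), `reason` (`frameshift`, `cds_majority_removed`,
#'   `splice_donor`, `splice_acceptor`, `splice_region`, `inframe`),
#'   `fraction_cds_removed`, `net_frame_shift` (0/1/2), `noncoding`.
#' @export
classify_indel <- function(indel, t, intronic_bp = 8L, exonic_bp = 3L) {
  stopifnot(inherits(t, "transcript_model"))
  pos <- as.integer(indel$pos); kind <- as.character(indel$kind)
  len <- as.integer(indel$length)
  stopifnot(kind %in% c("ins", "del"), len >= 1L)

  ## footprint for window membership: deleted bases, or the anchor base
  fs <- if (kind == "del") pos + 1L else pos
  fe <- if (kind == "del") pos + len else pos

  sw <- splice_windows(t, intronic_bp, exonic_bp)
  hit <- sw[sw$start <= fe & sw$end >= fs, , drop = FALSE]

  cds_bp <- if (kind == "del") .cds_overlap_bp(t, fs, fe) else 0L
  frac <- if (t$cds_length > 0L) cds_bp / t$cds_length else 0
  net <- if (kind == "del") -cds_bp
         else if (.in_cds(t, pos)) len else 0L
  shift <- abs(net) %% 3L

  if (nrow(hit)) {
    ## canonical intronic window wins over the exonic splice region
    reason <- if (any(hit$reason != "splice_region"))
      hit$reason[hit$reason != "splice_region"][1L] else "splice_region"
    category <- "SS"
  } else if (shift != 0L || frac > 0.5) {
    category <- "LOF"
    reason <- if (shift != 0L) "frameshift" else "cds_majority_removed"
  } else {
    category <- "IF"; reason <- "inframe"
  }
  span <- c(min(GenomicRanges::start(t$exons)),
            max(GenomicRanges::end(t$exons)))
  noncoding <- category == "IF" && (fe < span[1L] || fs > span[2L])
  data.frame(pos = pos, kind = kind, length = len, category = category,
             reason = reason, fraction_cds_removed = frac,
             net_frame_shift = shift, noncoding = noncoding,
             stringsAsFactors = FALSE)
}

.in_cds <- function(t, p) {
  length(t$cds) > 0L &&
    any(GenomicRanges::start(t$cds) <= p & GenomicRanges::end(t$cds) >= p)
}

#' Classify a table of indel calls
#'
#' Applies [classify_indel()] to every row; with `by_allele = TRUE`,
#' frameshift status is decided from the summed net coding-length change
#' of all indels carried by the same read (composite allele), as a clone
#' with e.g. a +1 insertion and a -1 deletion keeps its reading frame.
#'
#' @param calls `data.frame` from [parse_cigar_indels()] /
#'   [call_indels_at_site()].
#' @param t a [transcript_model].
#' @param by_allele classify composite alleles per read instead of
#'   individual indels.
#' @inheritParams classify_indel
#' @return the calls with annotation columns appended (per unique indel,
#'   or per read when `by_allele`).
#' @export
classify_indels <- function(calls, t, intronic_bp = 8L, exonic_bp = 3L,
                            by_allele = FALSE) {
  if (!nrow(calls)) {
    ann <- classify_indel(list(pos = 1L, kind = "del", length = 1L), t,
                          intronic_bp, exonic_bp)[0, ]
    return(cbind(calls, ann[, setdiff(names(ann), names(calls))]))
  }
  ann <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i)
    classify_indel(calls[i, ], t, intronic_bp, exonic_bp)))
  out <- cbind(calls[setdiff(names(calls), names(ann))], ann)
  if (by_allele && "read_id" %in% names(calls)) {
    for (id in unique(calls$read_id)) {
      sel <- out$read_id == id
      net <- vapply(which(sel), function(i) {
        if (out$kind[i] == "del")
          -.cds_overlap_bp(t, out$pos[i] + 1L, out$pos[i] + out$length[i])
        else if (.in_cds(t, out$pos[i])) out$length[i] else 0L
      }, numeric(1L))
      allele_shift <- abs(sum(net)) %% 3L
      ## an allele-level frame restoration demotes frameshift calls to IF
      fix <- sel & out$reason == "frameshift" & allele_shift == 0L
      out$category[fix] <- "IF"; out$reason[fix] <- "inframe"
      out$net_frame_shift[sel] <- allele_shift
    }
  }
  rownames(out) <- NULL
  out
}

#' Summarise indel effects per target site
#'
#' Counts annotated indels per consequence category, deduplicating by
#' allele key (`kind`, `length`, `pos`, inserted sequence) so that the
#' same indel observed in several clone reads is counted once — the
#' per-site three-category histogram of unique indels. Set
#' `unique_indels = FALSE` to count clone reads instead.
#'
#' @param annotated output of [classify_indels()].
#' @param site_id site label for the summary.
#' @param unique_indels deduplicate identical indels (default) or count
#'   every annotated row.
#' @return object of class `"effect_summary"`: list with `site_id`,
#'   `counts` (named integer vector over LOF/SS/IF), `n_indels`, and the
#'   deduplicated `annotations`.
#' @export
summarize_effects <- function(annotated, site_id, unique_indels = TRUE) {
  d <- annotated
  if (unique_indels && nrow(d)) {
    key <- paste(d$kind, d$length, d$pos,
                 if ("inserted_seq" %in% names(d)) d$inserted_seq else "",
                 sep = "|")
    d <- d[!duplicated(key), , drop = FALSE]
  }
  counts <- c(LOF = sum(d$category == "LOF"),
              SS = sum(d$category == "SS"),
              IF = sum(d$category == "IF"))
  structure(list(site_id = site_id, counts = counts,
                 n_indels = nrow(d), annotations = d),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat("Effect summary for site ", x$site_id, " (", x$n_indels,
      " unique indel", if (x$n_indels != 1L) "s", "):\n", sep = "")
  cat(sprintf("  LOF: %d   SS: %d   IF: %d\n",
              x$counts[["LOF"]], x$counts[["SS"]], x$counts[["IF"]]))
  invisible(x)
}
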