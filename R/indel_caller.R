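#' Extract indels from CIGAR strings
#'
#' Walks each record's CIGAR left to right, laying the operations onto the
#' reference: M/=/X consume reference and query, D and N reference only,
#' I and S query only, H neither. Every I or D operation yields one call,
#' anchored VCF-style at the reference base immediately before the event
#' (so a deletion at anchor `pos` removes bases `pos+1 .. pos+length`).
#' N gaps are spliced introns, not indels, and are never called.
#'
#' @param reads alignment `data.frame` as from [read_alignments()] (columns
#'   `read_id`, `chrom`, `pos`, `cigar`; optional `seq`, `individual_id`).
#' @return `data.frame` of calls: `chrom`, `pos` (1-based anchor), `kind`
#'   (`"ins"`/`"del"`), `length`, `inserted_seq` (`NA` for deletions or
#'   when the record has no sequence), `read_id`, `individual_id`.
#' @examples
#' r <- data.frame(read_id = "c1", chrom = "amp", pos = 101,
#'                 cigar = "10M2D15M", seq = NA, individual_id = "F01")
#' parse_cigar_indels(r)   # one 2-bp deletion anchored at 110
#' @export
parse_cigar_indels <- function(reads) {
  out <- lapply(seq_len(nrow(reads)), function(i)
    .indels_one(reads[i, , drop = FALSE]))
  out <- do.call(rbind, out)
  if (is.null(out)) .empty_indels() else out
}

.empty_indels <- function()
  data.frame(chrom = character(), pos = integer(), kind = character(),
             length = integer(), inserted_seq = character(),
             read_id = character(), individual_id = character(),
             stringsAsFactors = FALSE)

.indels_one <- function(r) {
  co <- .cigar_ops(r$cigar)
  seq <- if (!is.null(r$seq) && !is.na(r$seq) && r$seq != "*") r$seq else NA
  ref <- r$pos
  qry <- 1L
  calls <- list()
  for (i in seq_along(co$op)) {
    op <- co$op[i]; len <- co$len[i]
    if (op %in% c("M", "=", "X")) { ref <- ref + len; qry <- qry + len }
    else if (op %in% c("D", "N")) {
      if (op == "D")
        calls[[length(calls) + 1L]] <- list(pos = ref - 1L, kind = "del",
                                            length = len, ins = NA_character_)
      ref <- ref + len
    } else if (op == "I") {
      ins <- if (!is.na(seq)) substr(seq, qry, qry + len - 1L) else NA_character_
      calls[[length(calls) + 1L]] <- list(pos = ref - 1L, kind = "ins",
                                          length = len, ins = ins)
      qry <- qry + len
    } else if (op == "S") qry <- qry + len
    ## H: nothing
  }
  if (!length(calls)) return(NULL)
  data.frame(
    chrom = r$chrom,
    pos = vapply(calls, `[[`, integer(1L), "pos"),
    kind = vapply(calls, `[[`, character(1L), "kind"),
    length = vapply(calls, `[[`, integer(1L), "length"),
    inserted_seq = vapply(calls, `[[`, character(1L), "ins"),
    read_id = r$read_id,
    individual_id = if (!is.null(r$individual_id)) r$individual_id
                    else NA_character_,
    stringsAsFactors = FALSE)
}

## Reference footprint of a call, 1-based closed. An insertion sits between
## anchor and anchor+1; both flanking bases are taken as its footprint.
.indel_footprint <- function(calls) {
  s <- ifelse(calls$kind == "del", calls$pos + 1L, calls$pos)
  e <- ifelse(calls$kind == "del", calls$pos + calls$length, calls$pos + 1L)
  data.frame(start = s, end = e)
}

#' Which reads can be genotyped at a target site?
#'
#' A read is informative only if its aligned reference span covers the
#' whole target window plus `min_flank` bases on both sides; reads that
#' start, end or are clipped inside the window can neither be counted as
#' wild type nor as mutant.
#'
#' @param reads alignment `data.frame`.
#' @param site a [target_site()].
#' @param min_flank required covered flank (bp) on each side of the window.
#' @return the subset of `reads` passing the spanning criterion
#'   (unmapped, secondary and supplementary records already removed).
#' @export
genotypable_reads <- function(reads, site, min_flank = 5L) {
  reads <- .primary_records(reads)
  reads <- reads[reads$chrom == site$chrom, , drop = FALSE]
  if (!nrow(reads)) return(reads)
  sp <- alignment_span(reads)
  keep <- sp$start <= site$start - min_flank & sp$end >= site$end + min_flank
  reads[keep, , drop = FALSE]
}

#' Define a CRISPR target site
#'
#' @param site_id label, e.g. `"T1"`.
#' @param chrom reference sequence name.
#' @param start,end 1-based closed window in which indels are sought.
#' @param guide_sequence optional guide nucleotide string.
#' @return a `list` of class `"target_site"`.
#' @export
target_site <- function(site_id, chrom, start, end, guide_sequence = NA) {
  stopifnot(nzchar(chrom), start >= 1L, end >= start)
  structure(list(site_id = site_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 guide_sequence = guide_sequence),
            class = "target_site")
}

#' Read target-site definitions from a TSV file
#'
#' Expects columns `site_id`, `chrom`, `start`, `end` and optionally
#' `guide_sequence` (1-based closed coordinates).
#' @param path TSV file.
#' @return list of [target_site()] objects.
#' @export
read_target_sites <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "chrom", "start", "end")
  if (!all(need %in% names(d)))
    stop("target-site table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(d)), function(i)
    target_site(d$site_id[i], d$chrom[i], d$start[i], d$end[i],
                if ("guide_sequence" %in% names(d)) d$guide_sequence[i] else NA))
}

#' Call indels overlapping a CRISPR target site
#'
#' Restricts [parse_cigar_indels()] output to calls whose reference
#' footprint overlaps the site window, keeping only genotypable reads
#' (see [genotypable_reads()]). When the reference sequence is supplied,
#' calls are left-normalised: shifted to the smallest anchor position at
#' which the event describes the same alternate sequence, so identical
#' alleles from different reads share one key.
#'
#' @inheritParams genotypable_reads
#' @param ref optional reference sequence for `site$chrom` (character or
#'   `Biostrings::DNAString`) enabling left-normalisation.
#' @return `data.frame` of calls as in [parse_cigar_indels()], plus a
#'   `site_id` column.
#' @export
call_indels_at_site <- function(reads, site, min_flank = 5L, ref = NULL) {
  stopifnot(inherits(site, "target_site"))
  geno <- genotypable_reads(reads, site, min_flank)
  if (!nrow(geno)) {
    out <- .empty_indels(); out$site_id <- character(); return(out)
  }
  calls <- parse_cigar_indels(geno)
  if (nrow(calls) && !is.null(ref))
    calls <- left_normalize_indels(calls, ref)
  fp <- .indel_footprint(calls)
  keep <- fp$start <= site$end & fp$end >= site$start
  calls <- calls[keep, , drop = FALSE]
  calls$site_id <- rep(site$site_id, nrow(calls))
  rownames(calls) <- NULL
  calls
}

#' Left-normalise indel calls against the reference
#'
#' VCF-style left alignment: a deletion anchored at `p` removing
#' `ref[p+1..p+L]` shifts to `p-1` while `ref[p] == ref[p+L]`; an
#' insertion shifts left while its last inserted base equals the reference
#' base at the anchor (rotating the inserted sequence). Insertions without
#' a recorded sequence are left untouched.
#'
#' @param calls `data.frame` from [parse_cigar_indels()].
#' @param ref reference sequence (character or `Biostrings::DNAString`).
#' @return the calls with normalised `pos` (and `inserted_seq`).
#' @export
left_normalize_indels <- function(calls, ref) {
  ref <- toupper(as.character(ref))
  base <- function(i) substr(ref, i, i)
  for (i in seq_len(nrow(calls))) {
    p <- calls$pos[i]; L <- calls$length[i]
    if (calls$kind[i] == "del") {
      while (p >= 1L && base(p) == base(p + L)) p <- p - 1L
      calls$pos[i] <- p
    } else {
      ins <- calls$inserted_seq[i]
      if (is.na(ins)) next
      ins <- toupper(ins)
      while (p >= 1L && substr(ins, L, L) == base(p)) {
        ins <- paste0(base(p), substr(ins, 1L, L - 1L))
        p <- p - 1L
      }
      calls$pos[i] <- p; calls$inserted_seq[i] <- ins
    }
  }
  calls
}

## One key per allele: the ordered set of indels carried by a read.
.allele_key <- function(calls) {
  if (!nrow(calls)) return("WT")
  o <- order(calls$pos, calls$kind, calls$length)
  paste(ifelse(calls$kind[o] == "del",
               sprintf("del%d@%d", calls$length[o], calls$pos[o]),
               sprintf("ins%d@%d%s", calls$length[o], calls$pos[o],
                       ifelse(is.na(calls$inserted_seq[o]), "",
                              paste0(":", calls$inserted_seq[o])))),
        collapse = "+")
}

#' Tally alleles and mosaic mutant fraction for one individual
#'
#' Each genotyped read votes for one allele: the ordered set of indel
#' calls it carries, or wild type (WT) when it carries none. Reads with
#' identical indel sets collapse onto one allele key. The mosaic
#' mutant-allele fraction is `1 - n_wt / n_total`.
#'
#' @param calls calls from [call_indels_at_site()] for this individual.
#' @param genotyped_reads exactly the reads that passed
#'   [genotypable_reads()] for the site.
#' @param individual_id label for the individual (fish, founder, sample).
#' @param site the [target_site()].
#' @return an object of class `"allele_tally"`: list with
#'   `individual_id`, `site_id`, `n_reads_total`, `n_reads_wt`,
#'   `allele_table` (named integer vector, keys like `"del2@110"` or
#'   `"WT"`), and `mutant_fraction` (`NA` with a `no_reads` flag when no
#'   read could be genotyped).
#' @examples
#' # 8 clones: 3 WT, 5 with the same 2-bp deletion -> mutant fraction 0.625
#' @export
tally_alleles <- function(calls, genotyped_reads, individual_id, site) {
  stopifnot(inherits(site, "target_site"))
  n_total <- nrow(genotyped_reads)
  keys <- vapply(genotyped_reads$read_id, function(id)
    .allele_key(calls[calls$read_id == id, , drop = FALSE]), character(1L))
  tab <- if (n_total) table(keys) else table(character())
  allele_table <- as.integer(tab); names(allele_table) <- names(tab)
  n_wt <- if ("WT" %in% names(allele_table)) allele_table[["WT"]] else 0L
  structure(list(
    individual_id = individual_id,
    site_id = site$site_id,
    n_reads_total = n_total,
    n_reads_wt = n_wt,
    allele_table = allele_table,
    mutant_fraction = if (n_total) 1 - n_wt / n_total else NA_real_,
    no_reads = n_total == 0L
  ), class = "allele_tally")
}

#' @export
print.allele_tally <- function(x, ...) {
  cat("Allele tally for individual '", x$individual_id, "' at site ",
      x$site_id, ": ", x$n_reads_total, " reads, ", x$n_reads_wt,
      " WT, mutant fraction ",
      if (is.na(x$mutant_fraction)) "NA (no genotypable reads)"
      else sprintf("%.3f", x$mutant_fraction), "\n", sep = "")
  if (length(x$allele_table)) {
    for (k in names(sort(x$allele_table, decreasing = TRUE)))
      cat("  ", k, ": ", x$allele_table[[k]], "\n", sep = "")
  }
  invisible(x)
}

#' Write indel calls as a minimal VCF
#'
#' Emits CHROM/POS/REF/ALT records (VCF 4.2, left-anchored) for a call
#' table, using the reference sequence to spell out REF and ALT alleles.
#' Insertions without a recorded sequence are skipped with a warning.
#'
#' @param calls `data.frame` from [call_indels_at_site()]; calls should
#'   be left-normalised against the same reference.
#' @param ref reference sequence for the calls' chromosome (character or
#'   `Biostrings::DNAString`).
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_indel_vcf <- function(calls, ref, path) {
  ref <- toupper(as.character(ref))
  keep <- calls$kind == "del" | !is.na(calls$inserted_seq)
  if (any(!keep)) {
    warning(sum(!keep), " insertion call(s) without sequence skipped")
    calls <- calls[keep, , drop = FALSE]
  }
  key <- paste(calls$chrom, calls$pos, calls$kind, calls$length,
               calls$inserted_seq)
  calls <- calls[!duplicated(key), , drop = FALSE]
  anchor <- substr(rep(ref, nrow(calls)), calls$pos, calls$pos)
  refal <- ifelse(calls$kind == "del",
                  substr(rep(ref, nrow(calls)), calls$pos,
                         calls$pos + calls$length),
                  anchor)
  altal <- ifelse(calls$kind == "del", anchor,
                  paste0(anchor, calls$inserted_seq))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                       calls$chrom, calls$pos, refal, altal)[seq_len(nrow(calls))]),
             path)
  invisible(path)
}

#' Flatten allele tallies to a data.frame
#' @param tallies list of `"allele_tally"` objects.
#' @return one row per tally: `individual_id`, `site_id`,
#'   `n_reads_total`, `n_reads_wt`, `n_alleles`, `mutant_fraction`.
#' @export
allele_tally_table <- function(tallies) {
  do.call(rbind, lapply(tallies, function(x)
    data.frame(individual_id = x$individual_id, site_id = x$site_id,
               n_reads_total = x$n_reads_total, n_reads_wt = x$n_reads_wt,
               n_alleles = sum(names(x$allele_table) != "WT"),
               mutant_fraction = x$mutant_fraction,
               stringsAsFactors = FALSE)))
}
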