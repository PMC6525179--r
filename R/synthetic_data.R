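#' Configuration for the synthetic-data generator
#'
#' Bundles all knobs of the toy-locus, amplicon-read and spliced-read
#' simulators. Defaults emulate the validation design of a CRISPR
#' knockout screen: a multi-exon coding locus, a handful of Sanger-clone
#' amplicon reads per mosaic founder, and a few thousand short RNA-seq
#' fragments over the locus with a controlled exon-skip fraction.
#'
#' @param seed integer seed; a fixed config reproduces byte-identical
#'   output files.
#' @param n_exons,exon_length,intron_length toy-locus geometry (bp).
#' @param read_length spliced-read length (bp).
#' @param amplicon list: `flank` (bp of reference kept either side of the
#'   target window in each clone read), `n_reads` (clones per
#'   individual), `mutant_fraction` (mosaic mutant-allele fraction),
#'   `spectrum` (`data.frame` with `kind` in ins/del, `length`, `offset`
#'   of the anchor relative to the window start, `prob`; probabilities
#'   may sum to less than 1, the remainder meaning wild type), and
#'   `composition` (`"exact"`: the realised mutant-read count is
#'   `round(mutant_fraction * n_reads)`, modelling clone picking from a
#'   mosaic at that fraction; `"binomial"`: each read is independently
#'   mutant with probability `mutant_fraction`).
#' @param splicing list: `skip_fraction` (per-molecule probability that
#'   the exon of interest is skipped), `n_fragments`, `min_anchor`
#'   (bp; also the feasibility bound for exon length).
#' @return a `list` of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_exons = 8L, exon_length = 120L,
                       intron_length = 300L, read_length = 100L,
                       amplicon = list(), splicing = list()) {
  amp <- list(
    flank = 60L, n_reads = 8L, mutant_fraction = 0.625,
    spectrum = data.frame(kind = "del", length = 2L, offset = 0L, prob = 1),
    composition = "exact")
  amp[names(amplicon)] <- amplicon      # no recursion into the spectrum
  spl <- list(skip_fraction = 0.5, n_fragments = 4000L, min_anchor = 8L)
  spl[names(splicing)] <- splicing
  stopifnot(n_exons >= 3L, exon_length >= 1L, intron_length >= 10L,
            amp$mutant_fraction >= 0, amp$mutant_fraction <= 1,
            spl$skip_fraction >= 0, spl$skip_fraction <= 1,
            amp$composition %in% c("exact", "binomial"))
  if (sum(amp$spectrum$prob) > 1 + 1e-9)
    stop("indel spectrum probabilities must sum to at most 1")
  structure(list(seed = as.integer(seed), n_exons = as.integer(n_exons),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 read_length = as.integer(read_length),
                 amplicon = amp, splicing = spl),
            class = "sim_config")
}

#' Generate a toy reference locus with a multi-exon coding gene
#'
#' Writes a reference FASTA and a GFF3 gene model for one plus-strand
#' transcript whose exons are equally sized and equally spaced, with
#' canonical GT/AG dinucleotides at every intron end. The CDS covers the
#' exons, trimmed at the 3' end so its length is a multiple of 3.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with `fasta`, `gff3` (paths), `transcript` (a
#'   [transcript_model]), `chrom`, `seq` (reference sequence, character).
#' @export
make_toy_locus <- function(cfg, dir = tempfile("toylocus")) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$exon_length < 2L * cfg$splicing$min_anchor)
    stop("infeasible geometry: exon_length ", cfg$exon_length,
         " is shorter than twice the junction anchor requirement (",
         cfg$splicing$min_anchor, " bp)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  pad <- 200L
  n <- cfg$n_exons; el <- cfg$exon_length; il <- cfg$intron_length
  starts <- pad + (seq_len(n) - 1L) * (el + il) + 1L
  ends <- starts + el - 1L
  total <- 2L * pad + n * el + (n - 1L) * il
  seq <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  for (j in seq_len(n - 1L)) {      # canonical splice dinucleotides
    seq[ends[j] + 1L:2L] <- c("G", "T")
    seq[starts[j + 1L] - 2L:1L] <- c("A", "G")
  }
  seq <- paste(seq, collapse = "")
  chrom <- "toy_chr"
  cds_total <- n * el
  trim <- cds_total %% 3L
  cds <- data.frame(start = starts, end = ends)
  cds$end[n] <- cds$end[n] - trim
  tx <- transcript_model("toy_tx", "toy_gene", chrom, "+",
                         exons = data.frame(start = starts, end = ends),
                         cds = cds)
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(seq, chrom)), fasta)
  gff3 <- file.path(dir, "genemodel.gff3")
  write_gene_model(tx, gff3)
  list(fasta = fasta, gff3 = gff3, transcript = tx, chrom = chrom,
       seq = seq)
}

#' Simulate mosaic Sanger-clone amplicon reads at a target site
#'
#' Each clone read covers the target window plus `flank` reference bases
#' on both sides. A read carries either the wild-type sequence or one
#' indel drawn from the configured spectrum, applied at its offset from
#' the window start; the CIGAR and sequence are constructed to match.
#' A truth table records every read's allele.
#'
#' @param cfg a [sim_config()].
#' @param locus output of [make_toy_locus()] (or a compatible list with
#'   `chrom` and `seq`).
#' @param site a [target_site()].
#' @param dir output directory.
#' @param individual_id label written into read names and the truth table.
#' @return list with `sam`, `truth_tsv` (paths) and `truth`
#'   (`data.frame`: `read_id`, `individual_id`, `allele` — `"WT"` or
#'   e.g. `"del2@461"` with the 1-based anchor).
#' @export
simulate_amplicon_reads <- function(cfg, locus, site,
                                    dir = tempfile("amplicon"),
                                    individual_id = "sim1") {
  stopifnot(inherits(cfg, "sim_config"), inherits(site, "target_site"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  amp <- cfg$amplicon
  reflen <- nchar(locus$seq)
  rs <- max(1L, site$start - amp$flank)
  re <- min(reflen, site$end + amp$flank)
  n <- amp$n_reads
  spec <- amp$spectrum
  p <- spec$prob / sum(spec$prob)

  mutant <- if (amp$composition == "exact") {
    k <- round(amp$mutant_fraction * n)
    sample(rep(c(TRUE, FALSE), c(k, n - k)))
  } else stats::runif(n) < amp$mutant_fraction
  which_allele <- ifelse(mutant, sample(nrow(spec), n, replace = TRUE,
                                        prob = p), NA_integer_)

  recs <- vector("list", n)
  truth <- vector("character", n)
  for (i in seq_len(n)) {
    rid <- sprintf("%s_clone%02d", individual_id, i)
    if (!mutant[i]) {
      sq <- substr(locus$seq, rs, re)
      cigar <- paste0(nchar(sq), "M")
      truth[i] <- "WT"
    } else {
      a <- spec[which_allele[i], ]
      anchor <- site$start + a$offset          # base before the event
      if (a$kind == "del") {
        if (anchor < rs || anchor + a$length > re)
          stop("indel spectrum entry falls outside the amplicon")
        pre <- anchor - rs + 1L
        post <- re - (anchor + a$length)
        cigar <- sprintf("%dM%dD%dM", pre, a$length, post)
        sq <- paste0(substr(locus$seq, rs, anchor),
                     substr(locus$seq, anchor + a$length + 1L, re))
        truth[i] <- sprintf("del%d@%d", a$length, anchor)
      } else {
        if (anchor < rs || anchor >= re)
          stop("indel spectrum entry falls outside the amplicon")
        ins <- paste(sample(c("A", "C", "G", "T"), a$length, replace = TRUE),
                     collapse = "")
        pre <- anchor - rs + 1L
        post <- re - anchor
        cigar <- sprintf("%dM%dI%dM", pre, a$length, post)
        sq <- paste0(substr(locus$seq, rs, anchor), ins,
                     substr(locus$seq, anchor + 1L, re))
        truth[i] <- sprintf("ins%d@%d:%s", a$length, anchor, ins)
      }
    }
    recs[[i]] <- data.frame(qname = rid, flag = 0L, rname = locus$chrom,
                            pos = rs, cigar = cigar, seq = sq,
                            stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  sam <- file.path(dir, paste0(individual_id, "_amplicon.sam"))
  .write_sam(recs, locus$chrom, reflen, sam)
  truth_df <- data.frame(read_id = recs$qname, individual_id = individual_id,
                         allele = truth, stringsAsFactors = FALSE)
  truth_tsv <- file.path(dir, paste0(individual_id, "_amplicon_truth.tsv"))
  utils::write.table(truth_df, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(sam = sam, truth_tsv = truth_tsv, truth = truth_df)
}

#' Simulate spliced RNA-seq reads with controlled exon skipping
#'
#' Each fragment originates either from the isoform that includes the
#' exon of interest or from the isoform that skips it. The source
#' isoform is drawn with probability proportional to its molecular
#' abundance (`1 - skip_fraction` vs `skip_fraction`) times its number
#' of valid read start positions, the standard length-weighted sampling
#' of short-read RNA-seq; reads are then placed uniformly along the
#' chosen isoform, so junction anchors of every length from 1 bp up
#' occur and the minimum-anchor filter is exercised. CIGARs encode the
#' traversed introns as N operations.
#'
#' @param cfg a [sim_config()].
#' @param locus output of [make_toy_locus()].
#' @param eoi_index internal exon ordinal to subject to skipping.
#' @param dir output directory.
#' @param individual_id label for read names and the truth table.
#' @return list with `sam`, `truth_tsv` (paths) and `truth`
#'   (`data.frame`: `read_id`, `individual_id`, `isoform` in
#'   `{"inclusion", "skip"}`).
#' @export
simulate_spliced_reads <- function(cfg, locus, eoi_index,
                                   dir = tempfile("spliced"),
                                   individual_id = "sim1") {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  t <- locus$transcript
  g <- genomic_exon_index(t, eoi_index)
  .eoi_junctions(t, eoi_index)             # validates internal exon
  exons <- data.frame(start = GenomicRanges::start(t$exons),
                      end = GenomicRanges::end(t$exons))
  iso <- list(inclusion = exons, skip = exons[-g, , drop = FALSE])
  rl <- cfg$read_length
  s <- cfg$splicing$skip_fraction
  starts_avail <- vapply(iso, function(e)
    sum(e$end - e$start + 1L) - rl + 1L, numeric(1L))
  if (any(starts_avail < 1))
    stop("read_length ", rl, " exceeds the skip-isoform length")
  w <- c(inclusion = (1 - s) * starts_avail[["inclusion"]],
         skip = s * starts_avail[["skip"]])
  n <- cfg$splicing$n_fragments
  from_skip <- stats::runif(n) < w[["skip"]] / sum(w)

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    e <- if (from_skip[i]) iso$skip else iso$inclusion
    tstart <- sample.int(sum(e$end - e$start + 1L) - rl + 1L, 1L)
    ali <- .tx_to_genomic(e, tstart, rl)
    sq <- paste(vapply(seq_len(nrow(ali$blocks)), function(b)
      substr(locus$seq, ali$blocks[b, 1L], ali$blocks[b, 2L]),
      character(1L)), collapse = "")
    recs[[i]] <- data.frame(
      qname = sprintf("%s_frag%05d", individual_id, i), flag = 0L,
      rname = locus$chrom, pos = ali$blocks[1L, 1L], cigar = ali$cigar,
      seq = sq, stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  sam <- file.path(dir, paste0(individual_id, "_spliced.sam"))
  .write_sam(recs, locus$chrom, nchar(locus$seq), sam)
  truth_df <- data.frame(read_id = recs$qname, individual_id = individual_id,
                         isoform = ifelse(from_skip, "skip", "inclusion"),
                         stringsAsFactors = FALSE)
  truth_tsv <- file.path(dir, paste0(individual_id, "_spliced_truth.tsv"))
  utils::write.table(truth_df, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(sam = sam, truth_tsv = truth_tsv, truth = truth_df)
}

## Map a read of length rl starting at transcript coordinate tstart onto
## the genome through the given exon blocks (genomic order, + strand).
## Returns genomic aligned blocks and the M/N CIGAR.
.tx_to_genomic <- function(exons, tstart, rl) {
  widths <- exons$end - exons$start + 1L
  offs <- cumsum(c(0L, widths))[seq_len(nrow(exons))]  # tx offset of exon starts
  qs <- tstart; qe <- tstart + rl - 1L
  blocks <- NULL
  for (j in seq_len(nrow(exons))) {
    es <- offs[j] + 1L; ee <- offs[j] + widths[j]      # exon in tx coords
    os <- max(qs, es); oe <- min(qe, ee)
    if (os > oe) next
    gs <- exons$start[j] + (os - es)
    ge <- exons$start[j] + (oe - es)
    blocks <- rbind(blocks, c(gs, ge))
  }
  cig <- character()
  for (b in seq_len(nrow(blocks))) {
    if (b > 1L)
      cig <- c(cig, sprintf("%dN", blocks[b, 1L] - blocks[b - 1L, 2L] - 1L))
    cig <- c(cig, sprintf("%dM", blocks[b, 2L] - blocks[b, 1L] + 1L))
  }
  list(blocks = blocks, cigar = paste(cig, collapse = ""))
}

## Minimal SAM text writer for simulator output.
.write_sam <- function(recs, chrom, reflen, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, reflen)), con)
  if (nrow(recs))
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                       recs$qname, recs$flag, recs$rname, recs$pos,
                       recs$cigar, recs$seq,
                       strrep("I", nchar(recs$seq))), con)
  invisible(path)
}

#' Write simulated reads to FASTQ
#'
#' Convenience emitter for end-to-end tests with an external aligner:
#' re-exports the sequences of a (simulated) SAM file as FASTQ with
#' uniform base qualities.
#'
#' @param sam_path SAM/BAM file.
#' @param fastq_path output FASTQ path.
#' @return `fastq_path`, invisibly.
#' @export
sam_to_fastq <- function(sam_path, fastq_path) {
  reads <- read_alignments(sam_path)
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                             "+", strrep("I", nchar(reads$seq)))),
             fastq_path)
  invisible(fastq_path)
}
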