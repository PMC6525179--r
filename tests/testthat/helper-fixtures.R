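# Shared fixtures and independent oracles. The oracles deliberately avoid
# every code path of the package: they expand alignments base by base and
# build splice windows as explicit coordinate sets.

# --- toy transcripts -------------------------------------------------------

# 3-exon plus-strand toy: exons 1-100, 201-300, 401-500 (1-based closed)
toy3_exons <- function() data.frame(start = c(1L, 201L, 401L),
                                    end = c(100L, 300L, 500L))

toy3_tx <- function(strand = "+", cds = toy3_exons())
  transcript_model("tx3", "g3", "chrT", strand, toy3_exons(), cds)

toy3_gff3 <- function(path = tempfile(fileext = ".gff3"), strand = "+") {
  write_gene_model(toy3_tx(strand), path)
  path
}

spliced_read <- function(pos, cigar, read_id = "r1")
  data.frame(read_id = read_id, flag = 0L, chrom = "chrT", pos = pos,
             cigar = cigar, seq = NA, individual_id = "F01",
             stringsAsFactors = FALSE)

# write a SAM file from a record data.frame (qname/flag/pos/cigar/seq)
write_sam_fixture <- function(recs, path = tempfile(fileext = ".sam"),
                              chrom = "chrT", reflen = 5000L) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, reflen))
  if (!is.null(recs) && nrow(recs)) {
    seq <- if (is.null(recs$seq)) strrep("A", 10L) else recs$seq
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                              recs$qname,
                              if (is.null(recs$flag)) 0L else recs$flag,
                              chrom, recs$pos, recs$cigar, seq,
                              strrep("I", nchar(seq))))
  }
  writeLines(lines, path)
  path
}

# --- brute-force alignment-walk oracle for indel extraction ----------------

# Expands the CIGAR one base at a time into alignment columns, then reads
# indels off the columns: a deletion is a maximal run of reference-only
# columns (op D), an insertion a maximal run of query-only columns, each
# anchored at the last reference base laid down before the run.
oracle_indels <- function(pos, cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSH=X]", cigar))[[1L]]
  ref <- pos
  cols <- data.frame(op = character(), ref = integer())
  for (tk in toks) {
    n <- as.integer(sub("[A-Z=]$", "", tk))
    op <- sub("^[0-9]+", "", tk)
    for (k in seq_len(n)) {
      if (op %in% c("M", "=", "X", "D", "N")) {
        cols <- rbind(cols, data.frame(op = op, ref = ref)); ref <- ref + 1L
      } else if (op == "I") {
        cols <- rbind(cols, data.frame(op = "I", ref = NA_integer_))
      }
      # S and H columns lie outside the alignment
    }
  }
  out <- data.frame(pos = integer(), kind = character(), length = integer())
  i <- 1L
  while (i <= nrow(cols)) {
    if (cols$op[i] %in% c("D", "I")) {
      j <- i
      while (j < nrow(cols) && cols$op[j + 1L] == cols$op[i]) j <- j + 1L
      anchor <- if (cols$op[i] == "D") cols$ref[i] - 1L
                else {
                  prev <- cols$ref[seq_len(i - 1L)]
                  prev <- prev[!is.na(prev)]
                  if (length(prev)) max(prev) + 1L - 1L else pos - 1L
                }
      out <- rbind(out, data.frame(
        pos = anchor, kind = if (cols$op[i] == "D") "del" else "ins",
        length = j - i + 1L))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# random but structurally valid CIGAR: M blocks interleaved with indels
random_cigar_read <- function(max_indels = 3L) {
  n_ind <- sample(0:max_indels, 1L)
  cig <- sprintf("%dM", sample(5:20, 1L))
  for (k in seq_len(n_ind)) {
    op <- sample(c("I", "D"), 1L)
    cig <- paste0(cig, sprintf("%d%s%dM", sample(1:5, 1L), op,
                               sample(5:20, 1L)))
  }
  list(pos = sample(1:500, 1L), cigar = cig)
}

# --- direct-rule oracle for consequence classification ---------------------

# Classifies a deletion [ds, de] (or insertion anchored at ds, de = NA)
# against plain exon/CDS tables by materialising every coordinate set the
# rule text mentions. Plus strand only (matches the toy fixtures).
oracle_classify <- function(exons, cds, ds, de = NA, ins_len = NA,
                            intronic = 8L, exonic = 3L) {
  ib <- max(intronic, 2L)
  windows <- integer()
  for (j in seq_len(nrow(exons) - 1L)) {
    ee <- exons$end[j]; ns <- exons$start[j + 1L]
    windows <- c(windows,
                 (ee + 1L):(ee + ib),                 # donor intronic
                 (ee - exonic + 1L):ee,               # donor exonic
                 (ns - ib):(ns - 1L),                 # acceptor intronic
                 ns:(ns + exonic - 1L))               # acceptor exonic
  }
  cds_pos <- unlist(mapply(seq, cds$start, cds$end, SIMPLIFY = FALSE))
  if (is.na(de)) {                                    # insertion
    in_window <- ds %in% windows
    net <- if (ds %in% cds_pos) ins_len else 0L
    frac <- 0
  } else {
    in_window <- any(ds:de %in% windows)
    net <- -sum(ds:de %in% cds_pos)
    frac <- sum(ds:de %in% cds_pos) / length(cds_pos)
  }
  if (in_window) "SS"
  else if (abs(net) %% 3L != 0L || frac > 0.5) "LOF"
  else "IF"
}
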