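mkread <- function(pos, cigar, read_id = "r1", chrom = "chrT", seq = NA,
                   individual_id = "F01", flag = 0L)
  data.frame(read_id = read_id, flag = flag, chrom = chrom, pos = pos,
             cigar = cigar, seq = seq, individual_id = individual_id,
             stringsAsFactors = FALSE)

test_that("CIGAR walk anchors indels by cumulative reference consumption", {
  del <- parse_cigar_indels(mkread(101L, "10M2D15M"))
  expect_equal(nrow(del), 1L)
  expect_equal(del$kind, "del")
  expect_equal(del$length, 2L)
  expect_equal(del$pos, 110L)            # deleted bases are 111-112

  ins <- parse_cigar_indels(mkread(51L, "5M3I20M",
                                   seq = strrep("ACGTACGT", 4L)))
  expect_equal(ins$kind, "ins")
  expect_equal(ins$pos, 55L)
  expect_equal(ins$length, 3L)
  expect_equal(nchar(ins$inserted_seq), 3L)

  expect_equal(nrow(parse_cigar_indels(mkread(1L, "25M"))), 0L)
  # N is a spliced intron, never an indel call
  expect_equal(nrow(parse_cigar_indels(mkread(1L, "10M500N10M"))), 0L)
})

test_that("malformed CIGAR tokens are rejected by name", {
  expect_error(parse_cigar_indels(mkread(1L, "10M2Q5M")), "malformed CIGAR")
  expect_error(parse_cigar_indels(mkread(1L, "10M17")), "malformed CIGAR")
})

test_that("parse_cigar_indels matches the brute-force alignment-walk oracle", {
  set.seed(424L)
  for (i in 1:200) {
    r <- random_cigar_read()
    got <- parse_cigar_indels(mkread(r$pos, r$cigar))
    want <- oracle_indels(r$pos, r$cigar)
    expect_equal(nrow(got), nrow(want), info = r$cigar)
    if (nrow(want)) {
      expect_equal(got$pos, want$pos, info = r$cigar)
      expect_equal(got$kind, want$kind, info = r$cigar)
      expect_equal(got$length, want$length, info = r$cigar)
    }
  }
})

test_that("reference consumption from the CIGAR equals the aligned span", {
  set.seed(77L)
  for (i in 1:50) {
    r <- random_cigar_read()
    sp <- spliceko:::alignment_span(mkread(r$pos, r$cigar))
    toks <- regmatches(r$cigar, gregexpr("[0-9]+[A-Z]", r$cigar))[[1L]]
    ref_ops <- grepl("[MDN=X]$", toks)
    expect_equal(sp$end - sp$start + 1L,
                 sum(as.integer(sub("[A-Z]$", "", toks))[ref_ops]))
  }
})

test_that("only indels overlapping the target window are called", {
  site <- target_site("T1", "chrT", 100L, 120L)
  inside <- mkread(80L, "25M2D40M")          # deletion at 105-106
  faraway <- mkread(500L, "25M2D40M", read_id = "r2")
  expect_equal(nrow(call_indels_at_site(inside, site, min_flank = 5L)), 1L)
  expect_equal(nrow(call_indels_at_site(faraway, site, min_flank = 5L)), 0L)
})

test_that("reads not spanning window plus flank are ungenotypable", {
  site <- target_site("T1", "chrT", 100L, 120L)
  ends_inside <- mkread(80L, "30M")                 # ends at 109
  clipped <- mkread(80L, "30M40S", read_id = "r2")  # soft-clip doesn't span
  spanning <- mkread(80L, "60M", read_id = "r3")    # 80-139 covers 95-125
  reads <- rbind(ends_inside, clipped, spanning)
  geno <- genotypable_reads(reads, site, min_flank = 5L)
  expect_equal(geno$read_id, "r3")
  # the clipped read must appear in neither WT nor mutant tallies
  tal <- tally_alleles(call_indels_at_site(reads, site), geno, "F01", site)
  expect_equal(tal$n_reads_total, 1L)
})

test_that("secondary/supplementary/unmapped records never vote", {
  site <- target_site("T1", "chrT", 100L, 120L)
  reads <- rbind(mkread(80L, "60M", read_id = "p", flag = 0L),
                 mkread(80L, "60M", read_id = "s", flag = 256L),
                 mkread(80L, "60M", read_id = "u", flag = 4L),
                 mkread(80L, "60M", read_id = "sup", flag = 2048L))
  expect_equal(genotypable_reads(reads, site)$read_id, "p")
})

test_that("allele tallies count WT reads and collapse identical alleles", {
  site <- target_site("T2", "chrT", 100L, 120L)
  reads <- do.call(rbind, lapply(1:8, function(i)
    mkread(80L, if (i <= 5L) "25M2D40M" else "60M",
           read_id = sprintf("c%d", i))))
  geno <- genotypable_reads(reads, site)
  calls <- call_indels_at_site(reads, site)
  tal <- tally_alleles(calls, geno, "F01", site)
  expect_equal(tal$n_reads_total, 8L)
  expect_equal(tal$n_reads_wt, 3L)
  expect_equal(tal$mutant_fraction, 0.625)
  expect_equal(sum(tal$allele_table), 8L)
  expect_equal(unname(tal$allele_table[names(tal$allele_table) != "WT"]), 5L)

  # all WT
  wt <- do.call(rbind, lapply(1:8, function(i)
    mkread(80L, "60M", read_id = sprintf("w%d", i))))
  tal_wt <- tally_alleles(call_indels_at_site(wt, site),
                          genotypable_reads(wt, site), "F02", site)
  expect_equal(tal_wt$mutant_fraction, 0)

  # two distinct mutant alleles, no WT
  mixed <- do.call(rbind, lapply(1:8, function(i)
    mkread(80L, if (i <= 4L) "25M2D40M" else "25M1I40M",
           read_id = sprintf("m%d", i), seq = strrep("A", 66L))))
  tal_mx <- tally_alleles(call_indels_at_site(mixed, site),
                          genotypable_reads(mixed, site), "F03", site)
  expect_equal(tal_mx$mutant_fraction, 1)
  expect_equal(sum(names(tal_mx$allele_table) != "WT"), 2L)
})

test_that("zero genotypable reads yield a flagged NA mutant fraction", {
  site <- target_site("T1", "chrT", 100L, 120L)
  none <- mkread(1L, "10M")[0, ]
  tal <- tally_alleles(call_indels_at_site(none, site), none, "F00", site)
  expect_equal(tal$n_reads_total, 0L)
  expect_true(is.na(tal$mutant_fraction))
  expect_true(tal$no_reads)
})

test_that("mutant fraction is invariant under read order permutation", {
  site <- target_site("T1", "chrT", 100L, 120L)
  reads <- do.call(rbind, lapply(1:10, function(i)
    mkread(80L, if (i %% 3L == 0L) "25M2D40M" else "60M",
           read_id = sprintf("c%d", i))))
  set.seed(5L)
  perm <- reads[sample(nrow(reads)), ]
  f <- function(r) tally_alleles(call_indels_at_site(r, site),
                                 genotypable_reads(r, site),
                                 "F", site)$mutant_fraction
  expect_equal(f(reads), f(perm))
})

test_that("left normalisation shifts indels to their leftmost equivalent", {
  #        1234567890123
  ref <- "ACGTTTTTGCAAC"
  # deleting any single T of the 4-8 homopolymer is the same allele; all
  # raw anchors must normalise to 3, the base before the leftmost T
  for (anchor in 4:7) {
    calls <- data.frame(chrom = "chrT", pos = anchor, kind = "del",
                        length = 1L, inserted_seq = NA_character_,
                        read_id = "r", individual_id = "F")
    expect_equal(left_normalize_indels(calls, ref)$pos, 3L)
  }
  # insertion of "T" anywhere inside the run also shifts to anchor 3
  ins <- data.frame(chrom = "chrT", pos = 7L, kind = "ins", length = 1L,
                    inserted_seq = "T", read_id = "r", individual_id = "F")
  expect_equal(left_normalize_indels(ins, ref)$pos, 3L)
  # a deletion not in a repeat stays put
  fix <- data.frame(chrom = "chrT", pos = 9L, kind = "del", length = 1L,
                    inserted_seq = NA_character_, read_id = "r",
                    individual_id = "F")
  expect_equal(left_normalize_indels(fix, ref)$pos, 9L)
})

test_that("VCF output spells REF/ALT from the reference, deduplicated", {
  #        123456789012
  ref <- "ACGTAGGCATTC"
  calls <- data.frame(chrom = "chrT", pos = c(4L, 4L, 7L),
                      kind = c("del", "del", "ins"),
                      length = c(2L, 2L, 3L),
                      inserted_seq = c(NA, NA, "TTG"),
                      read_id = c("r1", "r2", "r3"), individual_id = "F",
                      stringsAsFactors = FALSE)
  vcf <- tempfile(fileext = ".vcf")
  write_indel_vcf(calls, ref, vcf)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2L)    # duplicate deletion collapsed
  expect_equal(body[1L], "chrT\t4\t.\tTAG\tT\t.\t.\t.")
  expect_equal(body[2L], "chrT\t7\t.\tG\tGTTG\t.\t.\t.")
})

test_that("SAM files round-trip through the alignment reader", {
  recs <- data.frame(qname = c("a", "b"), flag = 0L, pos = c(10L, 20L),
                     cigar = c("10M", "5M2D5M"),
                     seq = c(strrep("A", 10L), strrep("C", 10L)))
  sam <- write_sam_fixture(recs)
  reads <- read_alignments(sam, "ind1")
  expect_equal(reads$read_id, c("a", "b"))
  expect_equal(reads$pos, c(10L, 20L))
  expect_equal(reads$cigar, c("10M", "5M2D5M"))
  expect_equal(unique(reads$individual_id), "ind1")
})
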