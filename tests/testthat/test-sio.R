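test_that("alignment TSV dialect round-trips byte-identically", {
  reads <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(159L, 0L, 500L),
    end = c(180L, 24L, 521L),
    strand = c("+", "-", "+"),
    sample_id = c("s1", "s1", "s2"),
    stringsAsFactors = FALSE
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_alignments(reads, f)
  got <- read_alignments(f, "tsv")
  expect_equal(got$chrom, reads$chrom)
  expect_equal(got$length, c(21L, 24L, 21L))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_alignments(got, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("alignment parsing enforces invariants with line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstrand\tsample_id",
               "chr1\t200\t190\t+\ts1"), f)
  expect_error(read_alignments(f, "tsv"), "line 2")

  writeLines(c("chrom\tstart\tend\tstrand\tsample_id",
               "chr1\t100\t121\t*\ts1"), f)
  expect_error(read_alignments(f, "tsv"), "strand")

  writeLines("chrom\tstart\tend\tstrand\tsample_id", f)
  expect_equal(nrow(read_alignments(f, "tsv")), 0L)

  file.create(f2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_equal(nrow(read_alignments(f2, "tsv")), 0L)
})

test_that("BAM dialect is an adapter over the same record type", {
  skip_if_not_installed("Rsamtools")
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    paste("r1", 0, "chr1", 160, 255, "21M", "*", 0, 0,
          paste(rep("A", 21), collapse = ""), "*", sep = "\t"),
    paste("r2", 16, "chr1", 301, 255, "22M", "*", 0, 0,
          paste(rep("A", 22), collapse = ""), "*", sep = "\t")
  ), sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  got <- read_alignments(bam, "bam", sample_id = "s1")
  expect_equal(got$start, c(159L, 300L))
  expect_equal(got$end, c(180L, 322L))
  expect_equal(got$strand, c("+", "-"))
  expect_equal(got$length, c(21L, 22L))
})

test_that("GFF3 conversion is 1-based closed to 0-based half-open", {
  ann <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
    start = c(100L, 300L), end = c(200L, 350L), stringsAsFactors = FALSE
  )
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, f, chrom_lengths = c(chr1 = 1000L))
  got <- read_gff(f)
  expect_equal(got$start, c(100L, 300L))
  expect_equal(got$end, c(200L, 350L))
  # disk representation is 1-based closed: 101..200
  expect_match(readLines(f)[3L], "\t101\t200\t")

  # 1 nt feature start = end = k maps to [k-1, k)
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t7\t7\t.\t+\t.\tID=g1"), f)
  one <- read_gff(f)
  expect_equal(one$start, 6L)
  expect_equal(one$end, 7L)

  # empty annotation
  writeLines("##gff-version 3", f)
  expect_equal(nrow(read_gff(f)), 0L)

  # duplicate ids rejected
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t10\t20\t.\t+\t.\tID=g1",
               "chr1\tx\tgene\t30\t40\t.\t+\t.\tID=g1"), f)
  expect_error(read_gff(f), "duplicate")

  # outside declared sequence-region: warning, record kept
  writeLines(c("##gff-version 3",
               "##sequence-region chr1 1 100",
               "chr1\tx\tgene\t90\t120\t.\t+\t.\tID=g1"), f)
  expect_warning(kept <- read_gff(f), "sequence-region")
  expect_equal(nrow(kept), 1L)
})

test_that("target sites attach RNA-normalized miRNA sequences", {
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(miR1 = "TGATTGAGCCGCGCCAATATC"), fa)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tmirna_name\tstart\tend\tn_sites",
               "t1\tmiR1\t101\t121\t1"), tsv)
  sites <- read_target_sites(tsv, fa)
  expect_equal(sites$mirna_seq, "UGAUUGAGCCGCGCCAAUAUC")
  expect_equal(sites$start, 100L)  # converted to 0-based half-open
  expect_equal(sites$end, 121L)

  writeLines(c("transcript_id\tmirna_name\tstart\tend\tn_sites",
               "t1\tmiRabsent\t101\t121\t1"), tsv)
  expect_error(read_target_sites(tsv, fa), "miRabsent")

  # invariant: site length within [18, 26]
  writeLines(c("transcript_id\tmirna_name\tstart\tend\tn_sites",
               "t1\tmiR1\t101\t110\t1"), tsv)
  expect_error(read_target_sites(tsv, fa), "site length")
})

test_that("RNA alphabet helpers reject junk and invert cleanly", {
  expect_equal(as_rna("acgt"), "ACGU")
  expect_error(as_rna("ACGX"), "non-RNA")
  expect_equal(transitr:::rna_revcomp("AUGC"), "GCAU")
  expect_equal(transitr:::dna_revcomp("ATGC"), "GCAT")
})
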