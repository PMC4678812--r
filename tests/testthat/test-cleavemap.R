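test_that("cleavage coordinate follows slicer geometry", {
  # 21-nt miRNA fully paired at transcript 1-based 101..121:
  # cut between 111 and 112, c = 111 (0-based)
  site <- list(transcript_id = "t1", mirna_name = "miR1",
               start = 100L, end = 121L)
  cs <- derive_cleavage_site(site)
  expect_equal(cs$cleavage, 111L)

  # a 22-nt miRNA with a 3' overhang leaves c unchanged (the convention
  # hangs off the site's 3' end pairing miRNA position 1)
  expect_equal(derive_cleavage_site(site)$cleavage, 111L)

  # sites too short to span the cut are rejected
  expect_error(derive_cleavage_site(list(start = 100L, end = 110L)),
               "shorter than 11")
})

prof_reads <- function(tpos, gene, sizes = 21L, strand = "+",
                       sample_id = "s1") {
  n <- length(tpos)
  sizes <- rep_len(sizes, n)
  strand <- rep_len(strand, n)
  gpos <- if (gene$strand == "+") gene$start + tpos else gene$end - 1L - tpos
  start <- ifelse(strand == "+", gpos, gpos - sizes + 1L)
  r <- data.frame(chrom = rep_len(gene$chrom, n), start = as.integer(start),
                  end = as.integer(start + sizes), strand = strand,
                  sample_id = rep_len(sample_id, n), stringsAsFactors = FALSE)
  r$length <- r$end - r$start
  class(r) <- c("aligned_reads", "data.frame")
  r
}

test_that("profiles count 5' ends around the cleavage site", {
  gene <- list(gene_id = "g1", chrom = "chr1", strand = "+",
               start = 1000L, end = 3000L)
  site <- list(transcript_id = "g1", mirna_name = "miR1",
               start = 990L, end = 1011L)  # transcript coords, c = 1001
  # no reads: all-zero profile
  p0 <- build_profile(prof_reads(integer(), gene), gene, site)
  expect_equal(p0$n5 + p0$n3, 0L)

  # 95 reads 5' of c, 5 at/after c
  tpos <- c(rep(950L, 95), rep(1001L, 5))
  p <- build_profile(prof_reads(tpos, gene), gene, site)
  expect_equal(p$n5, 95L)
  expect_equal(p$n3, 5L)

  # boundary rule: 5' end exactly at c belongs to the 3' side
  pb <- build_profile(prof_reads(1001L, gene), gene, site)
  expect_equal(pb$n3, 1L)
  expect_equal(pb$n5, 0L)

  # reads outside the flank are ignored
  pf <- build_profile(prof_reads(c(400L, 950L), gene), gene, site,
                      flank = 100L)
  expect_equal(pf$n5 + pf$n3, 1L)

  # minus-strand genes profile in transcript orientation
  gm <- list(gene_id = "g2", chrom = "chr1", strand = "-",
             start = 1000L, end = 3000L)
  pm <- build_profile(prof_reads(c(900L, 1500L), gm), gm, site)
  expect_equal(pm$n5, 1L)
  expect_equal(pm$n3, 1L)

  expect_error(
    build_profile(prof_reads(950L, gene), gene,
                  list(transcript_id = "g1", mirna_name = "m",
                       start = 1500L, end = 1521L), flank = 100L),
    NA
  )
  # cleavage coordinate beyond the transcript end is rejected
  expect_error(
    build_profile(prof_reads(950L, gene), gene,
                  list(transcript_id = "g1", mirna_name = "m",
                       start = 1995L, end = 2016L)),
    "outside transcript"
  )
})

test_that("direction classification applies thresholds and mirrors", {
  call_of <- function(n5, n3, ...) {
    classify_direction(list(n5 = n5, n3 = n3), ...)$call
  }
  expect_equal(call_of(95, 5), "five_prime")
  expect_equal(call_of(4, 5), "none")          # below min_reads
  # exactly min_reads reads is enough to classify (strict "<" rule)
  expect_equal(call_of(5, 5), "bidirectional")
  expect_equal(call_of(50, 50), "bidirectional")
  expect_equal(call_of(5, 95), "three_prime")
  expect_equal(classify_direction(list(n5 = 95, n3 = 5))$f, 0.95)

  # mirror symmetry: swapping sides maps five_prime <-> three_prime with
  # the same exclusivity fraction
  a <- classify_direction(list(n5 = 91, n3 = 9))
  b <- classify_direction(list(n5 = 9, n3 = 91))
  expect_equal(a$call, "five_prime")
  expect_equal(b$call, "three_prime")
  expect_equal(a$f, b$f)
})

test_that("per-10-million normalization never changes a call", {
  gene <- list(gene_id = "g1", chrom = "chr1", strand = "+",
               start = 1000L, end = 3000L)
  site <- list(transcript_id = "g1", mirna_name = "miR1",
               start = 990L, end = 1011L)
  tpos <- c(rep(950L, 40), rep(1010L, 3))
  p1 <- build_profile(prof_reads(tpos, gene), gene, site)
  p2 <- build_profile(prof_reads(tpos, gene), gene, site,
                      library_size = 12345678)
  expect_equal(classify_direction(p1)$call, classify_direction(p2)$call)
  expect_true(all(is.na(p1$profile$per10M)))
  expect_equal(sum(p2$profile$per10M * 12345678 / 1e7), sum(p2$profile$count))
})

test_that("planted direction is recovered on simulated loci", {
  cfg <- tiny_sim(seed = 21L, signal_mean = 120)
  ref <- simulate_reference(cfg)
  rd <- simulate_reads(ref, cfg)
  case <- rd$reads[grepl("^ski2_RDR6", rd$reads$sample_id), , drop = FALSE]
  want_map <- c("5p" = "five_prime", "3p" = "three_prime",
                both = "bidirectional")
  ok <- 0L
  for (i in seq_len(nrow(ref$truth))) {
    tr <- ref$truth[i, ]
    g <- ref$annotation[ref$annotation$gene_id == tr$gene_id, ]
    s <- ref$target_sites[ref$target_sites$transcript_id == tr$gene_id, ][1, ]
    dc <- classify_direction(build_profile(case, g, s))
    ok <- ok + (dc$call == want_map[[tr$direction]])
  }
  expect_gte(ok / nrow(ref$truth), 0.95)
})
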