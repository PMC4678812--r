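test_that("simulation is deterministic under a fixed seed", {
  cfg <- tiny_sim(seed = 3L)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1, r2)
  d1 <- simulate_reads(r1, cfg)
  d2 <- simulate_reads(r2, cfg)
  expect_identical(d1$reads, d2$reads)

  # byte-identical files too
  t1 <- withr::local_tempdir()
  t2 <- withr::local_tempdir()
  p1 <- write_simulation(r1, d1, t1)
  p2 <- write_simulation(r2, d2, t2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), label = nm)
  }

  # a different seed changes the world
  r3 <- simulate_reference(tiny_sim(seed = 4L))
  expect_false(identical(r1$genome, r3$genome))
})

test_that("reference construction honours its contracts", {
  cfg <- tiny_sim(seed = 5L)
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$annotation), cfg$n_genes)
  expect_equal(nrow(ref$target_sites), cfg$n_targets * cfg$sites_per_gene)

  # planted site sequence is the reverse complement of its miRNA
  for (i in seq_len(nrow(ref$target_sites))) {
    s <- ref$target_sites[i, ]
    g <- ref$annotation[ref$annotation$gene_id == s$transcript_id, ]
    tx <- transitr:::gene_transcript_seq(ref$genome[[g$chrom]], g)
    expect_equal(as_rna(substr(tx, s$start + 1L, s$end)),
                 transitr:::rna_revcomp(s$mirna_seq))
  }

  # truth loci always lie inside their annotated gene
  for (i in seq_len(nrow(ref$truth))) {
    tr <- ref$truth[i, ]
    g <- ref$annotation[ref$annotation$gene_id == tr$gene_id, ]
    expect_true(tr$cleavage_genomic >= g$start && tr$cleavage_genomic < g$end)
  }

  # zero targets: empty sites, nonempty annotation
  ref0 <- simulate_reference(tiny_sim(seed = 5L, n_targets = 0L))
  expect_equal(nrow(ref0$target_sites), 0L)
  expect_gt(nrow(ref0$annotation), 0L)

  # over-stuffed genomes are rejected
  expect_error(
    simulate_reference(sim_config(n_chrom = 1L, chrom_len = 10000L,
                                  n_genes = 50L)),
    "capacity"
  )
})

test_that("read simulation respects direction, sizes and bookkeeping", {
  # pure planted signal (no background/ballast) so every read is labeled
  cfg <- tiny_sim(seed = 6L, bg_mean = 0, ballast_loci = 0L,
                  signal_mean = 600,
                  direction_probs = c("5p" = 1, "3p" = 0, both = 0))
  ref <- simulate_reference(cfg)
  rd <- simulate_reads(ref, cfg)

  # library-size bookkeeping: totals equal emitted records
  expect_equal(sum(rd$library_sizes), nrow(rd$reads))
  expect_equal(unname(rd$library_sizes),
               as.integer(table(factor(rd$reads$sample_id,
                                       levels = rd$samples))[rd$samples]))

  # rdr6_dependence = 1: planted signal absent from rdr6 genotypes
  expect_equal(sum(grepl("rdr6_r", rd$reads$sample_id)), 0L)

  # direction 5p: planted 5' ends strictly before the cleavage site
  case <- rd$reads[rd$reads$sample_id == "ski2_RDR6_r1", , drop = FALSE]
  frac5 <- vapply(seq_len(nrow(ref$truth)), function(i) {
    tr <- ref$truth[i, ]
    g <- ref$annotation[ref$annotation$gene_id == tr$gene_id, ]
    on_g <- case[case$chrom == g$chrom & case$start >= g$start &
                   case$end <= g$end, , drop = FALSE]
    tpos <- transitr:::genome_to_transcript(
      transitr:::read_five_prime(on_g), g)
    mean(tpos < tr$cleavage_tx)
  }, 0)
  expect_true(all(frac5 >= 0.99))

  # 21-mer fraction within binomial error of the configured 0.8
  n <- nrow(rd$reads)
  expect_gt(n, 5000)
  expect_lt(abs(mean(rd$reads$length == 21L) - 0.8), 0.02)

  # all records satisfy the alignment invariants
  expect_true(all(rd$reads$start >= 0L))
  expect_true(all(rd$reads$end > rd$reads$start))
  expect_true(all(rd$reads$length == rd$reads$end - rd$reads$start))
})

test_that("rdr6 genotypes keep background but lose dependent signal", {
  cfg <- tiny_sim(seed = 7L)
  ref <- simulate_reference(cfg)
  rd <- simulate_reads(ref, cfg)
  # background present in all eight samples
  expect_true(all(rd$library_sizes > 0))
  # planted excess visible in ski2_RDR6 vs ski2_rdr6 near cleavage sites
  near <- function(smp) {
    r <- rd$reads[rd$reads$sample_id == smp, , drop = FALSE]
    sum(vapply(seq_len(nrow(ref$truth)), function(i) {
      tr <- ref$truth[i, ]
      sum(r$chrom == tr$chrom &
            abs((r$start + r$end) / 2 - tr$cleavage_genomic) < 200)
    }, 0))
  }
  expect_gt(near("ski2_RDR6_r1"), 10 * max(1, near("ski2_rdr6_r1")))
})
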