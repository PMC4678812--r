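# Fully synthetic reference, small-RNA alignments and RACE clones with
# machine-readable ground truth.
#
# The generator emulates the stated experimental world: four genotypes
# (SKI2_RDR6, ski2_RDR6, SKI2_rdr6, ski2_rdr6) x two replicates; 19-26 nt
# reads with 21-nt dominance at transitive loci; low-abundance siRNA
# peaks immediately adjacent to planted cleavage sites with configurable
# 5'/3'/bidirectional spreading; negative-binomial replicate noise
# (var = mu + phi*mu^2, same parameterization as the differential test);
# a background of non-differential degradation reads; and RACE clones
# with configurable 3' trimming and U/A/C tailing.  Reads are emitted as
# alignments directly (alignment itself is out of scope).

GENOTYPES <- c("SKI2_RDR6", "ski2_RDR6", "SKI2_rdr6", "ski2_rdr6")

#' Simulation configuration
#'
#' Defaults state the emulated world: a desk-scale two-chromosome genome,
#' ~8-fold induction of planted transitive loci in ski2_RDR6 over wild
#' type with planted mean 100 reads, 80% 21-mers in planted peaks, peak
#' half-width 150 nt, fully RDR6-dependent signal, and NB replicate noise
#' with dispersion 0.2.
#'
#' @param seed integer; fixed seed implies byte-identical outputs.
#' @param n_chrom,chrom_len chromosomes and their common length (nt).
#' @param n_genes genes laid out non-overlapping across the genome.
#' @param gene_len_range min/max gene length (nt).
#' @param n_targets number of miRNA-targeted genes (planted transitive
#'   loci).
#' @param sites_per_gene target sites per targeted gene (PHO2-like
#'   multi-site genes use > 1).
#' @param mirna_len miRNA length (nt, default 21).
#' @param replicates replicates per genotype (>= 2).
#' @param bg_mean mean background degradation reads per gene per sample.
#' @param bg_phi NB dispersion of replicate noise.
#' @param ballast_loci,ballast_mean number of intergenic high-abundance
#'   small-RNA source loci (miRNA/hc-siRNA-like) and their mean reads per
#'   sample.  They are non-differential and exist so that libraries are
#'   dominated — as real small-RNA libraries are — by reads unrelated to
#'   transitive loci, keeping planted signal a small library fraction.
#' @param signal_mean mean planted read count per locus in ski2_RDR6.
#' @param fold_change induction of planted signal in ski2_RDR6 vs wild
#'   type (>= 1).
#' @param peak_halfwidth planted 5' ends fall within this many nt of the
#'   cleavage site (default 150).
#' @param frac21 fraction of 21-mers among planted reads (default 0.8).
#' @param size_min,size_max read-size range (default 19-26).
#' @param direction_probs probabilities of planting a locus with 5', 3' or
#'   bidirectional spreading (named `5p`, `3p`, `both`).
#' @param rdr6_dependence fraction of planted signal removed in rdr6
#'   genotypes (default 1 = fully RDR6-dependent).
#' @param mismatch_5p,mismatch_3p mismatches injected into the site region
#'   pairing the corresponding miRNA half (for duplex tests; default 0 =
#'   perfect reverse-complement sites).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_len = 150000L,
                       n_genes = 120L, gene_len_range = c(1400L, 2400L),
                       n_targets = 30L, sites_per_gene = 1L,
                       mirna_len = 21L,
                       replicates = 2L,
                       bg_mean = 5, bg_phi = 0.2,
                       ballast_loci = 20L, ballast_mean = 1000,
                       signal_mean = 100, fold_change = 8,
                       peak_halfwidth = 150L, frac21 = 0.8,
                       size_min = 19L, size_max = 26L,
                       direction_probs = c("5p" = 0.7, "3p" = 0.2, both = 0.1),
                       rdr6_dependence = 1.0,
                       mismatch_5p = 0L, mismatch_3p = 0L) {
  stopifnot(replicates >= 2L, frac21 >= 0, frac21 <= 1,
            rdr6_dependence >= 0, rdr6_dependence <= 1,
            fold_change >= 1, all(direction_probs >= 0))
  direction_probs <- direction_probs / sum(direction_probs)
  structure(
    list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
         chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
         gene_len_range = as.integer(gene_len_range),
         n_targets = as.integer(n_targets),
         sites_per_gene = as.integer(sites_per_gene),
         mirna_len = as.integer(mirna_len),
         replicates = as.integer(replicates),
         bg_mean = bg_mean, bg_phi = bg_phi,
         ballast_loci = as.integer(ballast_loci),
         ballast_mean = ballast_mean,
         signal_mean = signal_mean, fold_change = fold_change,
         peak_halfwidth = as.integer(peak_halfwidth), frac21 = frac21,
         size_min = as.integer(size_min), size_max = as.integer(size_max),
         direction_probs = direction_probs,
         rdr6_dependence = rdr6_dependence,
         mismatch_5p = as.integer(mismatch_5p),
         mismatch_3p = as.integer(mismatch_3p)),
    class = "sim_config"
  )
}

rnb <- function(n, mean, phi) {
  if (phi <= 0) stats::rpois(n, mean) else rnbinom(n, size = 1 / phi, mu = mean)
}

sample_sizes <- function(n, config) {
  sizes <- seq.int(config$size_min, config$size_max)
  other <- setdiff(sizes, 21L)
  is21 <- runif(n) < config$frac21 & 21L %in% sizes
  out <- integer(n)
  out[is21] <- 21L
  n_other <- sum(!is21)
  if (n_other > 0L) {
    pool <- if (length(other)) other else sizes
    out[!is21] <- pool[sample.int(length(pool), n_other, replace = TRUE)]
  }
  out
}

#' Simulate the reference world
#'
#' Generates random-composition chromosomes, a non-overlapping gene
#' layout on both strands, miRNA-targeted genes whose site sequence is
#' the reverse complement of the miRNA (perfect pairing; configurable
#' mismatch injection per miRNA half), and the ground-truth table of
#' planted loci with genotype-wise expected mean counts.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_reference`: `genome` (named DNA character
#'   vector), `annotation` (`gene_annotation`), `target_sites`
#'   (`target_sites`, transcript coordinates), `mirnas` (named RNA
#'   character vector), `truth` (data.frame, one row per planted locus).
#' @export
simulate_reference <- function(config = sim_config()) {
  set.seed(stage_seed(config$seed, "reference"))
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  genome <- setNames(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_len, replace = TRUE),
          collapse = "")
  }, ""), chroms)

  # sequential layout with random inter-gene gaps
  genes <- list()
  gid <- 0L
  per_chrom <- ceiling(config$n_genes / config$n_chrom)
  for (ch in chroms) {
    pos <- 0L
    placed <- 0L
    while (placed < per_chrom && gid < config$n_genes) {
      gap <- sample.int(400L, 1L) + 100L
      len <- sample.int(diff(config$gene_len_range) + 1L, 1L) +
        config$gene_len_range[1L] - 1L
      if (pos + gap + len > config$chrom_len) break
      gid <- gid + 1L
      placed <- placed + 1L
      genes[[gid]] <- data.frame(
        gene_id = sprintf("g%04d", gid), chrom = ch,
        strand = sample(c("+", "-"), 1L),
        start = pos + gap, end = pos + gap + len,
        stringsAsFactors = FALSE
      )
      pos <- pos + gap + len
    }
  }
  if (gid < config$n_genes) {
    stop("genes requested exceed genome capacity (placed ", gid, " of ",
         config$n_genes, ")")
  }
  annotation <- do.call(rbind, genes)
  annotation <- annotation[order(annotation$chrom, annotation$start), ,
                           drop = FALSE]
  rownames(annotation) <- NULL
  class(annotation) <- c("gene_annotation", "data.frame")

  # targeted genes and their sites
  n_t <- config$n_targets
  sites <- list()
  mirnas <- character()
  truth <- list()
  if (n_t > 0L) {
    target_idx <- sort(sample.int(nrow(annotation), n_t))
    dirs <- names(config$direction_probs)[
      sample.int(length(config$direction_probs), n_t, replace = TRUE,
                 prob = config$direction_probs)]
    for (t in seq_len(n_t)) {
      g <- annotation[target_idx[t], ]
      tx_len <- g$end - g$start
      mir_name <- sprintf("miR%04d", t)
      mir <- paste(sample(c("A", "C", "G", "U"), config$mirna_len,
                          replace = TRUE), collapse = "")
      mirnas[mir_name] <- mir
      site_len <- config$mirna_len
      n_sites <- config$sites_per_gene
      # sites spaced every (site_len + 10) nt around the transcript middle
      span <- n_sites * (site_len + 10L)
      first <- as.integer(tx_len / 2 - span / 2)
      stopifnot(first > config$peak_halfwidth,
                first + span < tx_len - config$peak_halfwidth)
      for (s in seq_len(n_sites)) {
        s_start <- first + (s - 1L) * (site_len + 10L)
        s_end <- s_start + site_len
        site_rna <- rna_revcomp(mir)
        site_rna <- inject_mismatches(site_rna, mir, config)
        genome[[g$chrom]] <- write_site(genome[[g$chrom]], g, s_start, site_rna)
        c0 <- s_end - 10L
        sites[[length(sites) + 1L]] <- data.frame(
          transcript_id = g$gene_id, mirna_name = mir_name,
          start = s_start, end = s_end, n_sites = n_sites,
          mirna_seq = mir, stringsAsFactors = FALSE
        )
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
          mirna_name = mir_name,
          cleavage_tx = c0,
          cleavage_genomic = transcript_to_genome(c0, g),
          direction = dirs[t],
          mean_SKI2_RDR6 = config$signal_mean / config$fold_change,
          mean_ski2_RDR6 = config$signal_mean,
          mean_SKI2_rdr6 = config$signal_mean / config$fold_change *
            (1 - config$rdr6_dependence),
          mean_ski2_rdr6 = config$signal_mean * (1 - config$rdr6_dependence),
          is_mirna_target = TRUE, rdr6_dependent = config$rdr6_dependence > 0,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  target_sites <- if (length(sites)) {
    ts <- do.call(rbind, sites)
    class(ts) <- c("target_sites", "data.frame")
    ts
  } else {
    ts <- data.frame(transcript_id = character(), mirna_name = character(),
                     start = integer(), end = integer(), n_sites = integer(),
                     mirna_seq = character(), stringsAsFactors = FALSE)
    class(ts) <- c("target_sites", "data.frame")
    ts
  }
  truth <- if (length(truth)) do.call(rbind, truth) else NULL

  # intergenic high-abundance small-RNA source loci (library ballast)
  ballast <- NULL
  if (config$ballast_loci > 0L) {
    picks <- list()
    tries <- 0L
    while (length(picks) < config$ballast_loci && tries < 10000L) {
      tries <- tries + 1L
      ch <- chroms[sample.int(length(chroms), 1L)]
      pos <- sample.int(config$chrom_len - 30L, 1L) - 1L
      in_gene <- any(annotation$chrom == ch & annotation$start <= pos + 30L &
                       annotation$end > pos - 30L)
      if (!in_gene) {
        picks[[length(picks) + 1L]] <- data.frame(
          chrom = ch, pos = pos, stringsAsFactors = FALSE
        )
      }
    }
    if (length(picks) < config$ballast_loci) {
      stop("could not place ballast loci outside genes")
    }
    ballast <- do.call(rbind, picks)
  }
  structure(
    list(genome = genome, annotation = annotation,
         target_sites = target_sites, mirnas = mirnas, truth = truth,
         ballast = ballast, config = config),
    class = "sim_reference"
  )
}

# substitute `n` site positions within the region pairing one miRNA half
# with a non-complementary base
inject_mismatches <- function(site_rna, mir, config) {
  len <- nchar(site_rna)
  c_off <- len - 10L  # first nt of the 3'-fragment part
  mutate <- function(seq, positions) {
    v <- strsplit(seq, "")[[1L]]
    for (p in positions) {
      v[p] <- sample(setdiff(c("A", "C", "G", "U"), v[p]), 1L)
    }
    paste(v, collapse = "")
  }
  if (config$mismatch_5p > 0L) {
    pos <- sample(seq_len(c_off), min(config$mismatch_5p, c_off))
    site_rna <- mutate(site_rna, pos)
  }
  if (config$mismatch_3p > 0L) {
    pos <- sample((c_off + 1L):len, min(config$mismatch_3p, 10L))
    site_rna <- mutate(site_rna, pos)
  }
  site_rna
}

# overwrite the genomic sequence so that the gene's transcript carries
# `site_rna` at transcript interval [s_start, s_start + len)
write_site <- function(chrom_seq, gene, s_start, site_rna) {
  site_dna <- chartr("U", "T", site_rna)
  len <- nchar(site_dna)
  if (gene$strand == "+") {
    g0 <- gene$start + s_start
    piece <- site_dna
  } else {
    g0 <- gene$end - s_start - len
    piece <- dna_revcomp(site_dna)
  }
  paste0(substr(chrom_seq, 1L, g0),
         piece,
         substr(chrom_seq, g0 + len + 1L, nchar(chrom_seq)))
}

#' Simulate small-RNA alignments for all genotypes and replicates
#'
#' Background reads are NB(bg_mean, bg_phi) per gene per sample with
#' uniform positions, sizes and strands.  Planted transitive reads have
#' 5' ends within `peak_halfwidth` nt on the configured side(s) of the
#' cleavage coordinate, sizes drawn with the configured 21-mer fraction,
#' both strands; rdr6 genotypes carry the planted signal scaled by
#' `1 - rdr6_dependence`.
#'
#' @param reference a `sim_reference`.
#' @param config a [sim_config()] (defaults to the reference's own).
#' @return list of class `sim_reads`: `reads` (`aligned_reads` across all
#'   samples), `library_sizes` (records per sample), `samples`.
#' @export
simulate_reads <- function(reference, config = reference$config) {
  set.seed(stage_seed(config$seed, "reads"))
  ann <- reference$annotation
  truth <- reference$truth
  samples <- as.vector(outer(GENOTYPES, seq_len(config$replicates),
                             function(g, r) paste0(g, "_r", r)))
  out <- list()
  for (geno in GENOTYPES) {
    for (rep_i in seq_len(config$replicates)) {
      smp <- paste0(geno, "_r", rep_i)
      # background
      n_bg <- rnb(nrow(ann), config$bg_mean, config$bg_phi)
      if (sum(n_bg) > 0L) {
        gi <- rep(seq_len(nrow(ann)), n_bg)
        g <- ann[gi, , drop = FALSE]
        sizes <- sample(seq.int(config$size_min, config$size_max),
                        sum(n_bg), replace = TRUE)
        maxs <- g$end - g$start - sizes
        start <- g$start + floor(runif(sum(n_bg)) * pmax(1L, maxs))
        out[[length(out) + 1L]] <- data.frame(
          chrom = g$chrom, start = as.integer(start),
          end = as.integer(start + sizes),
          strand = sample(c("+", "-"), sum(n_bg), replace = TRUE),
          sample_id = smp, stringsAsFactors = FALSE
        )
      }
      # library ballast: abundant non-differential small-RNA sources
      if (!is.null(reference$ballast)) {
        bl <- reference$ballast
        n_bl <- rnb(nrow(bl), config$ballast_mean, config$bg_phi)
        if (sum(n_bl) > 0L) {
          li <- rep(seq_len(nrow(bl)), n_bl)
          jit <- sample.int(3L, sum(n_bl), replace = TRUE) - 1L
          start <- bl$pos[li] + jit
          out[[length(out) + 1L]] <- data.frame(
            chrom = bl$chrom[li], start = as.integer(start),
            end = as.integer(start + 21L),
            strand = "+", sample_id = smp, stringsAsFactors = FALSE
          )
        }
      }
      # planted transitive signal
      if (!is.null(truth)) {
        mu <- truth[[paste0("mean_", geno)]]
        n_sig <- rnb(nrow(truth), mu, config$bg_phi)
        for (li in which(n_sig > 0L)) {
          tr <- truth[li, ]
          g <- ann[ann$gene_id == tr$gene_id, ]
          n <- n_sig[li]
          side <- switch(tr$direction,
            "5p" = rep("5p", n),
            "3p" = rep("3p", n),
            both = sample(c("5p", "3p"), n, replace = TRUE)
          )
          off <- sample.int(config$peak_halfwidth, n, replace = TRUE)
          tpos <- ifelse(side == "5p", tr$cleavage_tx - off,
                         tr$cleavage_tx + off - 1L)
          sizes <- sample_sizes(n, config)
          gpos <- transcript_to_genome(tpos, g)  # genomic 5'-end
          strand <- sample(c("+", "-"), n, replace = TRUE)
          start <- ifelse(strand == "+", gpos, gpos - sizes + 1L)
          end <- start + sizes
          ok <- start >= 0L & end <= config$chrom_len
          if (any(ok)) {
            out[[length(out) + 1L]] <- data.frame(
              chrom = g$chrom, start = as.integer(start[ok]),
              end = as.integer(end[ok]), strand = strand[ok],
              sample_id = smp, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  reads <- if (length(out)) do.call(rbind, out) else empty_alignments()
  reads$length <- reads$end - reads$start
  rownames(reads) <- NULL
  class(reads) <- c("aligned_reads", "data.frame")
  lib <- table(factor(reads$sample_id, levels = samples))
  structure(
    list(reads = reads,
         library_sizes = setNames(as.integer(lib), samples),
         samples = samples),
    class = "sim_reads"
  )
}

#' Simulate 3'-RACE clones of a 5'-cleavage fragment
#'
#' Each clone is a (possibly 3'-trimmed) prefix of the fragment followed
#' by a sampled non-templated tail; the truth table records the exact
#' trim and tail of every clone.
#'
#' @param fragment_sequence the 5'-cleavage fragment (RNA or DNA).
#' @param n_clones number of clones.
#' @param trim_dist named probability vector over 3'-trim lengths (names
#'   are lengths; default no trimming).
#' @param tail_spectrum named probability vector over tail strings; the
#'   empty name "" is the untailed class.
#' @param seed integer seed.
#' @return list of class `sim_race`: `clones` (named RNA character
#'   vector), `truth` (data.frame id/trim/tail).
#' @export
simulate_race_clones <- function(fragment_sequence, n_clones,
                                 trim_dist = c("0" = 1),
                                 tail_spectrum = setNames(1, ""),
                                 seed = 1L) {
  frag <- as_rna(fragment_sequence)
  if (nchar(frag) == 0L) stop("empty fragment sequence")
  stopifnot(abs(sum(trim_dist) - 1) < 1e-9, abs(sum(tail_spectrum) - 1) < 1e-9)
  set.seed(stage_seed(seed, "race"))
  trims <- as.integer(names(trim_dist))[
    sample.int(length(trim_dist), n_clones, replace = TRUE, prob = trim_dist)]
  tails <- names(tail_spectrum)[
    sample.int(length(tail_spectrum), n_clones, replace = TRUE,
               prob = tail_spectrum)]
  body <- substr(rep(frag, n_clones), 1L, nchar(frag) - trims)
  clones <- setNames(paste0(body, tails),
                     sprintf("clone%04d", seq_len(n_clones)))
  structure(
    list(clones = clones,
         truth = data.frame(id = names(clones), trim = trims, tail = tails,
                            stringsAsFactors = FALSE)),
    class = "sim_race"
  )
}

#' Write a simulated dataset to disk
#'
#' Emits genome FASTA, GFF3 annotation (with sequence-region pragmas),
#' miRNA FASTA, target-site TSV, truth TSV, the alignment TSV dialect and
#' a library-size TSV.
#'
#' @param reference a `sim_reference`.
#' @param reads a `sim_reads` (optional).
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_simulation <- function(reference, reads = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "genes.gff3"),
    mirnas = file.path(dir, "mirnas.fa"),
    sites = file.path(dir, "target_sites.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fasta(reference$genome, paths[["genome"]])
  write_gff3(reference$annotation, paths[["annotation"]],
             chrom_lengths = setNames(nchar(reference$genome),
                                      names(reference$genome)))
  if (length(reference$mirnas)) {
    write_fasta(reference$mirnas, paths[["mirnas"]])
  }
  write_target_sites(reference$target_sites, paths[["sites"]])
  if (!is.null(reference$truth)) {
    write_tsv(reference$truth, paths[["truth"]])
  }
  if (!is.null(reads)) {
    paths[["reads"]] <- file.path(dir, "reads.tsv")
    write_alignments(reads$reads, paths[["reads"]])
    paths[["library_sizes"]] <- file.path(dir, "library_sizes.tsv")
    write_tsv(data.frame(sample_id = names(reads$library_sizes),
                         n_reads = reads$library_sizes,
                         stringsAsFactors = FALSE),
              paths[["library_sizes"]])
  }
  invisible(paths)
}
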