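# Cleavage-site derivation, cleavage-site-relative siRNA profiles, and
# spreading-direction classification.
#
# Slicer geometry: the site's 3'-most nucleotide pairs miRNA position 1
# (antiparallel), and RISC cuts the target between the nucleotides paired
# to miRNA positions 10 and 11.  The cleavage coordinate c is the 0-based
# transcript index of the FIRST nucleotide of the 3'-cleavage fragment,
# i.e. the nucleotide paired to miRNA position 10.  With a 1-based closed
# site [s, e] this is c = e - 10 (0-based), independent of miRNA 3'
# overhangs.

#' Derive the cleavage coordinate of a target site
#'
#' @param site one row of a `target_sites` data.frame (or any list with
#'   0-based half-open `start`/`end` on the transcript).
#' @return list of class `cleavage_site` with `transcript_id`,
#'   `mirna_name` and `cleavage` (0-based transcript coordinate of the
#'   first nucleotide of the 3' fragment).
#' @export
derive_cleavage_site <- function(site) {
  len <- site$end - site$start
  if (len < 11L) stop("target site shorter than 11 nt; cannot place cut")
  structure(
    list(
      transcript_id = site$transcript_id,
      mirna_name = site$mirna_name,
      cleavage = site$end - 10L,
      site_start = site$start,
      site_end = site$end
    ),
    class = "cleavage_site"
  )
}

# transcript coordinate of a genomic position for an unspliced gene
genome_to_transcript <- function(gpos, gene) {
  if (gene$strand == "+") gpos - gene$start else gene$end - 1L - gpos
}

transcript_to_genome <- function(tpos, gene) {
  if (gene$strand == "+") gene$start + tpos else gene$end - 1L - tpos
}

#' Per-position siRNA profile around a cleavage site
#'
#' Counts read 5' ends at each transcript position inside
#' `[c - flank, c + flank)` (c = cleavage coordinate), stratified by read
#' size and strand, and totals the two sides: `n5` counts reads with 5'
#' end strictly before c, `n3` reads at or after c (half-open boundary:
#' a 5' end exactly at c belongs to the 3' side).  Genes are treated as
#' unspliced; the gene's strand orients the transcript.
#'
#' @param reads an `aligned_reads` data.frame (one sample or genotype).
#' @param gene one row of a `gene_annotation` data.frame.
#' @param site one row of a `target_sites` data.frame (transcript
#'   coordinates), or a `cleavage_site`.
#' @param flank half-width of the window in nt (default 500).
#' @param library_size optional mapped-read total used for the
#'   reads-per-10-million display column.
#' @return list of class `cleavage_profile`: `profile` data.frame
#'   (`offset` from c, `size`, `strand`, `count`, `per10M`), `n5`, `n3`,
#'   `cleavage`, `flank`.
#' @export
build_profile <- function(reads, gene, site, flank = 500L,
                          library_size = NULL) {
  cs <- if (inherits(site, "cleavage_site")) site else derive_cleavage_site(site)
  c0 <- cs$cleavage
  tx_len <- gene$end - gene$start
  if (c0 <= 0L || c0 >= tx_len) stop("cleavage site outside transcript")
  on_gene <- reads$chrom == gene$chrom
  r <- reads[on_gene, , drop = FALSE]
  if (nrow(r)) {
    tpos <- genome_to_transcript(read_five_prime(r), gene)
    keep <- tpos >= c0 - flank & tpos < c0 + flank & tpos >= 0L & tpos < tx_len
    r <- r[keep, , drop = FALSE]
    tpos <- tpos[keep]
  } else {
    tpos <- integer()
  }
  if (nrow(r)) {
    # read strand relative to the transcript
    rel_strand <- ifelse(r$strand == gene$strand, "+", "-")
    prof <- data.table::data.table(
      offset = tpos - c0, size = r$length, strand = rel_strand
    )[, .N, by = c("offset", "size", "strand")]
    data.table::setnames(prof, "N", "count")
    data.table::setorderv(prof, c("offset", "size", "strand"))
    prof <- as.data.frame(prof)
  } else {
    prof <- data.frame(offset = integer(), size = integer(),
                       strand = character(), count = integer(),
                       stringsAsFactors = FALSE)
  }
  prof$per10M <- if (!is.null(library_size) && library_size > 0) {
    prof$count / library_size * 1e7
  } else {
    rep(NA_real_, nrow(prof))
  }
  structure(
    list(
      transcript_id = cs$transcript_id, mirna_name = cs$mirna_name,
      profile = prof,
      n5 = sum(prof$count[prof$offset < 0L]),
      n3 = sum(prof$count[prof$offset >= 0L]),
      cleavage = c0, flank = as.integer(flank)
    ),
    class = "cleavage_profile"
  )
}

#' Classify the direction of siRNA spreading around a cleavage site
#'
#' With f = max(n5, n3) / (n5 + n3): `none` when fewer than `min_reads`
#' reads fall in the window; `five_prime` when n5/(n5+n3) >= exclusivity;
#' `three_prime` when n3/(n5+n3) >= exclusivity; otherwise
#' `bidirectional`.
#'
#' @param profile a `cleavage_profile` (or any list with `n5` and `n3`).
#' @param min_reads minimum in-window read count to call a direction
#'   (default 10).
#' @param exclusivity fraction on one side needed for an exclusive call
#'   (default 0.9).
#' @return list of class `direction_call`: `call`, `f`, `n5`, `n3`,
#'   `min_reads`, `exclusivity`.
#' @export
classify_direction <- function(profile, min_reads = 10L, exclusivity = 0.9) {
  n5 <- profile$n5
  n3 <- profile$n3
  tot <- n5 + n3
  if (tot < min_reads) {
    call <- "none"
    f <- NA_real_
  } else {
    f <- max(n5, n3) / tot
    call <- if (n5 / tot >= exclusivity) {
      "five_prime"
    } else if (n3 / tot >= exclusivity) {
      "three_prime"
    } else {
      "bidirectional"
    }
  }
  structure(
    list(call = call, f = f, n5 = n5, n3 = n3,
         min_reads = as.integer(min_reads), exclusivity = exclusivity),
    class = "direction_call"
  )
}
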