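# Locus assembly from significant windows and miRNA-target enrichment.

#' Merge significant windows into loci
#'
#' Significant windows of the same direction whose intervals overlap, or
#' lie within `gap` nt of one another, are merged across size classes.
#' Opposite-direction windows never merge.  With half-overlapping windows
#' contiguous signal always yields overlapping significant windows, so
#' the default gap is 0 (overlap only).
#'
#' @param results a `diff_results` data.frame (or any data.frame with
#'   `chrom`, `start`, `end`, `significant`, `direction`, `size`).
#' @param gap maximum separation in nt still merged (default 0).
#' @return data.frame of class `loci`: `chrom`, `start`, `end`,
#'   `direction`, `n_windows` (contributing window x size records),
#'   sorted by (chrom, start, direction).
#' @export
merge_windows <- function(results, gap = 0L) {
  sig <- results[!is.na(results$significant) & results$significant, ,
                 drop = FALSE]
  empty <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    direction = character(), n_windows = integer(),
    stringsAsFactors = FALSE
  )
  class(empty) <- c("loci", "data.frame")
  if (nrow(sig) == 0L) return(empty)
  pieces <- list()
  for (dir in unique(sig$direction)) {
    sd <- sig[sig$direction == dir, , drop = FALSE]
    for (ch in unique(sd$chrom)) {
      sc <- sd[sd$chrom == ch, , drop = FALSE]
      ir <- IRanges::IRanges(start = sc$start + 1L, end = sc$end)
      red <- IRanges::reduce(ir, min.gapwidth = gap + 1L)
      hits <- IRanges::countOverlaps(red, ir, maxgap = gap)
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = ch,
        start = IRanges::start(red) - 1L,
        end = IRanges::end(red),
        direction = dir,
        n_windows = as.integer(hits),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("loci", "data.frame")
  out
}

#' Attach genes and miRNA-target status to loci
#'
#' A locus is annotated with every gene it overlaps by at least 1 nt
#' (any-overlap), and flagged `is_target` iff at least one overlapped gene
#' carries a target-site record.
#'
#' @param loci a `loci` data.frame.
#' @param annotation a `gene_annotation` data.frame.
#' @param target_sites a `target_sites` data.frame (transcript ids must
#'   refer to gene ids of `annotation`).
#' @return `loci` with `genes` (comma-separated ids, "" if intergenic) and
#'   `is_target` columns.
#' @export
annotate_loci <- function(loci, annotation, target_sites) {
  target_genes <- unique(target_sites$transcript_id)
  genes <- character(nrow(loci))
  is_target <- logical(nrow(loci))
  if (nrow(loci)) {
    for (i in seq_len(nrow(loci))) {
      same <- annotation$chrom == loci$chrom[i] &
        annotation$start < loci$end[i] & annotation$end > loci$start[i]
      ids <- annotation$gene_id[same]
      genes[i] <- paste(ids, collapse = ",")
      is_target[i] <- any(ids %in% target_genes)
    }
  }
  loci$genes <- genes
  loci$is_target <- is_target
  loci
}

# hypergeometric upper tail and two-sided (by mass) Fisher p for a 2x2
# table with fixed margins
fisher_2x2 <- function(a, b, c, d) {
  K <- a + c          # target genes in universe
  n <- a + b          # genes hit by loci
  N <- a + b + c + d  # universe
  kmin <- max(0L, n - (N - K))
  kmax <- min(K, n)
  ks <- kmin:kmax
  pk <- dhyper(ks, K, N - K, n)
  pobs <- dhyper(a, K, N - K, n)
  p_one <- sum(pk[ks >= a])
  p_two <- min(1, sum(pk[pk <= pobs * (1 + 1e-9)]))
  list(p_one_sided = p_one, p_two_sided = p_two)
}

#' miRNA-target enrichment among locus genes (Fisher's exact test)
#'
#' Builds the 2x2 gene table (locus & target, locus & non-target,
#' target not in loci, rest of universe) and computes the hypergeometric
#' one-sided upper-tail p and a two-sided p summing all tables with
#' probability at most that of the observed table.
#'
#' @param loci annotated `loci` (after [annotate_loci()]).
#' @param gene_universe character vector of all gene ids.
#' @param target_genes character vector of miRNA-target gene ids
#'   (subset of the universe).
#' @return list of class `enrichment_result`: `table` (named a/b/c/d),
#'   `odds_ratio` (sample OR, NA when undefined), `p_one_sided`,
#'   `p_two_sided`.
#' @export
enrichment_test <- function(loci, gene_universe, target_genes) {
  gene_universe <- unique(gene_universe)
  if (length(gene_universe) == 0L) stop("empty gene universe")
  target_genes <- unique(target_genes)
  if (!all(target_genes %in% gene_universe)) {
    stop("target set must be a subset of the universe")
  }
  locus_genes <- unique(unlist(strsplit(loci$genes[nzchar(loci$genes)], ",")))
  if (!all(locus_genes %in% gene_universe)) {
    stop("locus gene(s) outside the universe: ",
         paste(setdiff(locus_genes, gene_universe), collapse = ", "))
  }
  a <- length(intersect(locus_genes, target_genes))
  b <- length(setdiff(locus_genes, target_genes))
  c_ <- length(setdiff(target_genes, locus_genes))
  d <- length(gene_universe) - a - b - c_
  if (length(target_genes) == 0L) {
    res <- list(p_one_sided = 1, p_two_sided = 1)
    or <- NA_real_
  } else {
    res <- fisher_2x2(a, b, c_, d)
    or <- if (b > 0 && c_ > 0) (a * d) / (b * c_) else NA_real_
  }
  structure(
    list(table = c(a = a, b = b, c = c_, d = d), odds_ratio = or,
         p_one_sided = res$p_one_sided, p_two_sided = res$p_two_sided),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("2x2 table (a,b,c,d):", paste(x$table, collapse = ", "), "\n")
  cat("odds ratio:", format(x$odds_ratio), "\n")
  cat("one-sided p:", format(x$p_one_sided), " two-sided p:",
      format(x$p_two_sided), "\n")
  invisible(x)
}
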