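# File formats and canonical in-memory records.
#
# One in-memory representation per entity, all genomic coordinates 0-based
# half-open.  GFF3 and the target-site TSV are 1-based closed on disk and
# converted exactly once, here at the boundary.

ALN_COLS <- c("chrom", "start", "end", "strand", "sample_id")

#' Read aligned small-RNA reads
#'
#' Reads a coordinate file of mapped small-RNA reads into the canonical
#' record layout: one row per alignment with `chrom`, `start` (0-based
#' inclusive), `end` (0-based exclusive), `strand` (`+`/`-`), `sample_id`
#' and derived `length = end - start`.
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`tsv`}{the package's 5-column BED-like dialect
#'     (`chrom  start  end  strand  sample_id`, tab separated, one header
#'     line). This is the canonical fixture format.}
#'   \item{`bam`}{an adapter over [Rsamtools::scanBam()] producing the same
#'     record type; `sample_id` is taken from the file name unless given.}
#' }
#'
#' Counts downstream are per alignment record: a multi-mapping read present
#' as several records is counted once per record.
#'
#' @param path path to the alignment file.
#' @param dialect `"tsv"` or `"bam"`.
#' @param sample_id optional sample label overriding the file's own labels
#'   (required for BAM).
#' @return data.frame of class `aligned_reads`, rows in file order.
#' @export
read_alignments <- function(path, dialect = c("tsv", "bam"), sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("alignment file does not exist: ", path)
  if (dialect == "tsv") {
    lines <- readLines(path)
    if (length(lines) == 0L || (length(lines) == 1L && !nzchar(lines[1L]))) {
      return(empty_alignments())
    }
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (!identical(header, ALN_COLS)) {
      stop("malformed alignment TSV header (expected ", paste(ALN_COLS, collapse = ", "), ")")
    }
    body <- lines[-1L]
    if (length(body) == 0L) return(empty_alignments())
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 5L)) {
      stop("malformed alignment line ", which(nf != 5L)[1L] + 1L, ": expected 5 fields")
    }
    m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
    start <- suppressWarnings(as.integer(m[, 2L]))
    end <- suppressWarnings(as.integer(m[, 3L]))
    bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
    if (length(bad)) {
      stop("malformed coordinates at line ", bad[1L] + 1L,
           " (need 0 <= start < end)")
    }
    bad_strand <- which(!m[, 4L] %in% c("+", "-"))
    if (length(bad_strand)) {
      stop("invalid strand at line ", bad_strand[1L] + 1L)
    }
    reads <- data.frame(
      chrom = m[, 1L], start = start, end = end,
      strand = m[, 4L], sample_id = m[, 5L],
      stringsAsFactors = FALSE
    )
  } else {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("BAM dialect requires the Rsamtools package")
    }
    p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "qwidth", "strand"))
    b <- Rsamtools::scanBam(path, param = p)[[1L]]
    keep <- !is.na(b$pos)
    sid <- if (is.null(sample_id)) sub("\\.bam$", "", basename(path)) else sample_id
    reads <- data.frame(
      chrom = as.character(b$rname)[keep],
      start = b$pos[keep] - 1L,
      end = b$pos[keep] - 1L + b$qwidth[keep],
      strand = as.character(b$strand)[keep],
      sample_id = sid,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(sample_id)) reads$sample_id <- sample_id
  reads$length <- reads$end - reads$start
  class(reads) <- c("aligned_reads", "data.frame")
  reads
}

empty_alignments <- function() {
  reads <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), sample_id = character(), length = integer(),
    stringsAsFactors = FALSE
  )
  class(reads) <- c("aligned_reads", "data.frame")
  reads
}

#' Write aligned reads in the TSV dialect
#'
#' Inverse of [read_alignments()] for the TSV dialect; a read/write round
#' trip reproduces the file byte-identically.
#'
#' @param reads an `aligned_reads` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_alignments <- function(reads, path) {
  write_tsv(reads[, ALN_COLS, drop = FALSE], path)
}

#' Read gene models from GFF3
#'
#' Imports features of type `gene` via [rtracklayer::import()] and converts
#' GFF3's 1-based closed intervals to the internal 0-based half-open
#' convention (a 1 nt feature with start = end = k becomes `[k-1, k)`).
#' `##sequence-region` pragmas, when present, are used to warn about (but
#' keep) genes outside the declared bounds.
#'
#' @param path path to a GFF3 file.
#' @return data.frame of class `gene_annotation` with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open), sorted by
#'   (chrom, start).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("GFF3 file does not exist: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) {
    ann <- data.frame(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer(), stringsAsFactors = FALSE
    )
    class(ann) <- c("gene_annotation", "data.frame")
    return(ann)
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids)) stop("gene feature without ID attribute")
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ann <- data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,  # 1-based closed -> 0-based half-open
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
  # sequence-region pragmas: "##sequence-region seqid start end" (1-based)
  prag <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (length(prag)) {
    f <- strsplit(trimws(prag), "[ \t]+")
    lens <- setNames(
      vapply(f, function(x) as.integer(x[4L]), 0L),
      vapply(f, function(x) x[2L], "")
    )
    known <- ann$chrom %in% names(lens)
    out <- known & (ann$end > lens[ann$chrom] | ann$start < 0L)
    if (any(out)) {
      warning("gene(s) outside declared sequence-region kept: ",
              paste(ann$gene_id[out], collapse = ", "))
    }
  }
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write gene models as GFF3
#'
#' @param annotation a `gene_annotation` data.frame (internal 0-based
#'   half-open coordinates).
#' @param path output path.
#' @param chrom_lengths optional named integer vector; when given,
#'   `##sequence-region` pragmas are emitted.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(annotation, path, chrom_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(chrom_lengths)) {
    writeLines(sprintf("##sequence-region %s 1 %d",
                       names(chrom_lengths), as.integer(chrom_lengths)), con)
  }
  if (nrow(annotation)) {
    writeLines(sprintf(
      "%s\ttransitr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      annotation$chrom, annotation$start + 1L, annotation$end,
      annotation$strand, annotation$gene_id
    ), con)
  }
  invisible(path)
}

#' Read miRNA target sites
#'
#' Reads the target-site TSV (`transcript_id`, `mirna_name`, `start`,
#' `end` 1-based closed on the transcript, `n_sites`) and attaches each
#' miRNA's sequence from a FASTA file, normalized to the RNA alphabet
#' (T read as U).  Site coordinates are converted to 0-based half-open.
#'
#' @param path_tsv target-site table.
#' @param mirna_fasta FASTA of miRNA sequences, names matching
#'   `mirna_name`.
#' @return data.frame of class `target_sites` with columns
#'   `transcript_id`, `mirna_name`, `start`, `end` (0-based half-open on
#'   the transcript), `n_sites`, `mirna_seq`.
#' @export
read_target_sites <- function(path_tsv, mirna_fasta) {
  tab <- read_tsv(path_tsv)
  need <- c("transcript_id", "mirna_name", "start", "end", "n_sites")
  if (!all(need %in% names(tab))) {
    stop("target-site TSV must have columns: ", paste(need, collapse = ", "))
  }
  seqs <- Biostrings::readBStringSet(mirna_fasta)
  mir <- setNames(as_rna(as.character(seqs)), names(seqs))
  missing <- setdiff(unique(tab$mirna_name), names(mir))
  if (length(missing)) {
    stop("miRNA sequence(s) missing from FASTA: ", paste(missing, collapse = ", "))
  }
  sites <- data.frame(
    transcript_id = tab$transcript_id,
    mirna_name = tab$mirna_name,
    start = as.integer(tab$start) - 1L,  # 1-based closed -> 0-based half-open
    end = as.integer(tab$end),
    n_sites = as.integer(tab$n_sites),
    mirna_seq = unname(mir[tab$mirna_name]),
    stringsAsFactors = FALSE
  )
  site_len <- sites$end - sites$start
  if (any(site_len < 18L | site_len > 26L)) {
    stop("site length outside [18, 26] nt for row(s): ",
         paste(which(site_len < 18L | site_len > 26L), collapse = ", "))
  }
  mir_len <- nchar(sites$mirna_seq)
  if (any(mir_len < 19L | mir_len > 24L)) {
    stop("miRNA length outside [19, 24] nt for: ",
         paste(unique(sites$mirna_name[mir_len < 19L | mir_len > 24L]), collapse = ", "))
  }
  class(sites) <- c("target_sites", "data.frame")
  sites
}

#' Write a target-site table (1-based closed on disk)
#' @param sites a `target_sites` data.frame (internal coordinates).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_target_sites <- function(sites, path) {
  out <- data.frame(
    transcript_id = sites$transcript_id,
    mirna_name = sites$mirna_name,
    start = sites$start + 1L,
    end = sites$end,
    n_sites = sites$n_sites,
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
}

#' Write named sequences as FASTA
#' @param seqs named character vector of sequences (DNA or RNA alphabet).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @param rna normalize to RNA alphabet?
#' @return named character vector.
#' @export
read_fasta <- function(path, rna = FALSE) {
  s <- Biostrings::readBStringSet(path)
  x <- setNames(as.character(s), names(s))
  if (rna) x <- as_rna(x) else x <- toupper(x)
  x
}
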