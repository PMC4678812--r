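#' @importFrom stats dbinom dnbinom dpois dhyper optimize rnbinom runif
#'   p.adjust var setNames
#' @importFrom utils read.table write.table head tail
#' @importFrom data.table data.table setnames setorderv .N
NULL

# Internal TSV conventions: tab separated, one header line naming columns,
# no quoting, no row names, "." for missing.  All writers in the package go
# through write_tsv() so files are byte-reproducible.
write_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE,
    na = "."
  )
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.table(path,
    sep = "\t", header = TRUE, quote = "", comment.char = "",
    stringsAsFactors = FALSE, colClasses = colClasses, na.strings = "."
  )
}

#' Derive a reproducible stage seed from a global seed
#'
#' Stage seeds are derived by hashing the stage name and folding the hash
#' into the global seed, so that each pipeline stage has an independent,
#' stable stream without manual seed bookkeeping.  The result is always a
#' positive integer below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the stage.
#' @return a positive integer scalar.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- digest::digest2int(stage, seed = 0L)
  s <- bitwXor(as.integer(seed %% 2147483647L), h)
  s <- abs(s)
  if (s == 0L) s <- 1L
  s
}

# DNA/RNA alphabet helpers ----------------------------------------------

#' Convert a nucleotide string to the RNA alphabet
#'
#' Uppercases and replaces T with U. Any character outside ACGUN raises an
#' error.
#' @param x character vector of sequences.
#' @return character vector in RNA alphabet.
#' @export
as_rna <- function(x) {
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop("non-RNA characters in sequence(s): ", paste(which(bad), collapse = ", "))
  }
  x
}

rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

dna_revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}
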