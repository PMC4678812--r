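# Non-templated 3' tail extraction and classification from 3'-RACE clone
# sequences against a reference 5'-cleavage fragment.
#
# Matching is exact (Sanger clones); the clone's 5' end is anchored at the
# reference 5' end and extended while it matches the reference
# (maximal-templated rule: a clone nucleotide identical to the next
# reference nucleotide is always called templated, so ambiguous tails are
# shortened, never lengthened).  The remaining clone suffix is the
# non-templated tail.

#' Extract the non-templated 3' tail of a RACE clone
#'
#' @param clone_seq clone insert sequence (DNA or RNA; normalized to RNA).
#' @param reference the full expected 5'-cleavage fragment sequence.
#' @param min_match clones whose maximal templated match is shorter than
#'   this are category `non-fragment` (off-target cDNAs; default 20).
#' @param downstream optional reference context 3' of the cleavage site;
#'   clones that run past the reference 3' end and continue matching this
#'   context for `unc_min` nt are uncleaved-mRNA cDNAs, category
#'   `non-fragment`.
#' @param unc_min matched downstream nt needed to call a clone uncleaved
#'   (default 4).
#' @return list of class `race_clone`: `matched_len`, `tail` (possibly
#'   ""), `category` (`fragment`/`non-fragment`).
#' @export
extract_tail <- function(clone_seq, reference, min_match = 20L,
                         downstream = NULL, unc_min = 4L) {
  clone <- as_rna(clone_seq)
  ref <- as_rna(reference)
  if (nchar(clone) == 0L) stop("empty clone sequence")
  cv <- strsplit(clone, "")[[1L]]
  rv <- strsplit(ref, "")[[1L]]
  k <- 0L
  while (k < length(cv) && k < length(rv) && cv[k + 1L] == rv[k + 1L]) {
    k <- k + 1L
  }
  tail_str <- if (k < length(cv)) paste(cv[(k + 1L):length(cv)], collapse = "") else ""
  category <- "fragment"
  if (k < min_match) {
    category <- "non-fragment"
  } else if (k == length(rv) && nzchar(tail_str) && !is.null(downstream)) {
    dv <- strsplit(as_rna(downstream), "")[[1L]]
    tv <- strsplit(tail_str, "")[[1L]]
    d <- 0L
    while (d < length(tv) && d < length(dv) && tv[d + 1L] == dv[d + 1L]) {
      d <- d + 1L
    }
    if (d >= min(unc_min, length(tv))) category <- "non-fragment"
  }
  structure(
    list(matched_len = k, tail = tail_str, category = category),
    class = "race_clone"
  )
}

#' Classify a non-templated tail by dominant nucleotide
#'
#' The class is the strictly most frequent nucleotide of the tail; ties go
#' to the class of the first tail nucleotide.  Tails mixing several
#' nucleotides still classify by majority (e.g. "UUA" is a U tail, "AAC"
#' an A tail).
#'
#' @param tail nonempty tail string (RNA alphabet).
#' @return one of "U", "A", "C", "G".
#' @export
classify_tail <- function(tail) {
  if (is.na(tail) || !nzchar(tail)) stop("empty tail cannot be classified")
  tv <- strsplit(as_rna(tail), "")[[1L]]
  tab <- table(tv)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) top else tv[1L]
}

#' Summarize tails over a set of processed clones
#'
#' @param clones data.frame with columns `tail` and `category` (one row
#'   per clone, as produced by [extract_tail()]), or a list of
#'   `race_clone` objects.
#' @return list of class `tail_summary`: `n_clones`, `n_fragment`,
#'   `n_tailed`, `spectrum` (named counts of exact tail strings),
#'   `class_totals` (U/A/C/G/mixed-free named counts).
#' @export
summarize_tails <- function(clones) {
  if (!is.data.frame(clones)) {
    clones <- data.frame(
      tail = vapply(clones, `[[`, "", "tail"),
      category = vapply(clones, `[[`, "", "category"),
      stringsAsFactors = FALSE
    )
  }
  frag <- clones[clones$category == "fragment", , drop = FALSE]
  tailed <- frag$tail[nzchar(frag$tail)]
  spectrum <- if (length(tailed)) {
    tab <- table(tailed)
    setNames(as.integer(tab), names(tab))
  } else {
    integer()
  }
  classes <- if (length(tailed)) {
    vapply(tailed, classify_tail, "")
  } else {
    character()
  }
  class_totals <- setNames(integer(4L), c("U", "A", "C", "G"))
  if (length(classes)) {
    tab <- table(factor(classes, levels = c("U", "A", "C", "G")))
    class_totals <- setNames(as.integer(tab), names(tab))
  }
  structure(
    list(
      n_clones = nrow(clones),
      n_fragment = nrow(frag),
      n_tailed = length(tailed),
      spectrum = spectrum,
      class_totals = class_totals
    ),
    class = "tail_summary"
  )
}

#' @export
print.tail_summary <- function(x, ...) {
  cat("clones:", x$n_clones, " fragment-derived:", x$n_fragment,
      " tailed:", x$n_tailed, "\n")
  if (length(x$spectrum)) {
    cat("tails:", paste(names(x$spectrum), x$spectrum, sep = "x",
                        collapse = ", "), "\n")
  }
  invisible(x)
}
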