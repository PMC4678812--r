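# Genome-wide scanning windows and size-stratified read counting.
#
# Windows of `window_length` nt advance by `step` nt (default 300/150, a
# 2x overlap), and read counts are kept separately for every read size in
# [size_min, size_max] (default 19-26 nt) and every sample.  A read is
# assigned to every window containing its 5'-end coordinate (start on the
# + strand, end - 1 on the - strand), which gives each in-range interior
# read an exact multiplicity of window_length / step windows.

#' Scanning-window configuration
#'
#' @param window_length window size in nt (default 300).
#' @param step distance between consecutive window starts in nt
#'   (default 150, i.e. half-overlapping windows).
#' @param size_min,size_max smallest and largest read length counted
#'   (defaults 19 and 26 nt).
#' @return a `window_config` list.
#' @export
window_config <- function(window_length = 300L, step = 150L,
                          size_min = 19L, size_max = 26L) {
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  size_min <- as.integer(size_min)
  size_max <- as.integer(size_max)
  if (!(step > 0L && step <= window_length)) {
    stop("need 0 < step <= window_length")
  }
  if (size_min > size_max) stop("need size_min <= size_max")
  structure(
    list(window_length = window_length, step = step,
         size_min = size_min, size_max = size_max),
    class = "window_config"
  )
}

#' Build the scanning-window list for a genome
#'
#' Per chromosome of length L, window starts are 0, step, 2*step, ... with
#' start < L, and each window ends at `min(start + window_length, L)`;
#' truncated terminal windows are retained.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (> 0).
#' @param config a [window_config()].
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), sorted by (chrom, start).
#' @export
make_windows <- function(chrom_lengths, config = window_config()) {
  if (length(chrom_lengths) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be named")
  }
  if (any(chrom_lengths <= 0L)) stop("chromosome lengths must be > 0")
  chrom_lengths <- chrom_lengths[order(names(chrom_lengths))]
  res <- lapply(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(0L, L - 1L, by = config$step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + config$window_length, L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

read_five_prime <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

#' Count reads per window, read size and sample
#'
#' Each read contributes one count to every window containing its 5'-end
#' coordinate, in its own size class.  Reads with length outside
#' `[size_min, size_max]` are excluded from both counts and library sizes.
#' Strands are pooled by default (transitive siRNAs arise from both
#' strands of the RDR6-made dsRNA); `stranded = TRUE` returns one count
#' array per strand for diagnostics.
#'
#' @param reads an `aligned_reads` data.frame.
#' @param windows window list from [make_windows()] (must be the regular
#'   grid implied by `config`).
#' @param config the [window_config()] used to build `windows`.
#' @param samples optional character vector fixing sample order (and the
#'   full sample universe); defaults to sorted unique `sample_id`.
#' @param stranded split counts by read strand?
#' @return an object of class `window_counts`: list with `windows`,
#'   `sizes`, `counts` (integer array window x size x sample, or a list of
#'   two such arrays when `stranded`), `library_sizes` (in-range mapped
#'   reads per sample) and `skipped` (reads on unknown chromosomes).
#' @export
count_reads <- function(reads, windows, config = window_config(),
                        samples = NULL, stranded = FALSE) {
  sizes <- seq.int(config$size_min, config$size_max)
  if (is.null(samples)) samples <- sort(unique(reads$sample_id))
  chroms <- unique(windows$chrom)
  n_win <- nrow(windows)

  # map (chrom, window start) -> row of `windows`
  win_key <- paste(windows$chrom, windows$start, sep = ":")
  win_row <- setNames(seq_len(n_win), win_key)
  chrom_max_start <- tapply(windows$start, windows$chrom, max)

  in_size <- reads$length >= config$size_min & reads$length <= config$size_max
  known <- reads$chrom %in% chroms
  skipped <- sum(!known & in_size)
  if (skipped > 0L) {
    warning(skipped, " in-range read(s) on unknown chromosome(s) skipped")
  }
  lib_sizes <- setNames(integer(length(samples)), samples)
  kept_all <- reads[in_size & known, , drop = FALSE]
  ls_tab <- table(factor(kept_all$sample_id, levels = samples))
  lib_sizes[names(ls_tab)] <- as.integer(ls_tab)

  count_one <- function(kept) {
    arr <- array(0L, dim = c(n_win, length(sizes), length(samples)),
                 dimnames = list(NULL, as.character(sizes), samples))
    if (nrow(kept) == 0L) return(arr)
    pos <- read_five_prime(kept)
    n_off <- ceiling(config$window_length / config$step)
    dt <- NULL
    for (o in seq_len(n_off) - 1L) {
      k <- pos %/% config$step - o
      wstart <- k * config$step
      ok <- k >= 0L & pos < wstart + config$window_length &
        wstart <= chrom_max_start[kept$chrom]
      if (!any(ok)) next
      key <- paste(kept$chrom[ok], wstart[ok], sep = ":")
      row <- win_row[key]
      stopifnot(!anyNA(row))
      piece <- data.table::data.table(
        w = unname(row),
        s = kept$length[ok],
        smp = kept$sample_id[ok]
      )
      dt <- if (is.null(dt)) piece else rbind(dt, piece)
    }
    if (is.null(dt)) return(arr)
    agg <- dt[, .N, by = c("w", "s", "smp")]
    idx <- cbind(agg$w, match(agg$s, sizes), match(agg$smp, samples))
    arr[idx] <- arr[idx] + agg$N
    arr
  }

  counts <- if (stranded) {
    list(`+` = count_one(kept_all[kept_all$strand == "+", , drop = FALSE]),
         `-` = count_one(kept_all[kept_all$strand == "-", , drop = FALSE]))
  } else {
    count_one(kept_all)
  }
  structure(
    list(windows = windows, sizes = sizes, counts = counts,
         library_sizes = lib_sizes, skipped = skipped,
         config = config, stranded = stranded),
    class = "window_counts"
  )
}

#' @export
print.window_counts <- function(x, ...) {
  cat("window_counts:", nrow(x$windows), "windows x", length(x$sizes),
      "sizes x", length(x$library_sizes), "samples\n")
  cat("library sizes:",
      paste(names(x$library_sizes), x$library_sizes, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Write a window count matrix as TSV
#'
#' Long layout: `chrom`, `start`, `end`, `size`, then one column per
#' sample.  All windows x sizes are emitted, including all-zero rows, so
#' window indexing is stable across files.
#'
#' @param wc a `window_counts` object (unstranded).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_window_counts <- function(wc, path) {
  stopifnot(!wc$stranded)
  n_win <- nrow(wc$windows)
  n_size <- length(wc$sizes)
  out <- data.frame(
    chrom = rep(wc$windows$chrom, times = n_size),
    start = rep(wc$windows$start, times = n_size),
    end = rep(wc$windows$end, times = n_size),
    size = rep(wc$sizes, each = n_win),
    stringsAsFactors = FALSE
  )
  for (smp in names(wc$library_sizes)) {
    out[[smp]] <- as.vector(wc$counts[, , smp])
  }
  attr_line <- paste0("# library_sizes ",
                      paste(names(wc$library_sizes), wc$library_sizes,
                            sep = "=", collapse = " "))
  con <- file(path, "w")
  writeLines(attr_line, con)
  close(con)
  suppressWarnings(utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE,
    append = TRUE
  ))
  invisible(path)
}
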