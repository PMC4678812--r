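# Exact negative-binomial two-group test with common dispersion,
# implemented from first principles.
#
# Model: counts y ~ NB(mean mu, dispersion phi) with var = mu + phi*mu^2
# (phi = 0 reduces to Poisson).  After library equalization, replicate
# counts within each group are summed and, conditional on the grand total
# t, the group-A sum follows the distribution of a sum of NB variables
# conditioned on t.  The two-sided p-value sums the probability of every
# split at most as likely as the observed one.

#' Differential-accumulation configuration
#'
#' @param alpha significance level on the (adjusted) p-value
#'   (default 0.05, the raw-threshold rule).
#' @param adjust multiple-testing adjustment, `"none"` (default) or
#'   `"BH"` (Benjamini-Hochberg across all tested window x size pairs).
#' @param min_total_count windows whose counts summed over all samples of
#'   the comparison fall below this are not tested (p = NA; default 5).
#' @param normalization `"total-count"` (default) or `"median-of-ratios"`.
#' @return a `diff_config` list.
#' @export
diff_config <- function(alpha = 0.05, adjust = c("none", "BH"),
                        min_total_count = 5L,
                        normalization = c("total-count", "median-of-ratios")) {
  adjust <- match.arg(adjust)
  normalization <- match.arg(normalization)
  if (!(alpha > 0 && alpha < 1)) stop("need 0 < alpha < 1")
  structure(
    list(alpha = alpha, adjust = adjust,
         min_total_count = as.integer(min_total_count),
         normalization = normalization),
    class = "diff_config"
  )
}

#' Normalization factors / effective library sizes
#'
#' `total-count` returns the library sizes unchanged (per-million style
#' scaling); `median-of-ratios` computes DESeq-style size factors from the
#' median ratio to the geometric-mean reference row, rescaled to geometric
#' mean 1, and returns `library_sizes * factor` as effective sizes.
#'
#' @param counts integer matrix (rows = windows, cols = samples).
#' @param library_sizes per-sample total mapped in-range reads (> 0).
#' @param method `"total-count"` or `"median-of-ratios"`.
#' @return list with `effective_sizes` and `factors` (geometric mean 1 for
#'   median-of-ratios; all 1 for total-count).
#' @export
normalize_factors <- function(counts, library_sizes,
                              method = c("total-count", "median-of-ratios")) {
  method <- match.arg(method)
  if (any(library_sizes <= 0)) {
    stop("sample(s) with zero in-range reads: ",
         paste(names(library_sizes)[library_sizes <= 0], collapse = ", "))
  }
  if (method == "total-count") {
    f <- rep(1, length(library_sizes))
  } else {
    counts <- as.matrix(counts)
    ref_ok <- rowSums(counts > 0) == ncol(counts)
    if (!any(ref_ok)) stop("no window with nonzero counts in all samples")
    logref <- rowMeans(log(counts[ref_ok, , drop = FALSE]))
    rat <- apply(counts[ref_ok, , drop = FALSE], 2L,
                 function(col) exp(stats::median(log(col) - logref)))
    f <- rat / exp(mean(log(rat)))  # geometric mean 1
  }
  names(f) <- names(library_sizes)
  list(effective_sizes = library_sizes * f, factors = f)
}

# rescale counts to a common (geometric-mean) library size and round to
# integers; the exact test's equal-library precondition
equalize_counts <- function(counts, library_sizes) {
  common <- exp(mean(log(library_sizes)))
  sweepd <- sweep(as.matrix(counts), 2L, common / library_sizes, `*`)
  storage.mode(sweepd) <- "double"
  round(sweepd)
}

#' Estimate the common NB dispersion
#'
#' Two estimators of the common dispersion phi (var = mu + phi*mu^2)
#' across all rows, pooling within-group information:
#' \describe{
#'   \item{`qcml`}{maximizes the summed conditional log-likelihood of the
#'     within-group splits given group totals, after equalizing libraries
#'     to their geometric mean (a common-dispersion qCML analogue).}
#'   \item{`moments`}{pooled method-of-moments:
#'     `max(0, sum(v - m) / sum(m^2))` over rows x groups with >= 2
#'     replicates, on equalized counts.}
#' }
#' Both are clamped to `[0, 10]`.
#'
#' @param counts integer matrix (rows = window x size units, cols =
#'   samples), already filtered to rows worth using.
#' @param groups factor/character of length `ncol(counts)`.
#' @param library_sizes per-sample library sizes (default: column sums).
#' @param method `"qcml"` or `"moments"`.
#' @return list with `phi` and `method` (class `dispersion_estimate`).
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       library_sizes = colSums(counts),
                                       method = c("qcml", "moments")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (ncol(counts) != length(groups)) stop("groups must match columns")
  if (!any(table(groups) >= 2L)) stop("need >= 2 replicates in some group")
  keep <- rowSums(counts) > 0
  if (!any(keep)) stop("all rows filtered (zero counts)")
  y <- equalize_counts(counts[keep, , drop = FALSE], library_sizes)

  if (method == "moments") {
    num <- 0
    den <- 0
    for (g in unique(groups)) {
      cols <- which(groups == g)
      if (length(cols) < 2L) next
      m <- rowMeans(y[, cols, drop = FALSE])
      v <- apply(y[, cols, drop = FALSE], 1L, stats::var)
      num <- num + sum(v - m)
      den <- den + sum(m^2)
    }
    phi <- if (den > 0) max(0, num / den) else 0
  } else {
    grp_cols <- lapply(unique(groups), function(g) which(groups == g))
    grp_cols <- grp_cols[lengths(grp_cols) >= 2L]
    tot <- lapply(grp_cols, function(cols) rowSums(y[, cols, drop = FALSE]))
    negll <- function(log_phi) {
      r <- 1 / exp(log_phi)
      ll <- 0
      for (i in seq_along(grp_cols)) {
        cols <- grp_cols[[i]]
        n <- length(cols)
        t <- tot[[i]]
        yg <- y[, cols, drop = FALSE]
        ll <- ll +
          sum(lgamma(yg + r)) - length(yg) * lgamma(r) -
          sum(lgamma(t + n * r)) + length(t) * lgamma(n * r)
      }
      -ll
    }
    opt <- stats::optimize(negll, lower = log(1e-6), upper = log(10))
    phi <- exp(opt$minimum)
    # the likelihood is flat towards phi -> 0 for Poisson data; snap to the
    # boundary when it fits at least as well
    if (negll(log(1e-6)) <= opt$objective + 1e-8) phi <- 0
  }
  structure(list(phi = min(phi, 10), method = method),
            class = "dispersion_estimate")
}

# conditional pmf of the group-A sum given total t, for groups of nA and
# nB equal-library replicates with common dispersion phi.  With equalized
# libraries the group sums are NB(nA/phi, p) and NB(nB/phi, p) with the
# same p, so the conditional law is negative hypergeometric (p cancels);
# for phi = 0 it is Binomial(t, nA/(nA+nB)).
cond_split_pmf <- function(t, nA, nB, phi) {
  s <- 0:t
  if (phi <= 0) {
    lp <- dbinom(s, t, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi
    rB <- nB / phi
    lp <- lchoose(s + rA - 1, s) + lchoose(t - s + rB - 1, t - s) -
      lchoose(t + rA + rB - 1, t)
  }
  p <- exp(lp - max(lp))
  p / sum(p)
}

# two-sided-by-mass p-value from a pmf vector and observed index (1-based)
pval_by_mass <- function(pmf, obs_idx) {
  po <- pmf[obs_idx]
  min(1, sum(pmf[pmf <= po * (1 + 1e-9)]))
}

#' Exact negative-binomial two-group test
#'
#' For each row, replicate counts are equalized to the geometric-mean
#' library size, summed within groups, and the group-A sum S is tested
#' conditional on the grand total t.  Under H0 (equal means, common
#' dispersion `phi`) the conditional law of S is computed by exact
#' convolution of the replicate NB pmfs — in the equal-library case this
#' collapses to a closed-form negative-hypergeometric law, which is used
#' and memoized by t.  The two-sided p-value sums `P(S = s)` over all s
#' with `P(S = s) <= P(S = s_obs)`.  `t = 0` gives p = 1 by convention.
#'
#' @param countsA,countsB integer matrices (rows = units, columns =
#'   replicates of group A / group B).
#' @param sizesA,sizesB library sizes for the columns of
#'   `countsA`/`countsB`.
#' @param phi common dispersion (>= 0).
#' @return numeric vector of p-values in (0, 1].
#' @export
exact_nb_test <- function(countsA, countsB, sizesA, sizesB, phi) {
  if (phi < 0) stop("phi must be >= 0")
  countsA <- as.matrix(countsA)
  countsB <- as.matrix(countsB)
  stopifnot(nrow(countsA) == nrow(countsB))
  nA <- ncol(countsA)
  nB <- ncol(countsB)
  y <- equalize_counts(cbind(countsA, countsB), c(sizesA, sizesB))
  sA <- rowSums(y[, seq_len(nA), drop = FALSE])
  sB <- rowSums(y[, nA + seq_len(nB), drop = FALSE])
  t <- sA + sB
  p <- rep(NA_real_, length(t))
  p[t == 0] <- 1
  todo <- which(t > 0)
  if (length(todo)) {
    memo <- new.env(parent = emptyenv())
    for (i in todo) {
      key <- as.character(t[i])
      pmf <- get0(key, envir = memo)
      if (is.null(pmf)) {
        pmf <- cond_split_pmf(t[i], nA, nB, phi)
        assign(key, pmf, envir = memo)
      }
      p[i] <- pval_by_mass(pmf, sA[i] + 1L)
    }
  }
  p
}

#' Flag significant windows
#'
#' Applies the multiple-testing policy and significance threshold of a
#' [diff_config()] to a result table carrying raw p-values: the default
#' reproduces the raw `p < alpha` rule; `adjust = "BH"` applies
#' Benjamini-Hochberg across all tested rows first.
#'
#' @param results data.frame with at least a `p` column (NA = untested).
#' @param config a [diff_config()].
#' @return `results` with columns `padj` and `significant` added; untested
#'   rows are never significant.
#' @export
call_significant <- function(results, config = diff_config()) {
  padj <- rep(NA_real_, nrow(results))
  tested <- !is.na(results$p)
  padj[tested] <- switch(config$adjust,
    none = results$p[tested],
    BH = p.adjust(results$p[tested], method = "BH")
  )
  results$padj <- padj
  results$significant <- !is.na(padj) & padj < config$alpha
  results
}

#' Differential siRNA accumulation between two genotypes
#'
#' Full per-window x size exact NB analysis of a [count_reads()] matrix:
#' normalization, common-dispersion estimation (qCML-style, across both
#' groups jointly), exact conditional test and significance calls.
#' Direction is `up_in_case` when the normalized case mean exceeds the
#' control mean.
#'
#' @param wc a `window_counts` object.
#' @param control,case character vectors of sample ids for the control and
#'   case groups (e.g. the two replicates of each genotype).
#' @param config a [diff_config()].
#' @param phi optional fixed dispersion; estimated when `NULL`.
#' @return data.frame of class `diff_results`: `chrom`, `start`, `end`,
#'   `size`, `mean_control`, `mean_case` (normalized to the geometric-mean
#'   library), `log2fc`, `p`, `padj`, `significant`, `direction`; one row
#'   per window x size.  Attribute `phi` records the dispersion used.
#' @export
diff_accumulation <- function(wc, control, case, config = diff_config(),
                              phi = NULL) {
  stopifnot(inherits(wc, "window_counts"), !wc$stranded)
  samples <- names(wc$library_sizes)
  if (!all(c(control, case) %in% samples)) {
    stop("unknown sample id(s): ",
         paste(setdiff(c(control, case), samples), collapse = ", "))
  }
  n_win <- nrow(wc$windows)
  n_size <- length(wc$sizes)
  # flatten window x size into rows; samples as columns
  flat <- function(smp) as.vector(wc$counts[, , smp])
  mat <- vapply(c(control, case), flat, numeric(n_win * n_size))
  lib <- wc$library_sizes[c(control, case)]
  nf <- normalize_factors(mat, lib, config$normalization)
  eff <- nf$effective_sizes

  total <- rowSums(mat)
  tested <- total >= config$min_total_count
  p <- rep(NA_real_, nrow(mat))
  if (any(tested)) {
    if (is.null(phi)) {
      groups <- c(rep("control", length(control)), rep("case", length(case)))
      disp <- estimate_common_dispersion(mat[tested, , drop = FALSE], groups,
                                         library_sizes = eff, method = "qcml")
      phi <- disp$phi
    }
    p[tested] <- exact_nb_test(
      mat[tested, seq_along(control), drop = FALSE],
      mat[tested, length(control) + seq_along(case), drop = FALSE],
      eff[seq_along(control)], eff[length(control) + seq_along(case)],
      phi
    )
  } else if (is.null(phi)) {
    phi <- 0
  }

  common <- exp(mean(log(eff)))
  ynorm <- sweep(mat, 2L, common / eff, `*`)
  mean_control <- rowMeans(ynorm[, seq_along(control), drop = FALSE])
  mean_case <- rowMeans(ynorm[, length(control) + seq_along(case), drop = FALSE])
  res <- data.frame(
    chrom = rep(wc$windows$chrom, times = n_size),
    start = rep(wc$windows$start, times = n_size),
    end = rep(wc$windows$end, times = n_size),
    size = rep(wc$sizes, each = n_win),
    mean_control = mean_control,
    mean_case = mean_case,
    log2fc = log2((mean_case + 0.5) / (mean_control + 0.5)),
    p = p,
    stringsAsFactors = FALSE
  )
  res <- call_significant(res, config)
  res$direction <- ifelse(mean_case > mean_control, "up_in_case",
                          ifelse(mean_case < mean_control, "down_in_case",
                                 NA_character_))
  attr(res, "phi") <- phi
  class(res) <- c("diff_results", "data.frame")
  res
}
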