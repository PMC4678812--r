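# Predicting the side of siRNA spreading from cleavage-fragment pairing
# energies, and exact binomial significance of the prediction accuracy.
#
# Rule: transitive siRNAs are expected on the cleavage fragment LEAST
# stably base-paired to the miRNA (the strand released first from RISC).
# When the two energies are similar (|dG5 - dG3| <= tau) the prediction
# defaults to five_prime: free-strand energies systematically
# underestimate pairing of the 3' fragment to the miRNA 5' half, because
# nucleotides 2-5 of an AGO-bound miRNA are pre-organized helically.

#' Predict the spreading side from fragment energies
#'
#' @param dG5,dG3 hybridization energies (kcal/mol) of the miRNA against
#'   the 5'- and 3'-cleavage fragments (see [fragment_energies()]); a
#'   `fragment_energies` object may be given as `dG5`.
#' @param tau similarity tolerance in kcal/mol (default 2.0): when
#'   `|dG5 - dG3| <= tau` the call is `five_prime`.
#' @return `"five_prime"` or `"three_prime"`.
#' @export
predict_side <- function(dG5, dG3 = NULL, tau = 2.0) {
  if (inherits(dG5, "fragment_energies")) {
    dG3 <- dG5$dG3
    dG5 <- dG5$dG5
  }
  if (is.null(dG3) || is.na(dG5) || is.na(dG3)) {
    stop("both dG5 and dG3 must be defined")
  }
  if (tau < 0) stop("tau must be >= 0")
  if (abs(dG5 - dG3) <= tau) {
    "five_prime"
  } else if (dG5 > dG3) {
    # 5' fragment less stably paired (less negative dG) -> spreading 5'
    "five_prime"
  } else {
    "three_prime"
  }
}

#' Compare predicted and observed spreading sides
#'
#' Restricts to eligible transcripts — targeted by a single small RNA and
#' with an unambiguous (exclusive) direction call — and counts agreements.
#' `bidirectional` and `none` calls are excluded from n.
#'
#' @param predictions character vector of predicted sides
#'   (`five_prime`/`three_prime`).
#' @param observed character vector of observed direction calls
#'   (`five_prime`, `three_prime`, `bidirectional`, `none`).
#' @param eligible logical vector (default all TRUE): single-small-RNA
#'   targets.
#' @return list with `k` (correct), `n` (eligible with exclusive calls).
#' @export
evaluate_predictions <- function(predictions, observed,
                                 eligible = rep(TRUE, length(observed))) {
  stopifnot(length(predictions) == length(observed),
            length(eligible) == length(observed))
  use <- eligible & observed %in% c("five_prime", "three_prime")
  list(k = sum(use & predictions == observed), n = sum(use))
}

# minimal exact big-integer support (base 1e7 little-endian digit vectors)
# for binomial numerators up to n = 64, where choose() exceeds 2^53
big_from_int <- function(x) {
  stopifnot(x >= 0)
  if (x == 0) return(0)
  d <- integer()
  while (x > 0) {
    d <- c(d, x %% 1e7)
    x <- x %/% 1e7
  }
  d
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, integer(n - length(a)))
  b <- c(b, integer(n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 1e7
    s[i] <- s[i] %% 1e7
  }
  if (carry > 0) s <- c(s, carry)
  s
}

big_to_double <- function(a) sum(a * 1e7^(seq_along(a) - 1))

#' Exact binomial upper tail P(X >= k)
#'
#' For `p0 = 0.5` and `n <= 64` the tail is computed exactly: the
#' numerator `sum_{j>=k} C(n, j)` is accumulated in integer arithmetic
#' (Pascal's triangle with big-integer addition, since C(64, 32) exceeds
#' 2^53) and divided by 2^n only at the end.  Other cases fall back to
#' floating-point summation of `dbinom`.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials.
#' @param p0 null success probability (default 0.5).
#' @return P(X >= k), in (0, 1] for k <= n.
#' @export
binomial_upper_tail <- function(k, n, p0 = 0.5) {
  if (!(n >= 0 && k >= 0 && k <= n)) stop("need 0 <= k <= n")
  if (!(p0 > 0 && p0 < 1)) stop("need 0 < p0 < 1")
  if (k == 0) return(1)
  if (p0 == 0.5 && n <= 64) {
    # Pascal's triangle row n in exact big integers
    row <- list(big_from_int(1))
    for (r in seq_len(n)) {
      new <- vector("list", r + 1L)
      new[[1L]] <- big_from_int(1)
      new[[r + 1L]] <- big_from_int(1)
      if (r > 1L) {
        for (j in 2L:r) new[[j]] <- big_add(row[[j - 1L]], row[[j]])
      }
      row <- new
    }
    num <- 0
    for (j in (k + 1L):(n + 1L)) num <- big_add(num, row[[j]])
    big_to_double(num) / 2^n
  } else {
    sum(dbinom(seq.int(n, k), n, p0))
  }
}
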