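# Independent oracles used by unit and acceptance tests.  Each oracle
# takes a route different from the implementation it checks: exhaustive
# enumeration or explicit convolution instead of closed forms and dynamic
# programming.

# conditional two-sided p-value by explicit convolution of per-replicate
# NB pmfs and exhaustive enumeration of splits (equal libraries)
bf_nb_cond_pval <- function(cA, cB, phi) {
  t <- sum(cA) + sum(cB)
  rep_pmf <- function() {
    if (phi <= 0) dpois(0:t, 1) else dnbinom(0:t, size = 1 / phi, mu = 1)
  }
  conv <- function(v, w) {
    vapply(0:t, function(s) {
      sum(v[seq_len(s + 1)] * w[(s + 1):1])
    }, 0)
  }
  group_pmf <- function(nrep) {
    out <- rep_pmf()
    if (nrep > 1L) for (k in 2:nrep) out <- conv(out, rep_pmf())
    out
  }
  pA <- group_pmf(length(cA))
  pB <- group_pmf(length(cB))
  joint <- vapply(0:t, function(s) pA[s + 1] * pB[t - s + 1], 0)
  joint <- joint / sum(joint)
  pobs <- joint[sum(cA) + 1]
  min(1, sum(joint[joint <= pobs * (1 + 1e-9)]))
}

# exhaustive enumeration of all antiparallel non-crossing pairings,
# scored with the same model as the DP via score_pairing()
bf_duplex <- function(a, b, params, temp_c = 21, gu = TRUE) {
  av <- strsplit(transitr::as_rna(a), "")[[1L]]
  bv <- strsplit(transitr::as_rna(b), "")[[1L]]
  n <- length(av)
  m <- length(bv)
  best <- 0
  rec <- function(pairs, i_min, j_max) {
    if (nrow(pairs) > 0L) {
      e <- score_pairing(a, b, pairs, params, temp_c, gu)
      if (e < best) best <<- e
    }
    if (i_min > n || j_max < 1L) return(invisible())
    for (i in i_min:n) {
      for (j in seq_len(j_max)) {
        if (transitr:::pair_allowed(av[i], bv[j], gu)) {
          rec(rbind(pairs, c(i, j)), i + 1L, j - 1L)
        }
      }
    }
  }
  rec(matrix(integer(), 0L, 2L), 1L, m)
  best
}

# Fisher p-values by exhaustive enumeration of all 2x2 tables with the
# observed margins, probabilities from exact binomial coefficients
bf_fisher <- function(a, b, c, d) {
  K <- a + c
  n <- a + b
  N <- a + b + c + d
  kmin <- max(0L, n - (N - K))
  kmax <- min(K, n)
  ks <- kmin:kmax
  probs <- vapply(ks, function(k) {
    choose(K, k) * choose(N - K, n - k) / choose(N, n)
  }, 0)
  pobs <- probs[ks == a]
  list(
    p_one_sided = sum(probs[ks >= a]),
    p_two_sided = min(1, sum(probs[probs <= pobs * (1 + 1e-9)]))
  )
}

# random RNA string
rand_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# tiny simulated world shared across tests (cheap: ~1 s); ... overrides
tiny_sim <- function(seed = 5L, ...) {
  args <- list(seed = seed, n_chrom = 1L, chrom_len = 60000L, n_genes = 25L,
               n_targets = 6L, ballast_loci = 5L, ballast_mean = 400)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
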