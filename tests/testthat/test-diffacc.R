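test_that("normalization factors behave per method", {
  counts <- matrix(c(10, 30, 20, 60, 40, 120, 8, 24), ncol = 2, byrow = TRUE)
  # equal library sizes -> equal effective sizes (total-count)
  eq <- normalize_factors(counts, c(s1 = 1e6, s2 = 1e6), "total-count")
  expect_equal(unname(eq$effective_sizes), c(1e6, 1e6))
  # per-million scaling differs by the library ratio
  tc <- normalize_factors(counts, c(s1 = 1e6, s2 = 2e6), "total-count")
  expect_equal(unname(tc$effective_sizes[2] / tc$effective_sizes[1]), 2)
  expect_error(normalize_factors(counts, c(s1 = 0, s2 = 1e6), "total-count"),
               "zero")

  # median-of-ratios on a no-DE matrix with one sample 3x the other:
  # factors ratio 3, geometric mean 1
  mor <- normalize_factors(counts, c(s1 = 1, s2 = 1), "median-of-ratios")
  expect_equal(unname(mor$factors[2] / mor$factors[1]), 3)
  expect_equal(exp(mean(log(mor$factors))), 1)
})

test_that("common dispersion is recovered and floors at zero", {
  groups <- c("a", "a", "b", "b")
  # identical replicates: zero within-group variance -> moments phi = 0
  y0 <- matrix(rep(c(5, 9, 40, 3), each = 4), ncol = 4, byrow = TRUE)
  expect_equal(
    estimate_common_dispersion(y0, groups, rep(1, 4), "moments")$phi, 0)

  set.seed(71)
  # Poisson data (phi = 0)
  yp <- matrix(rpois(2000 * 4, 100), ncol = 4)
  for (m in c("qcml", "moments")) {
    expect_lte(estimate_common_dispersion(yp, groups, rep(1, 4), m)$phi, 0.02)
  }
  # NB data phi = 0.2, mu = 100
  yn <- matrix(rnbinom(2000 * 4, size = 5, mu = 100), ncol = 4)
  for (m in c("qcml", "moments")) {
    phi <- estimate_common_dispersion(yn, groups, rep(1, 4), m)$phi
    expect_gte(phi, 0.15)
    expect_lte(phi, 0.25)
  }
})

test_that("exact NB test matches its closed forms and conventions", {
  # Poisson limit: (0,0) vs (5,5) conditional law Binomial(10, 1/2)
  p <- exact_nb_test(matrix(c(0, 0), 1), matrix(c(5, 5), 1),
                     c(1, 1), c(1, 1), phi = 0)
  expect_equal(p, 2 * choose(10, 0) / 2^10)

  # perfectly balanced split sits at the mode: p = 1
  expect_equal(exact_nb_test(matrix(c(3, 3), 1), matrix(c(3, 3), 1),
                             c(1, 1), c(1, 1), phi = 0), 1)

  # t = 0 convention
  expect_equal(exact_nb_test(matrix(c(0, 0), 1), matrix(c(0, 0), 1),
                             c(1, 1), c(1, 1), phi = 0.5), 1)

  expect_error(exact_nb_test(matrix(1), matrix(1), 1, 1, phi = -1), "phi")
})

test_that("exact NB test equals exhaustive conditional enumeration", {
  # all splits of small totals, over the dispersion grid
  for (phi in c(0, 0.5, 2)) {
    for (t in c(1, 4, 9, 12)) {
      for (sA in 0:t) {
        cA <- c(floor(sA / 2), ceiling(sA / 2))
        cB <- c(floor((t - sA) / 2), ceiling((t - sA) / 2))
        got <- exact_nb_test(matrix(cA, 1), matrix(cB, 1),
                             c(1, 1), c(1, 1), phi)
        expect_equal(got, bf_nb_cond_pval(cA, cB, phi), tolerance = 1e-10,
                     info = sprintf("phi=%g t=%d sA=%d", phi, t, sA))
      }
    }
  }
})

test_that("exact NB test is symmetric and monotone in extremity", {
  set.seed(4)
  for (i in 1:20) {
    cA <- rpois(2, 8)
    cB <- rpois(2, 8)
    phi <- sample(c(0, 0.3, 1), 1)
    pab <- exact_nb_test(matrix(cA, 1), matrix(cB, 1), c(1, 1), c(1, 1), phi)
    pba <- exact_nb_test(matrix(cB, 1), matrix(cA, 1), c(1, 1), c(1, 1), phi)
    expect_equal(pab, pba)
  }
  # moving one count from A to B on an already-extreme split (A below the
  # mode) never increases the p-value
  t <- 30L
  for (phi in c(0, 0.5)) {
    ps <- vapply(7:0, function(sA) {
      exact_nb_test(matrix(c(sA, 0), 1), matrix(c(t - sA, 0), 1),
                    c(1, 1), c(1, 1), phi)
    }, 0)
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("null calibration: fraction of p < 0.05 near nominal", {
  set.seed(99)
  y <- matrix(rnbinom(4000 * 4, size = 5, mu = 50), ncol = 4)
  p <- exact_nb_test(y[, 1:2], y[, 3:4], rep(1, 2), rep(1, 2), 0.2)
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("significance calls implement raw and BH policies", {
  res <- data.frame(p = c(0.049, 0.051, NA, 1))
  out <- call_significant(res, diff_config(alpha = 0.05, adjust = "none"))
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, FALSE))

  expect_equal(sum(call_significant(data.frame(p = rep(1, 10)),
                                    diff_config())$significant), 0L)

  # 100 p-values, 5 true signals at p <= 1e-6 survive BH
  set.seed(8)
  p <- c(rep(1e-6, 5), runif(95, 0.2, 1))
  bh <- call_significant(data.frame(p = p),
                         diff_config(alpha = 0.05, adjust = "BH"))
  expect_true(all(bh$significant[1:5]))
  expect_false(any(bh$significant[6:100]))
})

test_that("diff_accumulation wires windows, sizes and direction", {
  cfg <- tiny_sim()
  ref <- simulate_reference(cfg)
  rd <- simulate_reads(ref, cfg)
  wcfg <- window_config()
  win <- make_windows(setNames(nchar(ref$genome), names(ref$genome)), wcfg)
  wc <- count_reads(rd$reads, win, wcfg, samples = rd$samples)
  res <- diff_accumulation(wc, c("SKI2_RDR6_r1", "SKI2_RDR6_r2"),
                           c("ski2_RDR6_r1", "ski2_RDR6_r2"))
  expect_s3_class(res, "diff_results")
  expect_equal(nrow(res), nrow(win) * length(wc$sizes))
  expect_true(all(is.na(res$p) | (res$p > 0 & res$p <= 1)))
  # untested rows are never significant
  expect_false(any(res$significant[is.na(res$p)]))
  # phi attribute recorded and plausible for the simulated world
  expect_gte(attr(res, "phi"), 0)
  expect_error(diff_accumulation(wc, "nope", "ski2_RDR6_r1"), "unknown sample")
})
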