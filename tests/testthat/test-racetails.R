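REF <- "GGCAUCGAUUACGGAUCCAUGCAUGCUUA"  # toy 5'-cleavage fragment, 29 nt

test_that("tail extraction anchors at the 5' end and is maximal-templated", {
  # clone identical to the reference: untailed fragment
  rc <- extract_tail(REF, REF)
  expect_equal(rc$tail, "")
  expect_equal(rc$category, "fragment")
  expect_equal(rc$matched_len, nchar(REF))

  # full fragment plus UUU -> tail UUU
  rc2 <- extract_tail(paste0(REF, "UUU"), REF)
  expect_equal(rc2$tail, "UUU")

  # maximal-templated rule: reference ...GCAU, clone matching through
  # ...GCA then UU: the first U is templated, tail is the remaining U
  ref3 <- "GGCAUCGAUUACGGAUCCAUGCAUGGCAU"
  clone3 <- paste0(substr(ref3, 1, 28), "UU")  # ...GCA + UU
  rc3 <- extract_tail(clone3, ref3)
  expect_equal(rc3$matched_len, 29L)  # the 29th position U is templated
  expect_equal(rc3$tail, "U")

  # trimmed fragment with a tail
  rc4 <- extract_tail(paste0(substr(REF, 1, 24), "AA"), REF)
  expect_equal(rc4$matched_len, 24L)
  expect_equal(rc4$tail, "AA")

  # too-short match: non-fragment
  rc5 <- extract_tail(substr(REF, 1, 12), REF, min_match = 20)
  expect_equal(rc5$category, "non-fragment")

  expect_error(extract_tail("", REF), "empty")
})

test_that("uncleaved-mRNA clones are recognized via downstream context", {
  downstream <- "CCGAUGGAUCCGGAAUUCCGG"
  # clone continues past the reference 3' end with templated sequence
  unc <- paste0(REF, substr(downstream, 1, 8))
  rc <- extract_tail(unc, REF, downstream = downstream)
  expect_equal(rc$category, "non-fragment")
  # a genuine U tail is not mistaken for read-through (downstream starts C)
  tl <- extract_tail(paste0(REF, "UUUU"), REF, downstream = downstream)
  expect_equal(tl$category, "fragment")
  expect_equal(tl$tail, "UUUU")
  # without context the same clone is a (mis)tailed fragment, documented
  rc2 <- extract_tail(unc, REF)
  expect_equal(rc2$category, "fragment")
})

test_that("tail classes follow the dominant-nucleotide rule", {
  expect_equal(classify_tail("UUA"), "U")
  expect_equal(classify_tail("AAC"), "A")
  expect_equal(classify_tail("C"), "C")
  expect_equal(classify_tail("UCUAUUUUU"), "U")
  # tie goes to the first tail nucleotide
  expect_equal(classify_tail("UA"), "U")
  expect_equal(classify_tail("AU"), "A")
  expect_error(classify_tail(""), "empty")
})

test_that("summaries count tailed fragment clones and are order-invariant", {
  clones <- data.frame(
    tail = c("", "U", "UUA", "", "AA", ""),
    category = c("fragment", "fragment", "fragment", "fragment",
                 "fragment", "non-fragment"),
    stringsAsFactors = FALSE
  )
  s <- summarize_tails(clones)
  expect_equal(s$n_clones, 6L)
  expect_equal(s$n_fragment, 5L)
  expect_equal(s$n_tailed, 3L)
  expect_equal(s$spectrum[["UUA"]], 1L)
  expect_equal(unname(s$class_totals[c("U", "A")]), c(2L, 1L))

  set.seed(51)
  s2 <- summarize_tails(clones[sample(nrow(clones)), , drop = FALSE])
  expect_equal(s2[c("n_fragment", "n_tailed", "class_totals")],
               s[c("n_fragment", "n_tailed", "class_totals")])

  s0 <- summarize_tails(clones[0, , drop = FALSE])
  expect_equal(s0$n_tailed, 0L)
})

test_that("simulated clones round-trip exactly without trimming", {
  frag <- rand_rna(60)
  spec <- setNames(c(0.5, 0.2, 0.2, 0.1), c("", "U", "UUA", "AA"))
  race <- simulate_race_clones(frag, 120, tail_spectrum = spec, seed = 9)
  got <- vapply(race$clones, function(cl) extract_tail(cl, frag)$tail, "")
  expect_identical(unname(got), race$truth$tail)
})

test_that("trimming only ever shortens extracted tails", {
  # force the ambiguity: fragment ends in U, tails start with U
  frag <- paste0(rand_rna(40), "AUU")
  race <- simulate_race_clones(
    frag, 150, trim_dist = c("0" = 0.4, "1" = 0.3, "2" = 0.3),
    tail_spectrum = setNames(c(0.4, 0.6), c("", "UU")), seed = 10
  )
  got <- vapply(race$clones, function(cl) extract_tail(cl, frag)$tail, "")
  truth <- race$truth$tail
  for (i in seq_along(got)) {
    expect_true(nchar(got[i]) <= nchar(truth[i]) + race$truth$trim[i])
    if (got[i] != "") {
      # any recovered tail is a suffix of trimmed-reference + true tail
      full <- paste0(substr(frag, nchar(frag) - race$truth$trim[i] + 1,
                            nchar(frag)), truth[i])
      expect_true(grepl(paste0(got[i], "$"), full, fixed = FALSE) ||
                    got[i] == truth[i])
    }
    # mismatches happen only when the tail continues the reference
    if (got[i] != truth[i] && race$truth$trim[i] == 0L) {
      fail(sprintf("untrimmed clone %d changed tail: %s vs %s",
                   i, got[i], truth[i]))
    }
  }
})
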