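# Minimum hybridization free energy of two RNA strands under a
# nearest-neighbor model: intermolecular pairings only (no hairpins),
# stacks scored via dG(T) = dH - T*dS/1000, internal loops/bulges via a
# length-penalty table with Jacobson-Stockmayer extrapolation (treated as
# purely entropic, so scaled by T/310.15), terminal AU/GU penalties at the
# two outermost pairs, and one duplex-initiation term.  Salt correction is
# deliberately not modeled: only dG differences for the same miRNA under
# identical conditions are used downstream, and a uniform offset cancels.

GAS_CONSTANT <- 1.9872e-3  # kcal/(mol K)
T37 <- 310.15

#' Load a nearest-neighbor parameter set
#'
#' Reads the bundled (or a user-supplied) parameter TSV.  Stacks are keyed
#' `top/bottom` with `top` a 5'->3' dinucleotide and `bottom` the opposing
#' dinucleotide written 3'->5' (aligned; `bottom[k]` pairs `top[k]`);
#' symmetric orientations (reading the duplex from the other strand) are
#' expanded automatically.  Swapping tables requires no code change.
#'
#' @param path parameter TSV; default is the table shipped with the
#'   package.
#' @return list of class `nn_params`: `stacks` (named dH/dS lists),
#'   `init`, `terminal_au`, `loop_dG37` (length-indexed), `provenance`.
#' @export
nn_params <- function(path = system.file("extdata", "nn_params.tsv",
                                         package = "transitr")) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  prov <- grep("^#", readLines(path, n = 20L), value = TRUE)
  stacks <- new.env(parent = emptyenv())
  put <- function(key, dH, dS) {
    old <- get0(key, envir = stacks)
    if (!is.null(old) && (abs(old$dH - dH) > 1e-9 || abs(old$dS - dS) > 1e-9)) {
      stop("inconsistent symmetric stack entries for ", key)
    }
    assign(key, list(dH = dH, dS = dS), envir = stacks)
  }
  st <- tab[tab$type == "stack", , drop = FALSE]
  for (i in seq_len(nrow(st))) {
    kk <- strsplit(st$key[i], "/", fixed = TRUE)[[1L]]
    top <- strsplit(kk[1L], "")[[1L]]
    bot <- strsplit(kk[2L], "")[[1L]]
    put(st$key[i], st$dH[i], st$dS[i])
    # same physical stack read from the other strand:
    # top' = rev(bottom), bottom' = rev(top)
    sym <- paste0(bot[2L], bot[1L], "/", top[2L], top[1L])
    put(sym, st$dH[i], st$dS[i])
  }
  ini <- tab[tab$type == "init", ]
  ter <- tab[tab$type == "terminal_au", ]
  lo <- tab[tab$type == "loop", ]
  structure(
    list(
      stacks = stacks,
      init = list(dH = ini$dH[1L], dS = ini$dS[1L]),
      terminal_au = list(dH = ter$dH[1L], dS = ter$dS[1L]),
      loop_dG37 = setNames(lo$dG37, lo$key),
      provenance = prov
    ),
    class = "nn_params"
  )
}

pair_type <- function(x, y) paste0(x, y)

is_wc <- function(x, y) pair_type(x, y) %in% c("AU", "UA", "GC", "CG")
is_gu <- function(x, y) pair_type(x, y) %in% c("GU", "UG")

pair_allowed <- function(x, y, gu = TRUE) {
  is_wc(x, y) | (gu & is_gu(x, y))
}

dG_of <- function(hs, temp_k) hs$dH - temp_k * hs$dS / 1000

stack_dG <- function(params, a1, b1, a2, b2, temp_k) {
  key <- paste0(a1, a2, "/", b1, b2)
  hs <- get0(key, envir = params$stacks)
  if (is.null(hs)) stop("no stack parameters for ", key)
  dG_of(hs, temp_k)
}

loop_dG <- function(params, len, temp_k) {
  tab <- params$loop_dG37
  nmax <- length(tab)
  g37 <- if (len <= nmax) {
    tab[[as.character(len)]]
  } else {
    tab[[as.character(nmax)]] +
      1.75 * GAS_CONSTANT * T37 * log(len / nmax)
  }
  g37 * temp_k / T37  # loops treated as purely entropic
}

terminal_dG <- function(params, a, b, temp_k) {
  if (pair_type(a, b) %in% c("AU", "UA", "GU", "UG")) {
    dG_of(params$terminal_au, temp_k)
  } else {
    0
  }
}

#' Score a fixed intermolecular pairing
#'
#' Energy of a given antiparallel pairing between strands `a` and `b`
#' under the same model as [duplex_dG()]: initiation + stacks/loops
#' between consecutive pairs + terminal penalties on the two outermost
#' pairs.  Used both by the dynamic program's traceback and as the shared
#' scoring for brute-force verification.
#'
#' @param a,b RNA strands (character scalars, 5'->3').
#' @param pairs integer matrix with columns `i` (position in `a`) and `j`
#'   (position in `b`), 1-based; rows must have strictly increasing i and
#'   strictly decreasing j (antiparallel, non-crossing).
#' @param params an [nn_params()] set.
#' @param temp_c temperature in Celsius (default 21).
#' @param gu allow G.U wobble pairs (default TRUE)?
#' @return energy in kcal/mol (+Inf for an invalid pairing).
#' @export
score_pairing <- function(a, b, pairs, params = nn_params(), temp_c = 21,
                          gu = TRUE) {
  temp_k <- temp_c + 273.15
  av <- strsplit(as_rna(a), "")[[1L]]
  bv <- strsplit(as_rna(b), "")[[1L]]
  if (nrow(pairs) == 0L) return(0)
  i <- pairs[, 1L]
  j <- pairs[, 2L]
  if (any(diff(i) <= 0L) || any(diff(j) >= 0L)) return(Inf)
  if (!all(pair_allowed(av[i], bv[j], gu))) return(Inf)
  e <- dG_of(params$init, temp_k)
  e <- e + terminal_dG(params, av[i[1L]], bv[j[1L]], temp_k)
  n <- nrow(pairs)
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      gap <- (i[k + 1L] - i[k] - 1L) + (j[k] - j[k + 1L] - 1L)
      e <- e + if (gap == 0L) {
        stack_dG(params, av[i[k]], bv[j[k]], av[i[k + 1L]], bv[j[k + 1L]], temp_k)
      } else {
        loop_dG(params, gap, temp_k)
      }
    }
  }
  e + terminal_dG(params, av[i[n]], bv[j[n]], temp_k)
}

#' Minimum hybridization free energy of two RNA strands
#'
#' Dynamic program over intermolecular pairings only (no intramolecular
#' structure).  Returns the minimum free energy at temperature `temp_c`
#' and one optimal pairing trace.  If no pairing achieves dG < 0, the
#' result is "no duplex": dG = 0 with an empty trace.
#'
#' @param a,b RNA strands (character scalars, 5'->3'; T is read as U).
#' @param params an [nn_params()] set.
#' @param temp_c temperature in Celsius (default 21, i.e. 294.15 K).
#' @param gu allow G.U wobble pairs (default TRUE)?
#' @return list of class `duplex_result`: `dG` (kcal/mol), `trace`
#'   (integer matrix of paired 1-based indices `i`,`j`, antiparallel),
#'   `temp_k`.
#' @export
duplex_dG <- function(a, b, params = nn_params(), temp_c = 21, gu = TRUE) {
  temp_k <- temp_c + 273.15
  av <- strsplit(as_rna(a), "")[[1L]]
  bv <- strsplit(as_rna(b), "")[[1L]]
  n <- length(av)
  m <- length(bv)
  if (n < 1L || m < 1L) stop("strands must have length >= 1")
  init <- dG_of(params$init, temp_k)

  can <- outer(seq_len(n), seq_len(m),
               function(i, j) pair_allowed(av[i], bv[j], gu))
  # E[i, j]: best energy of a duplex whose 3'-most pair on `a` is (i, j),
  # including initiation and the 5'-terminal penalty but not the final one
  E <- matrix(Inf, n, m)
  from_i <- matrix(NA_integer_, n, m)
  from_j <- matrix(NA_integer_, n, m)
  # precomputed loop penalties by total gap length
  max_gap <- n + m
  loopv <- vapply(seq_len(max_gap), function(g) loop_dG(params, g, temp_k), 0)

  for (i in seq_len(n)) {
    for (j in rev(seq_len(m))) {
      if (!can[i, j]) next
      best <- init + terminal_dG(params, av[i], bv[j], temp_k)
      bi <- NA_integer_
      bj <- NA_integer_
      if (i > 1L && j < m) {
        for (ip in seq_len(i - 1L)) {
          for (jp in (j + 1L):m) {
            if (!is.finite(E[ip, jp])) next
            gap <- (i - ip - 1L) + (jp - j - 1L)
            cost <- if (gap == 0L) {
              stack_dG(params, av[ip], bv[jp], av[i], bv[j], temp_k)
            } else {
              loopv[gap]
            }
            cand <- E[ip, jp] + cost
            if (cand < best) {
              best <- cand
              bi <- ip
              bj <- jp
            }
          }
        }
      }
      E[i, j] <- best
      from_i[i, j] <- bi
      from_j[i, j] <- bj
    }
  }
  final <- E
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (is.finite(final[i, j])) {
        final[i, j] <- final[i, j] + terminal_dG(params, av[i], bv[j], temp_k)
      }
    }
  }
  best <- min(final)
  if (!is.finite(best) || best >= 0) {
    return(structure(
      list(dG = 0, trace = matrix(integer(), 0L, 2L,
                                  dimnames = list(NULL, c("i", "j"))),
           temp_k = temp_k),
      class = "duplex_result"
    ))
  }
  idx <- which(final == best, arr.ind = TRUE)[1L, ]
  trace <- list()
  i <- idx[[1L]]
  j <- idx[[2L]]
  while (!is.na(i)) {
    trace[[length(trace) + 1L]] <- c(i, j)
    ii <- from_i[i, j]
    jj <- from_j[i, j]
    i <- ii
    j <- jj
  }
  tr <- do.call(rbind, rev(trace))
  colnames(tr) <- c("i", "j")
  structure(list(dG = best, trace = tr, temp_k = temp_k),
            class = "duplex_result")
}

#' @export
print.duplex_result <- function(x, ...) {
  cat("duplex dG =", format(x$dG, digits = 4), "kcal/mol at",
      x$temp_k, "K;", nrow(x$trace), "pairs\n")
  invisible(x)
}

#' Pairing energies of the miRNA halves against the two cleavage fragments
#'
#' Splits the target site at the cleavage coordinate (cleavemap
#' convention: the nucleotide paired to miRNA position 10 starts the 3'
#' fragment) and computes `dG5`, the hybridization energy of the miRNA 3'
#' half (positions 11..L) with the site region on the 5'-cleavage
#' fragment, and `dG3`, the energy of the miRNA 5' half (positions 1..10)
#' with the site region on the 3'-cleavage fragment.  A `full` mode uses
#' the full-length miRNA against each region instead.
#'
#' @param mirna miRNA sequence, 5'->3' RNA.
#' @param site_seq target-site sequence on the transcript, 5'->3' RNA.
#' @param cleavage_offset 0-based offset of the cleavage coordinate within
#'   the site (first nucleotide of the 3'-fragment part); the cleavemap
#'   convention gives `length(site) - 10`.
#' @param params an [nn_params()] set.
#' @param temp_c temperature in Celsius (default 21).
#' @param mode `"halves"` (default) or `"full"`.
#' @param gu allow G.U pairs?
#' @return list of class `fragment_energies`: `dG5`, `dG3`, `ddG`
#'   (= dG5 - dG3), `temp_k`, `mode`.
#' @export
fragment_energies <- function(mirna, site_seq, cleavage_offset,
                              params = nn_params(), temp_c = 21,
                              mode = c("halves", "full"), gu = TRUE) {
  mode <- match.arg(mode)
  mirna <- as_rna(mirna)
  site_seq <- as_rna(site_seq)
  L <- nchar(mirna)
  slen <- nchar(site_seq)
  if (cleavage_offset <= 0L || cleavage_offset >= slen) {
    stop("cleavage offset inconsistent with site length")
  }
  frag5 <- substr(site_seq, 1L, cleavage_offset)          # on 5' fragment
  frag3 <- substr(site_seq, cleavage_offset + 1L, slen)   # on 3' fragment
  if (mode == "halves") {
    if (L < 11L) stop("miRNA shorter than 11 nt")
    mir5half <- substr(mirna, 1L, 10L)
    mir3half <- substr(mirna, 11L, L)
    dG5 <- duplex_dG(mir3half, frag5, params, temp_c, gu)$dG
    dG3 <- duplex_dG(mir5half, frag3, params, temp_c, gu)$dG
  } else {
    dG5 <- duplex_dG(mirna, frag5, params, temp_c, gu)$dG
    dG3 <- duplex_dG(mirna, frag3, params, temp_c, gu)$dG
  }
  structure(
    list(dG5 = dG5, dG3 = dG3, ddG = dG5 - dG3,
         temp_k = temp_c + 273.15, mode = mode),
    class = "fragment_energies"
  )
}
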