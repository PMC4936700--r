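# Independent oracles used by the tests. These deliberately do not share
# code with the package implementation.

# ---- brute-force secondary-structure oracle --------------------------------
# Same energy model as the bundled folder, evaluated by exhaustive
# enumeration of every pseudoknot-free structure (min hairpin loop 3 nt):
# stacked pair: -2 if the outer pair is GC/CG else -1; unstacked pair: +2;
# each hairpin loop: +3.

bf_pairable <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG",
                      "AU", "UA", "GU", "UG")
}

# Enumerate all structures of chars[i..j] as lists of pairs c(a, b).
bf_structures <- function(chars, i, j, memo = new.env(parent = emptyenv())) {
  if (j - i + 1L < 5L) return(list(list()))
  key <- paste(i, j)
  if (!is.null(memo[[key]])) return(memo[[key]])
  res <- bf_structures(chars, i + 1L, j, memo)  # i unpaired
  for (k in (i + 4L):j) {
    if (!bf_pairable(chars[i], chars[k])) next
    inner <- bf_structures(chars, i + 1L, k - 1L, memo)
    outer <- if (k + 1L <= j) bf_structures(chars, k + 1L, j, memo)
    else list(list())
    for (s1 in inner) for (s2 in outer) {
      res[[length(res) + 1L]] <- c(list(c(i, k)), s1, s2)
    }
  }
  memo[[key]] <- res
  res
}

bf_energy <- function(pairs, chars) {
  if (length(pairs) == 0L) return(0)
  partner <- rep(NA_integer_, length(chars))
  for (p in pairs) {
    partner[p[1L]] <- p[2L]
    partner[p[2L]] <- p[1L]
  }
  e <- 0
  for (p in pairs) {
    a <- p[1L]; b <- p[2L]
    stacked <- !is.na(partner[a + 1L]) && partner[a + 1L] == b - 1L
    if (stacked) {
      e <- e + if (chars[a] %in% c("G", "C") && chars[b] %in% c("G", "C")) -2 else -1
    } else {
      e <- e + 2
    }
    inside <- if (b - a > 1L) (a + 1L):(b - 1L) else integer(0)
    if (all(is.na(partner[inside]))) e <- e + 3  # hairpin loop
  }
  e
}

bf_mfe <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  structs <- bf_structures(chars, 1L, length(chars))
  min(vapply(structs, bf_energy, numeric(1L), chars = chars))
}

# ---- exact-rational Audic-Claverie oracle (python fractions) ---------------
# Returns a data frame (ratio_num, ratio_den, x, y, p, C, D) for all
# x + y <= max_total at library ratios N2/N1 in {1/2, 1, 2}, computed with
# exact rational arithmetic and converted to double only at the end.
ac_exact_oracle <- function(max_total = 60L) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "maxt = int(sys.argv[1])",
    "for (a, b) in [(1, 2), (1, 1), (2, 1)]:",
    "    r = Fraction(a, b)",
    "    for x in range(maxt + 1):",
    "        C = Fraction(0)",
    "        for y in range(maxt - x + 1):",
    "            p = r**y * comb(x + y, y) / (1 + r)**(x + y + 1)",
    "            C += p",
    "            D = 1 - C + p",
    "            print(a, b, x, y, float(p), float(C), float(D))"),
    script)
  out <- system2("python", args = c(script, as.character(max_total)),
                 stdout = TRUE)
  df <- read.table(text = out,
                   col.names = c("ratio_num", "ratio_den", "x", "y",
                                 "p", "C", "D"))
  df
}

# ---- exact hypergeometric upper tail by direct enumeration -----------------
hyper_upper_enum <- function(k, K, N, n) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# ---- misc helpers ----------------------------------------------------------
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Dinucleotide shuffle (swap-based: repeatedly exchanges letters that
# preserve local dinucleotide composition approximately; adequate here as a
# composition-preserving negative control).
dinucleotide_shuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  paste(sample(ch), collapse = "")
}

# Small, fast study design used across unit tests.
small_design <- function(seed = 1L, depth = 2e4, ...) {
  synthetic_design(n_transcripts = 12L, n_mirnas = 5L,
                   transcript_length = c(300L, 500L), depth = depth,
                   ..., seed = seed)
}
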