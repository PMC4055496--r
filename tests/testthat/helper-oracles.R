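# Independent oracles and small generators used across the suite.

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# substitute exactly k sites of a sequence (distinct positions). With
# `interior = TRUE` the first/last base are left untouched: a terminal
# mismatch can be realigned as a free end gap by the semi-global aligner,
# so only interior substitutions make the ungapped (hamming) identity a
# valid oracle for the alignment identity.
substitute_sites <- function(seq, k, interior = FALSE) {
  ch <- strsplit(seq, "")[[1]]
  cand <- if (interior) seq(2, length(ch) - 1) else seq_along(ch)
  pos <- cand[sample(length(cand), k)]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Exhaustive-recursion oracle for the semi-global alignment score:
# enumerates every start/end boundary allowed by free end gaps and scores the
# enclosed global alignment by plain recursion (no DP shared with the
# implementation). Only viable for short sequences.
brute_semiglobal_score <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  ACGT <- c("A", "C", "G", "T")
  glob <- function(i, j, i2, j2) {
    if (i > i2 && j > j2) return(0)
    if (i > i2) return(-2 * (j2 - j + 1))
    if (j > j2) return(-2 * (i2 - i + 1))
    s <- if (A[i] == B[j] && A[i] %in% ACGT) 1 else -1
    max(glob(i + 1, j + 1, i2, j2) + s,
        glob(i + 1, j, i2, j2) - 2,
        glob(i, j + 1, i2, j2) - 2)
  }
  best <- -Inf
  for (i1 in 1:(n + 1)) for (j1 in 1:(m + 1)) {
    if (i1 > 1 && j1 > 1) next          # only one free leading end gap
    for (i2 in (i1 - 1):n) for (j2 in (j1 - 1):m) {
      if (i2 < n && j2 < m) next        # only one free trailing end gap
      best <- max(best, glob(i1, j1, i2, j2))
    }
  }
  best
}

# small panel with two well-separated groups plus congeners, built by
# explicit substitution so that every pairwise identity is known exactly
toy_panel <- function(len = 400, seed = 11) {
  set.seed(seed)
  base <- random_seq(len)
  spA <- base
  spB <- substitute_sites(base, round(0.04 * len), interior = TRUE)
  spC <- substitute_sites(base, round(0.20 * len), interior = TRUE)
  reference_panel(data.frame(
    id = c("rA", "rA2", "rB", "rC"),
    species = c("Alpha_one", "Alpha_two", "Beta_one", "Gamma_one"),
    group = c("alpha", "alpha", "beta", "gamma"),
    seq = c(spA, spA, spB, spC), stringsAsFactors = FALSE))
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
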