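# shared fixtures built in code

# a protein with two coiled-coil domains and known registers
heptadProtein <- function(id = "hp", nHept = 3L, linker = 10L,
                          species = "spX") {
  dom <- strrep("LIEKLAS", nHept)     # registers a..g cycling
  lnk <- strrep("GSTNPQD", ceiling(linker / 7))
  lnk <- substr(lnk, 1, linker)
  seqStr <- paste0(lnk, dom, lnk, dom, lnk)
  n <- nchar(seqStr)
  prob <- rep(0.05, n)
  reg <- rep("-", n)
  d1 <- linker + seq_len(7 * nHept)
  d2 <- 2 * linker + 7 * nHept + seq_len(7 * nHept)
  prob[c(d1, d2)] <- 0.95
  reg[c(d1, d2)] <- rep(REGS7, 2 * nHept)
  CCProtein(id, seqStr, prob, reg, species = species)
}

REGS7 <- letters[1:7]

randomProtein <- function(id, len, alphabet = c("A", "C", "G", "T")) {
  # reduced alphabet keeps the exhaustive oracle tractable; these are
  # still valid amino-acid letters
  CCProtein(id, paste(sample(alphabet, len, replace = TRUE),
                      collapse = ""))
}

# independent brute-force local aligner: enumerates alignments
# recursively (no DP tables), affine gaps cost open+extend on the first
# gapped position; only feasible for very short strings
bruteLocalScore <- function(a, b, mat, open, extend) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- 0
  # global score of a[i1..i2] vs b[j1..j2] by exhaustive recursion
  rec <- function(i, i2, j, j2, state) {
    if (i > i2 && j > j2) return(0)
    sc <- -Inf
    if (i <= i2 && j <= j2)
      sc <- max(sc, mat[a[i], b[j]] + rec(i + 1, i2, j + 1, j2, 0L))
    if (i <= i2)
      sc <- max(sc, -(if (state == 1L) extend else open + extend) +
                  rec(i + 1, i2, j, j2, 1L))
    if (j <= j2)
      sc <- max(sc, -(if (state == 2L) extend else open + extend) +
                  rec(i, i2, j + 1, j2, 2L))
    sc
  }
  for (i1 in seq_along(a)) for (i2 in i1:length(a))
    for (j1 in seq_along(b)) for (j2 in j1:length(b))
      best <- max(best, rec(i1, i2, j1, j2, 0L))
  best
}
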