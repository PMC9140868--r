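# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check.

# Brute-force degenerate-primer scan: explicit per-position set expansion,
# no bit masks.
brute_scan <- function(subject, primer, max_mismatch = 2L,
                       three_prime_exact = 3L) {
  expand <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))
  match1 <- function(p, t) t %in% expand[[p]]   # target N matches nothing
  one_strand <- function(pat, strand) {
    k <- nchar(pat)
    pch <- strsplit(pat, "")[[1L]]
    sch <- strsplit(subject, "")[[1L]]
    out <- NULL
    for (o in seq_len(max(0L, nchar(subject) - k + 1L))) {
      ok <- vapply(seq_len(k), function(p) match1(pch[p], sch[o + p - 1L]),
                   logical(1L))
      mm <- sum(!ok)
      idx3 <- if (strand == "+") (k - three_prime_exact + 1L):k
              else seq_len(three_prime_exact)
      if (mm <= max_mismatch && all(ok[idx3]))
        out <- rbind(out, data.frame(strand = strand,
                                     pos5 = if (strand == "+") o
                                            else o + k - 1L,
                                     mismatches = mm))
    }
    out
  }
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(primer)))
  res <- rbind(one_strand(primer, "+"), one_strand(rc, "-"))
  if (is.null(res)) data.frame(strand = character(), pos5 = integer(),
                               mismatches = integer())
  else res[order(res$pos5, res$strand), , drop = FALSE]
}

# Exhaustive Smith-Waterman under the package's fixed scoring, via
# Biostrings (full dynamic programming, no seeding).
sw_oracle <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  list(score = Biostrings::score(al),
       qstart = al@pattern@range@start,
       qend = al@pattern@range@start + al@pattern@range@width - 1L,
       sstart = al@subject@range@start,
       send = al@subject@range@start + al@subject@range@width - 1L)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# plant `what` into `where` at position `at` (1-based), returning the string
plant_at <- function(where, at, what) {
  substr(where, at, at + nchar(what) - 1L) <- what
  where
}
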