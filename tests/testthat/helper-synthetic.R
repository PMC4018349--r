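# Shared fixtures and small oracles, all built in code at test time.

# Amino-acid alphabet safe for random precursor cargo: no basics (K, R), so
# random peptides can never contain or create a dibasic site, and no M so
# ORF-boundary reasoning stays unambiguous in round-trip tests.
CARGO_ALPHABET <- strsplit("ACDEFGHILNPQSTVWY", "")[[1]]

random_peptides <- function(n, len_range = c(5L, 15L)) {
  vapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1L)
    paste(sample(CARGO_ALPHABET, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Independent six-frame translation oracle (plain codon table, no Biostrings).
CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(bases, as.vector(t(outer(bases, bases, paste0))), paste0)))
  setNames(aas, codons)
})

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Brute-force best global alignment score by enumerating all alignments of
# two short strings (exponential; only for tiny inputs).
oracle_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# Exact two-sided permutation p-value for a 2-vs-2 mean difference.
oracle_permutation_p <- function(brain, eyestalk) {
  vals <- c(brain, eyestalk)
  obs <- abs(mean(eyestalk) - mean(brain))
  combos <- utils::combn(4L, 2L)
  diffs <- apply(combos, 2L, function(idx) {
    abs(mean(vals[-idx]) - mean(vals[idx]))
  })
  mean(diffs >= obs - 1e-12)
}

table2_family <- function(fam) {
  t2 <- load_study_tables("table2")
  t2[t2$family == fam, , drop = FALSE]
}
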