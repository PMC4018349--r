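#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment under a linear gap model with a fully specified,
#' deterministic traceback (diagonal preferred over up over left), so identity
#' counts are reproducible. The default scores (match +1, mismatch 0, gap -1)
#' make the alignment score a simple identity count for the near-identical,
#' equal-length peptide sets this package deals in, where no gaps arise and
#' identity is therefore parameter-independent.
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param match,mismatch,gap Scores for the linear model.
#' @return An object of class `np_alignment`: list with `seq_a_aligned`,
#'   `seq_b_aligned` (equal-length gapped strings), `score`,
#'   `identical_positions`, `identity_pct` (over aligned length) and `length`.
#' @examples
#' aln <- global_align("NAELINSILGLPKVMNDA", "NAELINSLLGIPKVMSDA")
#' aln$identical_positions # 15 of 18
#' @export
global_align <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  if (nchar(a) == 0L || nchar(b) == 0L) stopf("global_align: empty input sequence")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1L, m + 1L)
  S[1L, ] <- gap * (0:m)
  S[, 1L] <- gap * (0:n)
  for (i in seq_len(n)) {
    sub <- ifelse(av[i] == bv, match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j], S[i, j + 1L] + gap, S[i + 1L, j] + gap)
    }
  }
  # traceback, diagonal > up > left on ties
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + ifelse(av[i] == bv[j], match, mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }
  ident <- sum(ra == rb & ra != "-")
  structure(list(
    seq_a_aligned = paste(ra, collapse = ""),
    seq_b_aligned = paste(rb, collapse = ""),
    score = S[n + 1L, m + 1L],
    identical_positions = ident,
    identity_pct = 100 * ident / length(ra),
    length = length(ra)
  ), class = "np_alignment")
}

#' @export
print.np_alignment <- function(x, ...) {
  cat(x$seq_a_aligned, "\n")
  cat(ifelse(strsplit(x$seq_a_aligned, "")[[1]] == strsplit(x$seq_b_aligned, "")[[1]],
             "|", " "), "\n", sep = "")
  cat(x$seq_b_aligned, "\n")
  cat(sprintf("score %g, %d/%d identical (%.1f%%)\n",
              x$score, x$identical_positions, x$length, x$identity_pct))
  invisible(x)
}

#' @method glance np_alignment
#' @export
glance.np_alignment <- function(x, ...) {
  tibble(score = x$score, length = x$length,
         identical_positions = x$identical_positions,
         identity_pct = x$identity_pct)
}

#' Percent identity between two peptides
#'
#' Symmetric pairwise identity over the aligned length of the optimal global
#' alignment.
#'
#' @inheritParams global_align
#' @return A number in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  global_align(a, b, match, mismatch, gap)$identity_pct
}

#' Strict consensus motif of a peptide set
#'
#' Summarises a family of peptides column by column: a column keeps its
#' residue only when it is invariant across ALL members; every other column
#' becomes `X`. This matches how conserved-motif boxes are drawn for
#' neuropeptide families (only fully conserved letters are spelled out). If
#' all members are amidated, the consensus carries an `amide` suffix. Members
#' of unequal length are mapped onto the modal-length member via pairwise
#' global alignment first; a length spread beyond `gap_budget` is refused,
#' naming the outliers.
#'
#' @param peptides Character vector (>= 2) or tibble with `sequence` and
#'   optionally `amidated`.
#' @param amidated Logical vector (recycled) when `peptides` is a character
#'   vector.
#' @param gap_budget Maximum tolerated deviation from the modal length.
#' @return Object of class `np_consensus`: list with `consensus` (string over
#'   residues and `X`), `amide` (logical), `members`, `n_invariant`.
#' @export
consensus_motif <- function(peptides, amidated = FALSE, gap_budget = 5L) {
  if (is.data.frame(peptides)) {
    amidated <- peptides[["amidated"]] %||% FALSE
    peptides <- peptides$sequence
  }
  if (length(peptides) < 2L) stopf("consensus needs at least 2 peptides")
  amidated <- rep_len(amidated, length(peptides))
  lens <- nchar(peptides)
  modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1L])
  off <- abs(lens - modal) > gap_budget
  if (any(off)) {
    stopf("peptides beyond the gap budget of %d relative to modal length %d: %s",
          gap_budget, modal, paste(peptides[off], collapse = ", "))
  }
  ref <- peptides[which(lens == modal)[1L]]
  mat <- matrix("", nrow = length(peptides), ncol = modal)
  for (i in seq_along(peptides)) {
    if (nchar(peptides[i]) == modal && peptides[i] == ref) {
      mat[i, ] <- strsplit(peptides[i], "")[[1]]
    } else {
      aln <- global_align(ref, peptides[i])
      ra <- strsplit(aln$seq_a_aligned, "")[[1]]
      rb <- strsplit(aln$seq_b_aligned, "")[[1]]
      mat[i, ] <- rb[ra != "-"][seq_len(modal)]
    }
  }
  cols <- apply(mat, 2L, function(col) if (length(unique(col)) == 1L) col[1L] else "X")
  cols[cols == "-"] <- "X"
  structure(list(
    consensus = paste(cols, collapse = ""),
    amide = all(amidated),
    members = peptides,
    n_invariant = sum(cols != "X")
  ), class = "np_consensus")
}

#' @export
print.np_consensus <- function(x, ...) {
  cat(sprintf("%s%s  (%d members, %d/%d invariant columns)\n",
              x$consensus, if (x$amide) "amide" else "",
              length(x$members), x$n_invariant, nchar(x$consensus)))
  invisible(x)
}

#' Identity-based distance matrix for a peptide set
#'
#' Pairwise p-distances `d = 1 - identity/100` from global alignments.
#'
#' @param peptides Named character vector or tibble with `subject_id` and
#'   `sequence`.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
identity_distances <- function(peptides) {
  if (is.data.frame(peptides)) {
    peptides <- setNames(peptides$sequence, peptides$subject_id)
  }
  if (is.null(names(peptides))) names(peptides) <- peptides
  n <- length(peptides)
  d <- matrix(0, n, n, dimnames = list(names(peptides), names(peptides)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) {
      d[i, j] <- d[j, i] <- 1 - pairwise_identity(peptides[[i]], peptides[[j]]) / 100
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (exact on additive matrices), with the
#' common post-processing for non-additive input: negative branch lengths are
#' clamped to zero and the deficit moved onto the sister branch so the total
#' tree length is preserved.
#'
#' @param labels Taxon labels (>= 3).
#' @param distances Symmetric distance matrix with zero diagonal (or a `dist`).
#' @return Object of class `np_njtree`: list with `tree` (an [ape::nj] phylo),
#'   `newick` (serialised string), `labels` and `distances`.
#' @export
nj_tree <- function(labels, distances) {
  d <- as.matrix(distances)
  if (length(labels) < 3L) stopf("neighbor joining needs at least 3 taxa")
  if (nrow(d) != length(labels) || ncol(d) != length(labels)) {
    stopf("distance matrix must be %d x %d", length(labels), length(labels))
  }
  if (max(abs(d - t(d))) > 1e-8) stopf("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stopf("distance matrix diagonal must be zero")
  dimnames(d) <- list(labels, labels)
  phy <- ape::nj(d)
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    parent <- phy$edge[e, 1L]
    sisters <- setdiff(which(phy$edge[, 1L] == parent), e)
    if (length(sisters) > 0L) {
      phy$edge.length[sisters[1L]] <- phy$edge.length[sisters[1L]] + phy$edge.length[e]
    }
    phy$edge.length[e] <- 0
  }
  structure(list(
    tree = phy,
    newick = ape::write.tree(phy),
    labels = labels,
    distances = d
  ), class = "np_njtree")
}

#' @export
print.np_njtree <- function(x, ...) {
  cat("Neighbor-joining tree,", length(x$labels), "taxa\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Path-length (cophenetic) distances implied by a tree
#'
#' @param x An `np_njtree`.
#' @return Symmetric matrix of tree path lengths between taxa.
#' @export
tree_path_distances <- function(x) {
  stopifnot(inherits(x, "np_njtree"))
  m <- ape::cophenetic.phylo(x$tree)
  m[x$labels, x$labels]
}
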