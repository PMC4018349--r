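test_that("the two printed PDH peptides share 15 of 18 positions", {
  aln <- global_align("NAELINSILGLPKVMNDA", "NAELINSLLGIPKVMSDA")
  expect_equal(aln$length, 18L)
  expect_equal(aln$identical_positions, 15L)
  expect_equal(aln$identity_pct, 100 * 15 / 18)
  expect_false(grepl("-", aln$seq_a_aligned))
})

test_that("self-alignment and the enumerated gap case behave as scored", {
  x <- "SYWKQCAFNAVSCF"
  expect_equal(global_align(x, x)$identity_pct, 100)
  # AAA vs AA with gap -2, match +1: two matches and one gap column
  aln <- global_align("AAA", "AA", match = 1, mismatch = 0, gap = -2)
  expect_equal(aln$score, 1 * 2 - 2)
  expect_equal(nchar(aln$seq_a_aligned), 3L)
  expect_equal(stringr::str_count(aln$seq_b_aligned, "-"), 1L)
  expect_error(global_align("", "AA"), "empty")
})

test_that("alignment scores match a brute-force enumeration oracle", {
  withr::local_seed(5)
  for (rep in 1:40) {
    a <- paste(sample(c("A", "C", "G", "W"), sample(2:6, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "W"), sample(2:6, 1), replace = TRUE),
               collapse = "")
    expect_equal(global_align(a, b, gap = -1)$score,
                 oracle_align_score(a, b, gap = -1), info = paste(a, b))
  }
})

test_that("alignment score agrees with the Biostrings dynamic programme", {
  withr::local_seed(17)
  mat <- matrix(0, 20, 20, dimnames = list(Biostrings::AA_STANDARD,
                                           Biostrings::AA_STANDARD))
  diag(mat) <- 1
  for (rep in 1:25) {
    a <- paste(sample(Biostrings::AA_STANDARD, sample(5:25, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(Biostrings::AA_STANDARD, sample(5:25, 1), replace = TRUE),
               collapse = "")
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 1)
    expect_equal(global_align(a, b)$score, Biostrings::score(ref),
                 info = paste(a, b))
  }
})

test_that("identity is symmetric", {
  withr::local_seed(9)
  for (rep in 1:30) {
    a <- paste(sample(c("A", "D", "W", "L", "S"), sample(4:12, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "D", "W", "L", "S"), sample(4:12, 1), replace = TRUE),
               collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("consensus keeps invariant columns and Xs the rest", {
  pdh <- consensus_motif(c("NAELINSILGLPKVMNDA", "NAELINSLLGIPKVMSDA"),
                         amidated = TRUE)
  expect_equal(nchar(pdh$consensus), 18L)
  expect_equal(pdh$n_invariant, 15L)
  expect_equal(stringr::str_count(pdh$consensus, "X"), 3L)
  expect_true(pdh$amide)

  tachy <- consensus_motif(rep("APSGFLGMR", 7), amidated = TRUE)
  expect_equal(tachy$consensus, "APSGFLGMR")
  expect_equal(stringr::str_count(tachy$consensus, "X"), 0L)

  expect_equal(consensus_motif(c("AB", "CB"))$consensus, "XB")
  # idempotence: duplicating the member set changes nothing
  orig <- consensus_motif(c("ADWNKFHGSW", "ANWNKFHGSW"))
  dup <- consensus_motif(rep(c("ADWNKFHGSW", "ANWNKFHGSW"), 2))
  expect_equal(orig$consensus, dup$consensus)
  expect_error(consensus_motif(c("AAAA", "AAAAAAAAAAAAAA")), "gap budget")
})

test_that("neighbor joining is exact on additive matrices", {
  # three taxa: closed-form branch lengths (1, 1, 2)
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(c("A", "B", "C"), d3)
  lens <- sort(tr$tree$edge.length)
  expect_equal(lens, c(1, 1, 2))
  expect_equal(tree_path_distances(tr), d3, tolerance = 1e-9)

  # four taxa from a known topology ((A,B),(C,D)) with internal branch 1
  bl <- c(A = 1, B = 2, C = 3, D = 4)
  d4 <- matrix(0, 4, 4, dimnames = list(names(bl), names(bl)))
  for (i in names(bl)) for (j in names(bl)) {
    if (i != j) {
      inner <- if ((i %in% c("A", "B")) == (j %in% c("A", "B"))) 0 else 1
      d4[i, j] <- bl[i] + bl[j] + inner
    }
  }
  tr4 <- nj_tree(names(bl), d4)
  expect_equal(tree_path_distances(tr4), d4, tolerance = 1e-9)
  # recovered split is AB|CD: brute-force check over the three possibilities
  splits <- ape::prop.part(tr4$tree)
  pair <- sort(attr(splits, "labels")[splits[[2]]])
  expect_true(identical(pair, c("A", "B")) || identical(pair, c("C", "D")))
  expect_false(any(tr4$tree$edge.length < 0))
})

test_that("four-point condition picks the same split as the tree", {
  withr::local_seed(77)
  labs <- c("A", "B", "C", "D")
  for (rep in 1:20) {
    bl <- stats::runif(4, 0.1, 2)
    inner <- stats::runif(1, 0.1, 2)
    d <- matrix(0, 4, 4, dimnames = list(labs, labs))
    for (i in 1:4) for (j in 1:4) {
      if (i != j) d[i, j] <- bl[i] + bl[j] + if ((i <= 2) == (j <= 2)) 0 else inner
    }
    perm <- sample(4)
    dp <- d[perm, perm]
    tr <- nj_tree(labs[perm], dp)
    # oracle: the additive split minimises the four-point sum
    sums <- c(AB = dp["A", "B"] + dp["C", "D"],
              AC = dp["A", "C"] + dp["B", "D"],
              AD = dp["A", "D"] + dp["B", "C"])
    expect_equal(names(which.min(sums)), "AB")
    expect_equal(tree_path_distances(tr), dp, tolerance = 1e-9)
  }
})

test_that("degenerate and invalid distance matrices are handled", {
  labs <- c("A", "B", "C", "D")
  deq <- matrix(1, 4, 4, dimnames = list(labs, labs)); diag(deq) <- 0
  tr <- nj_tree(labs, deq)
  expect_equal(sum(tr$tree$edge.length), sum(deq[upper.tri(deq)]) / 3,
               tolerance = 1e-9) # star-like: total length preserved
  bad <- deq; bad[1, 2] <- 5
  expect_error(nj_tree(labs, bad), "not symmetric")
  expect_error(nj_tree(labs[1:2], deq[1:2, 1:2]), "at least 3")
})

test_that("newick output round-trips through ape", {
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(c("x", "y", "z"), d3)
  back <- ape::read.tree(text = tr$newick)
  expect_setequal(back$tip.label, c("x", "y", "z"))
})
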