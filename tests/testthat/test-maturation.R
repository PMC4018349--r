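test_that("signal heuristic recovers designed junctions and rejects cores", {
  # synthetic signals over the lengths seen across this precursor repertoire
  for (n in c(15L, 20L, 22L, 24L, 27L, 33L)) {
    protein <- paste0(synthetic_signal(n), "HNNYAFGLGKRAPSGFLGMRG")
    pred <- predict_signal_peptide(protein)
    expect_equal(pred$length_aa, n)
    expect_equal(pred$source, "heuristic")
    expect_gt(pred$score, 1.6)
  }
  # no hydrophobic core -> no signal
  expect_equal(predict_signal_peptide(strrep("G", 40))$length_aa, 0L)
  # too short -> length 0 with score 0
  short <- predict_signal_peptide("MKTLLVALSA")
  expect_equal(short$length_aa, 0L)
  expect_equal(short$score, 0)
  # external annotation overrides the heuristic
  ann <- tibble::tibble(transcript_id = "t1", signal_length = 19L)
  ext <- signal_from_annotation(ann, "t1")
  expect_equal(ext$length_aa, 19L)
  expect_equal(ext$source, "external")
  expect_null(signal_from_annotation(ann, "t2"))
})

test_that("cleavage-site scan finds dibasics left to right without overlap", {
  one <- find_cleavage_sites("AAKRGG")
  expect_equal(one$motif, "KR")
  expect_equal(one$pos_aa, 4L)
  expect_equal(one$kind, "dibasic")

  orco <- find_cleavage_sites("FDAFTTGFGHSKRNFDEIDRSGFAFAKK")
  expect_equal(orco$motif, c("KR", "KK"))
  expect_equal(orco$pos_aa, c(13L, 28L)) # the DR inside NFDEIDR is not a site

  overlap <- find_cleavage_sites("GKRR")
  expect_equal(overlap$motif, "KR")
  expect_equal(overlap$pos_aa, 3L)

  expect_equal(nrow(find_cleavage_sites("ACDEFG")), 0L)
  mono <- find_cleavage_sites("AARGG", monobasic_r = TRUE)
  expect_equal(mono$kind, "monobasic")
  expect_equal(mono$pos_aa, 3L)
})

test_that("overlap rule matches brute-force leftmost non-overlapping placement", {
  withr::local_seed(11)
  oracle_sites <- function(s, grammar) {
    pos <- integer(0); i <- 1L
    while (i < nchar(s)) {
      if (substr(s, i, i + 1L) %in% grammar) {
        pos <- c(pos, i + 1L); i <- i + 2L
      } else i <- i + 1L
    }
    pos
  }
  for (rep in 1:200) {
    s <- paste(sample(c("K", "R", "A", "G"), sample(4:20, 1), replace = TRUE),
               collapse = "")
    expect_equal(find_cleavage_sites(s)$pos_aa,
                 oracle_sites(s, c("KR", "RK", "KK", "RR")), info = s)
  }
})

test_that("segmentation conserves the propeptide and keeps trailing motifs", {
  segs <- segment_propeptide("AKRB", tibble::tibble(motif = "KR", pos_aa = 3L,
                                                    kind = "dibasic"))
  expect_equal(segs$raw_segment, c("AKR", "B"))
  expect_equal(segs$trailing_motif, c("KR", ""))

  none <- segment_propeptide("ACDEFG", find_cleavage_sites("ACDEFG"))
  expect_equal(none$raw_segment, "ACDEFG")

  withr::local_seed(23)
  for (rep in 1:100) {
    s <- paste(sample(c("K", "R", "A", "G", "L", "S"), sample(6:40, 1),
                      replace = TRUE), collapse = "")
    segs <- segment_propeptide(s, find_cleavage_sites(s))
    expect_equal(paste(segs$raw_segment, collapse = ""), s)
  }
})

test_that("trimming removes only the site motif, then the amide glycine", {
  a <- trim_and_modify("HNNYAFGLGKR", "KR")
  expect_equal(a$sequence, "HNNYAFGL")
  expect_true(a$amidated)

  # the tachykinin case: the peptide's own terminal R is retained
  b <- trim_and_modify("APSGFLGMRGKR", "KR")
  expect_equal(b$sequence, "APSGFLGMR")
  expect_true(b$amidated)
  expect_equal(nchar(b$sequence), 9L)

  c_ <- trim_and_modify("EDSPASDAYTLKR", "KR")
  expect_equal(c_$sequence, "EDSPASDAYTL")
  expect_false(c_$amidated)

  # precursor-terminal segment ending in G is an amide donor too
  d <- trim_and_modify("APSGFLGMRG", "")
  expect_equal(d$sequence, "APSGFLGMR")
  expect_true(d$amidated)

  q <- trim_and_modify("QTFQYSRGWTNGKR", "KR")
  expect_true(q$pyroglutamate)
  expect_equal(q$sequence, "QTFQYSRGWTN") # flag only, never a sequence edit

  expect_error(trim_and_modify("KR", "KR"), "degenerate")
})

test_that("study-family precursors process into their printed peptide lists", {
  for (fam in c("Allatostatin A", "Allatostatin B", "Allatostatin C",
                "Sulfakinin")) {
    built <- precursor_from_table(fam)
    pep <- process_precursor(built$protein) # heuristic signal
    expect_equal(attr(pep, "signal")$length_aa, built$signal_length, info = fam)
    expect_equal(pep$sequence, built$truth$sequence, info = fam)
    expect_equal(pep$amidated, built$truth$amidated, info = fam)
    expect_equal(pep$start_aa, built$truth$start_aa, info = fam)
    expect_equal(pep$end_aa, built$truth$end_aa, info = fam)
  }
  # peptides with internal single basics survive the dibasic-only grammar
  a <- process_precursor(precursor_from_table("Allatostatin A")$protein)
  expect_true("NRQYSFGL" %in% a$sequence)
  expect_true("SDLYDNDLGRSYDFGL" %in% a$sequence)
})

test_that("degenerate precursor: signal plus terminal dipeptide", {
  protein <- paste0(synthetic_signal(15L), "AG")
  pep <- process_precursor(protein, signal = 15L)
  expect_equal(nrow(pep), 1L)
  expect_equal(pep$sequence, "A")
  expect_true(pep$amidated)
  expect_error(process_precursor(synthetic_signal(15L), signal = 15L),
               "covers the whole protein")
})

test_that("generator/processor round-trip recovers random peptide lists", {
  withr::local_seed(314)
  for (rep in 1:200) {
    n_pep <- sample(1:6, 1L)
    peps <- random_peptides(n_pep)
    amid <- sample(c(TRUE, FALSE), n_pep, replace = TRUE)
    # an unamidated peptide ending in G is indistinguishable from an amide
    # donor once its site is trimmed; regenerate those draws
    for (k in seq_len(n_pep)) {
      while (!amid[k] && grepl("G$", peps[k])) peps[k] <- random_peptides(1L)
    }
    built <- build_precursor_protein(peps, amid,
                                     signal_length = sample(12:40, 1L),
                                     final_linker = sample(c(TRUE, FALSE), 1L))
    out <- process_precursor(built$protein, signal = built$signal_length)
    expect_equal(out$sequence, built$truth$sequence)
    expect_equal(out$amidated, built$truth$amidated)
    expect_equal(paste(out$raw_segment, collapse = ""),
                 substring(built$protein, built$signal_length + 1L))
  }
})
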