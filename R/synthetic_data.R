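#' Construct a synthetic signal peptide
#'
#' Builds an idealised secretory signal: initiator methionine, a leucine
#' hydrophobic core, and an A-x-A small-residue junction, so that the
#' package's signal-peptide heuristic recovers the designed length exactly.
#'
#' @param length_aa Signal length in residues (10-45).
#' @return Amino-acid string of `length_aa` residues.
#' @export
synthetic_signal <- function(length_aa) {
  length_aa <- as.integer(length_aa)
  if (length_aa < 10L || length_aa > 45L) {
    stopf("synthetic signal length must be in 10..45 (got %d)", length_aa)
  }
  paste0("M", strrep("L", length_aa - 4L), "ASA")
}

#' Build a ground-truthed precursor protein
#'
#' Inverse of the maturation model: assembles `signal + peptide (+ G if
#' amidated) + linker + ...` so that [process_precursor()] recovers exactly
#' the input peptide list. Peptides containing a grammar motif as a substring
#' would be split on processing, so the build refuses them by name rather
#' than silently emitting an inconsistent truth table.
#'
#' @param peptides Tibble with `sequence` and `amidated`, or a character
#'   vector (then `amidated` applies, recycled).
#' @param amidated Logical, used when `peptides` is a character vector.
#' @param signal_length Length of the synthetic signal peptide (default 24,
#'   a typical secretory signal length for this peptide repertoire).
#' @param linker Cleavage-site motif placed between peptides (default "KR").
#' @param final_linker Also append the linker after the last peptide
#'   (default FALSE: the terminal peptide ends the precursor, its amidation
#'   glycine exposed at the C-terminus).
#' @param grammar Grammar used for the embedded-motif validity check.
#' @return List with `protein`, `signal_length`, and `truth`: a tibble of the
#'   expected mature peptides (`sequence`, `amidated`, `start_aa`, `end_aa`
#'   in full-protein coordinates).
#' @export
build_precursor_protein <- function(peptides, amidated = FALSE,
                                    signal_length = 24L, linker = "KR",
                                    final_linker = FALSE,
                                    grammar = DEFAULT_GRAMMAR) {
  if (is.data.frame(peptides)) {
    amidated <- peptides$amidated
    peptides <- peptides$sequence
  }
  if (length(peptides) == 0L) stopf("peptide list must be non-empty")
  amidated <- rep_len(amidated, length(peptides))
  stopifnot(linker %in% grammar || nchar(linker) == 0L)
  for (p in peptides) {
    hit <- grammar[stringr::str_detect(p, stringr::fixed(grammar))]
    if (length(hit) > 0L) {
      stopf("peptide '%s' contains grammar motif '%s' and would be split on processing",
            p, hit[1L])
    }
  }
  n <- length(peptides)
  if (nchar(linker) == 0L && n > 1L) {
    stopf("multi-peptide precursors need a non-empty linker motif")
  }
  sig <- synthetic_signal(signal_length)
  cargo <- ifelse(amidated, paste0(peptides, "G"), peptides)
  linkers <- c(rep(linker, n - 1L), if (final_linker) linker else "")
  protein <- paste0(sig, paste0(cargo, linkers, collapse = ""))
  starts <- integer(n)
  offset <- signal_length
  for (k in seq_len(n)) {
    starts[k] <- offset + 1L
    offset <- offset + nchar(cargo[k]) + nchar(linkers[k])
  }
  truth <- tibble(
    sequence = peptides,
    amidated = amidated,
    start_aa = starts,
    end_aa = starts + nchar(peptides) - 1L
  )
  # a peptide starting in K/R next to a linker (or an amidation G) can create
  # an unintended dibasic at the junction; report it rather than silently
  # building a precursor whose truth table the processor cannot reproduce
  propeptide <- substring(protein, signal_length + 1L)
  unit_ends <- cumsum(nchar(cargo) + nchar(linkers))
  expected_sites <- unit_ends[nchar(linkers) == 2L]
  sites <- find_cleavage_sites(propeptide, grammar)
  if (!identical(sort(sites$pos_aa), sort(as.integer(expected_sites)))) {
    stray <- setdiff(sites$pos_aa, expected_sites)
    stopf("junction creates an unintended cleavage site at propeptide position %s",
          paste(stray, collapse = ", "))
  }
  list(protein = protein, signal_length = as.integer(signal_length), truth = truth)
}

#' Reverse-translate a protein into a synthetic transcript
#'
#' Chooses uniformly random synonymous codons under a fixed seed, appends a
#' TAA stop, and pads with random UTRs, so that translating the embedded ORF
#' recovers the protein exactly.
#'
#' @param protein Amino-acid string (no stops).
#' @param codon_seed Integer seed controlling codon and UTR choice.
#' @param utr5_nt,utr3_nt UTR lengths in nucleotides.
#' @return A one-row transcript tibble (`id`, `seq`, `length_nt`) with
#'   attribute `orf_start` (1-based position of the first codon).
#' @export
reverse_translate <- function(protein, codon_seed = 1L, utr5_nt = 0L, utr3_nt = 0L) {
  if (nchar(protein) == 0L) stopf("protein must be non-empty")
  aa <- strsplit(protein, "")[[1]]
  code <- Biostrings::GENETIC_CODE
  syn <- split(names(code), unname(code))
  unknown <- setdiff(unique(aa), names(syn))
  if (length(unknown) > 0L) stopf("cannot reverse-translate residue '%s'", unknown[1])
  withr::with_seed(codon_seed, {
    codons <- vapply(aa, function(a) {
      opts <- syn[[a]]
      if (a == "M") "ATG" else opts[sample.int(length(opts), 1L)]
    }, character(1))
    utr5 <- paste(sample(c("A", "C", "G", "T"), utr5_nt, replace = TRUE), collapse = "")
    # the last in-frame UTR codon is a stop, so the embedded ORF is the first
    # start codon of its frame and translation recovers the protein exactly
    if (utr5_nt >= 3L) substr(utr5, utr5_nt - 2L, utr5_nt) <- "TAA"
    utr3 <- paste(sample(c("A", "C", "G", "T"), utr3_nt, replace = TRUE), collapse = "")
    seq <- paste0(utr5, paste(codons, collapse = ""), "TAA", utr3)
  })
  out <- tibble(id = "synthetic_1", seq = seq, length_nt = nchar(seq))
  attr(out, "orf_start") <- utr5_nt + 1L
  out
}

#' Simulate a tissue count matrix
#'
#' Draws negative-binomial read counts for four pooled samples (male/female
#' by brain/eyestalk) with per-transcript eyestalk fold changes, emulating
#' deep CNS RNA-seq libraries. Counts are reproducible bit for bit under a
#' fixed seed and a truth table accompanies the matrix.
#'
#' @param transcripts Tibble with `transcript_id`, `length_nt`, `brain_mean`
#'   (expected counts per brain sample) and `eyestalk_fold` (fold change;
#'   eyestalk-specific hormones in this repertoire sit at 1e2-1e3).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); default 0.1.
#' @param depth Total mapped reads per sample; default 45e6, matching deep
#'   per-sample libraries (tests use scaled-down depths).
#' @param seed Integer seed.
#' @return List with `counts` (wide tibble), `samples` (sample sheet with
#'   `lib_size`), `lengths`, and `truth` (the input plus expected means).
#' @export
simulate_counts <- function(transcripts, dispersion = 0.1, depth = 45e6, seed = 1L) {
  stopifnot(all(c("transcript_id", "length_nt", "brain_mean", "eyestalk_fold")
                %in% names(transcripts)))
  if (dispersion <= 0) stopf("dispersion must be positive")
  if (depth < 1e4) stopf("depth must be at least 1e4 reads")
  samples <- tibble(
    sample = c("m_br", "f_br", "m_es", "f_es"),
    tissue = c("brain", "brain", "eyestalk", "eyestalk"),
    sex = c("M", "F", "M", "F")
  )
  size <- 1 / dispersion
  n <- nrow(transcripts)
  counts <- withr::with_seed(seed, {
    vals <- lapply(seq_len(nrow(samples)), function(j) {
      fold <- if (samples$tissue[j] == "eyestalk") transcripts$eyestalk_fold else 1
      mu <- transcripts$brain_mean * fold
      ifelse(mu == 0, 0L, rnbinom(n, mu = mu, size = size))
    })
    names(vals) <- samples$sample
    vals
  })
  wide <- tibble(transcript_id = transcripts$transcript_id) %>%
    dplyr::bind_cols(as_tibble(counts))
  samples$lib_size <- pmax(depth, vapply(samples$sample,
                                         function(s) sum(wide[[s]]), numeric(1)))
  list(
    counts = wide,
    samples = samples,
    lengths = transcripts %>% select("transcript_id", "length_nt"),
    truth = transcripts
  )
}

#' Build a precursor from the packaged printed-peptide table
#'
#' Convenience constructor for study-condition precursors: takes a family's
#' printed mature peptides and reassembles the precursor the way the
#' maturation conventions imply, using the signal-peptide length reported for
#' that family. The orcokinin rows already carry their trailing basic
#' residues, so they are concatenated directly rather than re-linked.
#'
#' @param family A `family` value of the `table2` fixture (e.g.
#'   `"Allatostatin A"`, `"Tachykinin"`).
#' @return As [build_precursor_protein()].
#' @export
precursor_from_table <- function(family) {
  tab <- load_study_tables("table2")
  rows <- tab[tab$family == family, , drop = FALSE]
  if (nrow(rows) == 0L) stopf("no printed peptides for family '%s'", family)
  sig <- STUDY_SIGNAL_LENGTHS[[family]] %||% 24L
  if (family == "Orcokinin") {
    # printed rows carry their trailing KR/KK/RR; concatenate verbatim
    protein <- paste0(synthetic_signal(sig), paste(rows$peptide, collapse = ""))
    ends <- cumsum(nchar(rows$peptide))
    starts <- ends - nchar(rows$peptide) + 1L
    truth <- tibble(sequence = rows$peptide, amidated = rows$amidated,
                    start_aa = sig + starts, end_aa = sig + ends)
    return(list(protein = protein, signal_length = sig, truth = truth))
  }
  build_precursor_protein(rows$peptide, rows$amidated, signal_length = sig)
}

# Signal-peptide lengths reported per family for this repertoire (residues).
STUDY_SIGNAL_LENGTHS <- list(
  "Allatostatin A" = 27L,
  "Allatostatin B" = 33L,
  "Allatostatin C" = 22L,
  "Hormone-1" = 25L,
  "Corazonin" = 24L,
  "Orcokinin" = 20L,
  "PDH" = 22L,
  "Sulfakinin" = 27L,
  "Tachykinin" = 22L
)
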