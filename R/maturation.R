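#' Predict a signal peptide with a von Heijne style heuristic
#'
#' Secretory signal peptides carry a hydrophobic core followed by a cleavage
#' junction with small residues at the -3 and -1 positions. This heuristic
#' scans candidate cleavage points `c` in 8..45 and accepts those where (a)
#' positions `c-2` and `c` are small (A, G, S, C, T) and (b) some window of
#' 6-12 residues inside `[2, c-2]`, ending no earlier than `c-8`, has a mean
#' Kyte-Doolittle hydropathy above 1.6. The reported cleavage point maximises
#' that window mean; ties go to the shortest signal. This is a deliberately
#' transparent stand-in for dedicated signal-peptide predictors: for real data
#' the recommended route is an external annotation table (see
#' [signal_from_annotation()]), which always overrides the heuristic.
#'
#' @param protein Amino-acid string (one-letter code).
#' @return A list with `length_aa` (0 when nothing qualifies), `source`
#'   (`"heuristic"`) and `score` (the winning hydrophobic-core mean, 0 when
#'   none).
#' @export
predict_signal_peptide <- function(protein) {
  res <- list(length_aa = 0L, source = "heuristic", score = 0)
  n <- nchar(protein)
  if (n < 15L) return(res)
  aa <- strsplit(protein, "")[[1]]
  kd <- unname(KD_SCALE[aa])
  kd[is.na(kd)] <- 0
  small <- c("A", "G", "S", "C", "T")
  best_c <- 0L; best_score <- -Inf
  for (cpos in 8:min(45L, n - 1L)) {
    if (!(aa[cpos] %in% small && aa[cpos - 2L] %in% small)) next
    score <- core_score(kd, cpos)
    if (is.na(score) || score <= 1.6) next
    if (score > best_score) {
      best_score <- score
      best_c <- cpos
    }
  }
  if (best_c > 0L) {
    res$length_aa <- best_c
    res$score <- best_score
  }
  res
}

# Best mean hydropathy over 6-12 residue windows within [2, c-2] whose end
# lies at or after c-8 (the core must sit against the cleavage region).
core_score <- function(kd, cpos) {
  hi <- cpos - 2L
  if (hi < 7L) return(NA_real_)
  best <- NA_real_
  for (e in max(7L, cpos - 8L):hi) {
    for (w in 6:12) {
      s <- e - w + 1L
      if (s < 2L) next
      m <- mean(kd[s:e])
      if (is.na(best) || m > best) best <- m
    }
  }
  best
}

#' Build signal predictions from an external annotation table
#'
#' @param annotations Tibble with columns `transcript_id` and `signal_length`
#'   (residues; 0 means no signal), e.g. exported from a dedicated predictor.
#' @param transcript_id Identifier to look up.
#' @return A list like [predict_signal_peptide()] with `source = "external"`,
#'   or `NULL` when the transcript is not annotated.
#' @export
signal_from_annotation <- function(annotations, transcript_id) {
  hit <- annotations[annotations$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  list(length_aa = as.integer(hit$signal_length[1L]), source = "external", score = NA_real_)
}

#' Locate prohormone-convertase cleavage sites
#'
#' Scans a propeptide left to right for basic cleavage motifs. The default
#' grammar is dibasic-only (`KR`, `RK`, `KK`, `RR`); monobasic arginine sites
#' are opt-in per family because enabling them globally would falsely split
#' peptides that carry internal single basics. Matches never overlap: in a run
#' such as `KRR` the leftmost dibasic wins and scanning resumes after it.
#'
#' @param propeptide Amino-acid string (signal peptide already removed).
#' @param grammar Character vector of dibasic motifs.
#' @param monobasic_r Also accept single `R` as a (monobasic) site.
#' @return Tibble with columns `motif`, `pos_aa` (1-based position of the
#'   motif's last residue) and `kind` (`"dibasic"` or `"monobasic"`), ordered
#'   by position. Zero rows when nothing matches.
#' @export
find_cleavage_sites <- function(propeptide, grammar = DEFAULT_GRAMMAR,
                                monobasic_r = FALSE) {
  if (length(grammar) == 0L) stopf("cleavage grammar must be non-empty")
  stopifnot(all(nchar(grammar) == 2L))
  aa <- strsplit(propeptide, "")[[1]]
  n <- length(aa)
  motifs <- character(); pos <- integer(); kind <- character()
  i <- 1L
  while (i <= n) {
    if (i < n && paste0(aa[i], aa[i + 1L]) %in% grammar) {
      motifs <- c(motifs, paste0(aa[i], aa[i + 1L]))
      pos <- c(pos, i + 1L)
      kind <- c(kind, "dibasic")
      i <- i + 2L
    } else if (monobasic_r && aa[i] == "R") {
      motifs <- c(motifs, "R")
      pos <- c(pos, i)
      kind <- c(kind, "monobasic")
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  tibble(motif = motifs, pos_aa = pos, kind = kind)
}

#' Split a propeptide at its cleavage sites
#'
#' Cuts immediately C-terminal to each site motif. Each raw segment keeps its
#' trailing motif, so the concatenation of all segments reproduces the
#' propeptide byte for byte.
#'
#' @param propeptide Amino-acid string.
#' @param sites Tibble from [find_cleavage_sites()].
#' @return Tibble with columns `raw_segment`, `start_aa`, `end_aa` (propeptide
#'   coordinates of the raw segment) and `trailing_motif` (empty string for the
#'   terminal segment).
#' @export
segment_propeptide <- function(propeptide, sites) {
  n <- nchar(propeptide)
  cuts <- sites$pos_aa
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  motifs <- character(length(starts))
  for (k in seq_along(starts)) {
    hit <- which(sites$pos_aa == ends[k])
    motifs[k] <- if (length(hit) == 1L) sites$motif[hit] else ""
  }
  tibble(
    raw_segment = substring(propeptide, starts, ends),
    start_aa = starts, end_aa = ends,
    trailing_motif = motifs
  )
}

#' Trim a raw segment into a mature peptide
#'
#' Carboxypeptidase trimming removes exactly the residues of the matched site
#' motif -- never basics that belong to the peptide itself (a tachykinin-type
#' peptide keeps its own terminal R). If the trimmed peptide then ends in
#' glycine and a motif was removed (or the segment is the precursor-terminal
#' one and ends in glycine), the glycine is the amide donor: it is stripped and
#' the peptide flagged amidated. An N-terminal glutamine is flagged as a
#' pyroglutamate candidate without editing the sequence.
#'
#' @param segment Raw segment including its trailing motif, if any.
#' @param trailing_motif The site motif at the segment end, or `""` for the
#'   precursor-terminal segment.
#' @return A list with `raw_segment`, `sequence`, `amidated`, `pyroglutamate`.
#' @export
trim_and_modify <- function(segment, trailing_motif = "") {
  ml <- nchar(trailing_motif)
  if (ml > 0L) {
    if (substring(segment, nchar(segment) - ml + 1L) != trailing_motif) {
      stopf("segment '%s' does not end with motif '%s'", segment, trailing_motif)
    }
  }
  core <- substr(segment, 1L, nchar(segment) - ml)
  amidated <- FALSE
  if (nchar(core) > 0L && substring(core, nchar(core)) == "G") {
    # amide donor glycine: exposed by motif removal, or precursor-terminal
    core2 <- substr(core, 1L, nchar(core) - 1L)
    if (nchar(core2) > 0L) {
      core <- core2
      amidated <- TRUE
    }
  }
  if (nchar(core) == 0L) {
    stopf("degenerate segment '%s': trimming leaves no peptide", segment)
  }
  list(
    raw_segment = segment,
    sequence = core,
    amidated = amidated,
    pyroglutamate = substr(core, 1L, 1L) == "Q"
  )
}

#' Process a precursor protein into mature peptides
#'
#' Runs the full maturation model: remove the signal peptide, scan the
#' propeptide for convertase sites, segment it, and trim each segment with
#' amidation and pyroglutamate flagging. Peptides are returned in precursor
#' order with coordinates mapped back to the full protein.
#'
#' @param protein Precursor protein string.
#' @param signal Either `NULL` (run [predict_signal_peptide()]), an integer
#'   signal length, or a prediction list with `length_aa` and `source`.
#' @param grammar,monobasic_r Passed to [find_cleavage_sites()].
#' @return A tibble of mature peptides (class `np_peptides`) with columns
#'   `raw_segment`, `sequence`, `amidated`, `pyroglutamate`, `start_aa`,
#'   `end_aa` (coordinates of the trimmed sequence within `protein`) and
#'   `trailing_motif`. Attributes `protein`, `signal` and `propeptide` carry
#'   the precursor model.
#' @export
process_precursor <- function(protein, signal = NULL, grammar = DEFAULT_GRAMMAR,
                              monobasic_r = FALSE) {
  if (is.null(signal)) signal <- predict_signal_peptide(protein)
  if (is.numeric(signal)) signal <- list(length_aa = as.integer(signal), source = "external",
                                         score = NA_real_)
  sig_len <- signal$length_aa
  if (sig_len >= nchar(protein)) {
    stopf("signal peptide (%d aa) covers the whole protein (%d aa)",
          sig_len, nchar(protein))
  }
  propeptide <- substring(protein, sig_len + 1L)
  sites <- find_cleavage_sites(propeptide, grammar, monobasic_r)
  segs <- segment_propeptide(propeptide, sites)
  rows <- purrr::map_dfr(seq_len(nrow(segs)), function(k) {
    tm <- segs$trailing_motif[k]
    trimmed <- trim_and_modify(segs$raw_segment[k], tm)
    tibble(
      raw_segment = trimmed$raw_segment,
      sequence = trimmed$sequence,
      amidated = trimmed$amidated,
      pyroglutamate = trimmed$pyroglutamate,
      start_aa = sig_len + segs$start_aa[k],
      end_aa = sig_len + segs$start_aa[k] + nchar(trimmed$sequence) - 1L,
      trailing_motif = tm
    )
  })
  structure(rows,
            class = c("np_peptides", class(rows)),
            protein = protein, signal = signal, propeptide = propeptide)
}

#' @export
print.np_peptides <- function(x, ...) {
  sig <- attr(x, "signal")
  cat(sprintf("Mature peptides (%d) from a %d-aa precursor (signal %d aa, %s)\n",
              nrow(x), nchar(attr(x, "protein")), sig$length_aa, sig$source))
  NextMethod()
}
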