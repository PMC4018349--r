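#' Find open reading frames in all six frames
#'
#' Scans every transcript in all six reading frames under the standard genetic
#' code. Complete ORFs run ATG to stop; partial ORFs are classified by which
#' end is open: `partial_nterm` (frame edge to first stop), `partial_cterm`
#' (last ATG to the open transcript end) and `partial_both` (a fully open
#' frame). Codons containing `N` translate to `X` and terminate ORF extension,
#' since assembly ambiguity breaks the reading evidence.
#'
#' @param transcripts Tibble with columns `id` and `seq` (see [read_fasta()]),
#'   or a single nucleotide string.
#' @param min_aa Minimum protein length in residues (stop excluded). The
#'   default of 40 keeps a margin below the shortest precursor ORFs seen in
#'   decapod CNS assemblies (~49 aa) while skipping spurious micro-ORFs.
#' @return Tibble with columns `transcript_id`, `frame` (+1..+3, -1..-3),
#'   `start_nt`, `end_nt` (1-based inclusive transcript coordinates; a stop
#'   codon is included when present), `protein`, `length_aa`, `completeness`.
#' @export
find_orfs <- function(transcripts, min_aa = 40) {
  stopifnot(min_aa >= 1)
  if (is.character(transcripts)) {
    transcripts <- tibble(id = paste0("seq", seq_along(transcripts)), seq = toupper(transcripts))
  }
  purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
    orfs_one(transcripts$id[i], transcripts$seq[i], min_aa)
  })
}

translate_frame <- function(seq, frame) {
  # frame is 1..3 on the given strand; returns the AA string (N-codons -> X)
  L <- nchar(seq)
  n_codon <- (L - frame + 1L) %/% 3L
  if (n_codon < 1L) return("")
  sub <- substr(seq, frame, frame + 3L * n_codon - 1L)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X", no.init.codon = TRUE))
}

orfs_one <- function(id, seq, min_aa) {
  L <- nchar(seq)
  if (L < 3L) return(tibble())
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand > 0) seq else rc
    for (f in 1:3) {
      prot <- translate_frame(s, f)
      if (nchar(prot) == 0L) next
      cand <- frame_orf_candidates(prot)
      for (k in seq_len(nrow(cand))) {
        p0 <- cand$p_start[k]; p1 <- cand$p_end[k]  # protein coords, stop excluded
        nt0 <- f + 3L * (p0 - 1L)
        nt1 <- f + 3L * (p1 + cand$has_stop[k]) - 1L  # include stop codon if present
        if (strand < 0) {
          tmp <- c(L - nt1 + 1L, L - nt0 + 1L)
          nt0 <- tmp[1]; nt1 <- tmp[2]
        }
        out[[length(out) + 1L]] <- tibble(
          transcript_id = id, frame = strand * f,
          start_nt = nt0, end_nt = nt1,
          protein = substr(prot, p0, p1),
          length_aa = p1 - p0 + 1L,
          completeness = cand$completeness[k]
        )
      }
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) return(res)
  res %>%
    filter(.data$length_aa >= min_aa) %>%
    distinct(.data$transcript_id, .data$frame, .data$start_nt, .data$end_nt,
             .keep_all = TRUE)
}

# Enumerate ORF candidates within one translated frame. Runs are maximal
# stretches free of stops ('*') and ambiguity ('X'); X breaks extension but,
# unlike a stop, leaves the flanking run ineligible for edge-open classes.
frame_orf_candidates <- function(prot) {
  chars <- strsplit(prot, "")[[1]]
  n <- length(chars)
  breaker <- chars %in% c("*", "X")
  runs <- rle(breaker)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- !runs$values
  out <- list()
  for (r in which(keep)) {
    a <- starts[r]; b <- ends[r]
    stopped <- b < n && chars[b + 1L] == "*"
    leading <- a == 1L
    trailing <- b == n
    ms <- a - 1L + which(chars[a:b] == "M")
    emitted_complete_from_start <- FALSE
    if (stopped && length(ms) > 0L) {
      out[[length(out) + 1L]] <- list(p_start = ms[1L], p_end = b, has_stop = 1L,
                                      completeness = "complete")
      emitted_complete_from_start <- ms[1L] == a
    }
    if (leading && stopped && !emitted_complete_from_start) {
      out[[length(out) + 1L]] <- list(p_start = a, p_end = b, has_stop = 1L,
                                      completeness = "partial_nterm")
    }
    if (leading && trailing) {
      out[[length(out) + 1L]] <- list(p_start = a, p_end = b, has_stop = 0L,
                                      completeness = "partial_both")
    } else if (trailing && length(ms) > 0L) {
      out[[length(out) + 1L]] <- list(p_start = ms[length(ms)], p_end = b, has_stop = 0L,
                                      completeness = "partial_cterm")
    }
  }
  if (length(out) == 0L) {
    return(tibble(p_start = integer(), p_end = integer(), has_stop = integer(),
                  completeness = character()))
  }
  bind_rows(lapply(out, as_tibble))
}

#' Select the precursor ORF among candidates
#'
#' Returns the longest ORF; ties are broken by completeness (complete before
#' partial), then frame order (+1, +2, +3, -1, -2, -3), then lowest start
#' coordinate.
#'
#' @param orfs Tibble as returned by [find_orfs()] (rows for one transcript).
#' @return A one-row tibble.
#' @export
select_precursor_orf <- function(orfs) {
  if (is.null(orfs) || nrow(orfs) == 0L) stopf("no ORFs to select from")
  frame_rank <- match(orfs$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  ord <- order(-orfs$length_aa, orfs$completeness != "complete", frame_rank, orfs$start_nt)
  orfs[ord[1L], , drop = FALSE]
}
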