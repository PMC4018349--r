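#' Read assembled transcripts from a FASTA file
#'
#' Reads a nucleotide FASTA file into a tidy transcript table. Sequences are
#' uppercased and validated against the `{A,C,G,T,N}` alphabet; the ambiguity
#' code `N` is allowed because de novo assemblies routinely contain it.
#'
#' @param path Path to a FASTA file of assembled (unoriented) transcripts.
#' @return A tibble with one row per record, in file order, and columns
#'   `id` (unique record identifier), `seq` (uppercase nucleotide string) and
#'   `length_nt`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">t1", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stopf("malformed FASTA in %s: %s", path, conditionMessage(e))
  )
  ids <- sub("\\s.*$", "", names(set))
  empty <- which(Biostrings::width(set) == 0L)
  if (length(empty) > 0L) {
    stopf("empty sequence for record %d (%s)", empty[1L], ids[empty[1L]])
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stopf("duplicate transcript id: %s", dup[1L])
  }
  seqs <- unname(toupper(as.character(set)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stopf("record %d (%s) contains characters outside {A,C,G,T,N}",
          which(bad)[1L], ids[which(bad)[1L]])
  }
  tibble(id = unname(ids), seq = unname(seqs), length_nt = nchar(seqs))
}

#' Write a transcript table to FASTA
#'
#' @param transcripts A tibble with columns `id` and `seq`, as returned by
#'   [read_fasta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path) {
  stopifnot(all(c("id", "seq") %in% names(transcripts)))
  set <- Biostrings::DNAStringSet(transcripts$seq)
  names(set) <- transcripts$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# md5 checksums of the packaged study-table fixtures; the loader refuses to
# serve a silently edited copy.
FIXTURE_MD5 <- c(
  table1 = "1591b50fd530c08462b4f74cabc29397",
  table2 = "ed6453d21e62f7492ffea9360bb8bb25",
  table3 = "f6da68b32de7e8baea6d21185ef41284"
)

#' Load the packaged study tables
#'
#' The package ships hand-transcribed copies of the three printed study tables
#' for the Eastern rock lobster CNS neuropeptidome: the 37-transcript precursor
#' inventory with best-hit annotations (`table1`), the printed mature peptide
#' sequences with amidation flags (`table2`), and the per-tissue RPKM values
#' for four pooled samples (`table3`). File checksums are verified so that an
#' edited fixture fails loudly rather than silently shifting results.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`.
#' @return A tibble. `table1`: transcript inventory (37 rows; columns `family`,
#'   `transcript`, `transcript_size_nt`, `orf_size_aa`, `comments`, `best_hit`,
#'   `evalue`). `table2`: mature peptides (columns `family`, `peptide`,
#'   `amidated`, `best_hit`, `accession`, `identity_note`); amidation encodes
#'   the printed trailing lowercase 'a'. `table3`: RPKM values (columns
#'   `family`, `transcript`, `comments`, `m_br`, `f_br`, `m_es`, `f_es`,
#'   `br_mean`, `es_mean`, `significant`), where `significant` transcribes the
#'   printed bold marking.
#' @export
load_study_tables <- function(name = c("table1", "table2", "table3")) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stopf("unknown fixture '%s'; use one of table1, table2, table3",
          paste(name, collapse = ", "))
  })
  path <- system.file("extdata", paste0(name, ".tsv"), package = "npmine",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(FIXTURE_MD5[[name]]))) {
    stopf("fixture %s has been modified (md5 %s); reinstall the package", name, md5)
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write precursor features as GFF3
#'
#' Serialises precursor ORFs and their derived features (signal peptides,
#' cleavage sites, mature peptides) as GFF3 v1.23 with 1-based inclusive
#' nucleotide coordinates on the transcript. Protein coordinates are converted
#' with `nt = orf_start + 3 * (aa - 1)` on the forward strand and mirrored on
#' the reverse strand; the strand is taken from the ORF frame sign.
#'
#' @param precursors Tibble with one row per precursor ORF: columns
#'   `transcript_id`, `frame`, `start_nt`, `end_nt`, and optionally
#'   `signal_length` (aa, 0 or NA for none).
#' @param peptides Tibble of features in protein coordinates: columns
#'   `transcript_id`, `start_aa`, `end_aa`, optionally `sequence` and `type`
#'   (defaults to `"mature_peptide"`; use `"cleavage_site"` for site features).
#'   May be empty.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3_features <- function(precursors, peptides, path) {
  stopifnot(all(c("transcript_id", "frame", "start_nt", "end_nt") %in% names(precursors)))
  lines <- "##gff-version 3"
  fmt <- function(seqid, type, start, end, strand, attrs) {
    sprintf("%s\tnpmine\t%s\t%d\t%d\t.\t%s\t.\t%s", seqid, type, start, end, strand, attrs)
  }
  aa_to_nt <- function(orf, start_aa, end_aa) {
    if (orf$frame > 0) {
      c(orf$start_nt + 3L * (start_aa - 1L), orf$start_nt + 3L * end_aa - 1L)
    } else {
      c(orf$end_nt - 3L * end_aa + 1L, orf$end_nt - 3L * (start_aa - 1L))
    }
  }
  for (i in seq_len(nrow(precursors))) {
    orf <- precursors[i, ]
    strand <- if (orf$frame > 0) "+" else "-"
    orf_id <- sprintf("orf_%s", orf$transcript_id)
    lines <- c(lines, fmt(orf$transcript_id, "ORF", orf$start_nt, orf$end_nt,
                          strand, sprintf("ID=%s;frame=%+d", orf_id, orf$frame)))
    sig <- orf[["signal_length"]]
    if (!is.null(sig) && !is.na(sig) && sig > 0) {
      nt <- aa_to_nt(orf, 1L, as.integer(sig))
      lines <- c(lines, fmt(orf$transcript_id, "signal_peptide", nt[1], nt[2],
                            strand, sprintf("ID=sig_%s;Parent=%s", orf$transcript_id, orf_id)))
    }
    feats <- peptides[peptides$transcript_id == orf$transcript_id, , drop = FALSE]
    for (j in seq_len(nrow(feats))) {
      f <- feats[j, ]
      type <- f[["type"]] %||% "mature_peptide"
      if (is.null(f[["type"]]) || is.na(type)) type <- "mature_peptide"
      prot_len <- (orf$end_nt - orf$start_nt + 1L) %/% 3L
      if (f$start_aa < 1L || f$end_aa > prot_len) {
        stopf("feature %s:%d-%d outside ORF bounds (1-%d aa)",
              f$transcript_id, f$start_aa, f$end_aa, prot_len)
      }
      nt <- aa_to_nt(orf, as.integer(f$start_aa), as.integer(f$end_aa))
      attrs <- sprintf("ID=%s_%d_%d;Parent=%s", f$transcript_id, f$start_aa, f$end_aa, orf_id)
      seqv <- f[["sequence"]]
      if (!is.null(seqv) && !is.na(seqv)) attrs <- paste0(attrs, ";sequence=", seqv)
      lines <- c(lines, fmt(f$transcript_id, type, nt[1], nt[2], strand, attrs))
    }
  }
  orphans <- setdiff(unique(peptides$transcript_id), precursors$transcript_id)
  if (length(orphans) > 0L) {
    stopf("peptide features reference transcripts without a precursor ORF: %s",
          paste(orphans, collapse = ", "))
  }
  writeLines(lines, path)
  invisible(path)
}
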