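#' Default motif, keyword and scaffold libraries
#'
#' The classifier is data-driven: its motif library, keyword map and cysteine
#' scaffold table ship as flat TSV config files, so adding a family needs no
#' code change. The defaults cover the peptide families recoverable from
#' printed decapod mature peptides: C-terminal YXFGL-amide (A-type
#' allatostatin), W-X6-W-amide (B-type), the QCxFNxxSCF Cys-pair motif (C-type
#' allatostatin / prohormone-1), N-terminal NFDEID (orcokinin), FxGxR-amide
#' (tachykinin), GH(M/L)RF-amide (sulfakinin), the 10-residue RF-amide
#' (myosuppressin), corazonin, the amidated 8-mer ...W-amide (RPCH), the
#' 2-cysteine amidated CCAP and the 18-mer PDH.
#'
#' @param path Optional path to an alternative TSV with the same columns.
#' @return A tibble; see `inst/extdata` for the column layout.
#' @export
default_motif_library <- function(path = NULL) {
  path <- path %||% system.file("extdata", "motif_library.tsv", package = "npmine",
                                mustWork = TRUE)
  lib <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  stopifnot(all(c("family", "pattern", "requires_amidation", "min_len",
                  "max_len", "cys_count", "scope") %in% names(lib)))
  bad <- lib$min_len > lib$max_len
  if (any(bad)) stopf("motif library: min_len > max_len for %s", lib$family[bad][1])
  for (p in lib$pattern) regexpr(p, "A", perl = TRUE)  # patterns must compile
  lib
}

#' @rdname default_motif_library
#' @export
default_keyword_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "keyword_map.tsv", package = "npmine",
                                mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname default_motif_library
#' @export
default_scaffolds <- function(path = NULL) {
  path <- path %||% system.file("extdata", "scaffold_library.tsv", package = "npmine",
                                mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# Count of literal alphabet characters in a pattern, used as a specificity
# score when several motifs match (longer literal content wins).
pattern_specificity <- function(pattern) {
  p <- gsub("\\[[^]]*\\]", "", pattern)     # character classes are not literal
  p <- gsub("\\{[0-9,]*\\}", "", p)
  p <- gsub("[.^$?*+|()\\\\]", "", p)
  nchar(p)
}

#' Match mature peptides against the family motif library
#'
#' Length, amidation and cysteine-count constraints are enforced before the
#' pattern is applied; a peptide can match several families and every match is
#' returned (resolution happens in [assign_family()]).
#'
#' @param peptides Tibble with columns `sequence` and `amidated`, and
#'   optionally `subject_id` (defaults to the sequence itself). A bare
#'   character vector is treated as unamidated sequences.
#' @param library Motif library tibble, see [default_motif_library()].
#' @return Tibble with columns `subject_id`, `family`, `evidence` (`"motif"`)
#'   and `detail` (the matched pattern). Zero rows when nothing matches.
#' @export
match_peptide_motifs <- function(peptides, library = default_motif_library()) {
  if (is.character(peptides)) {
    peptides <- tibble(sequence = peptides, amidated = FALSE)
  }
  if (is.null(peptides[["subject_id"]])) peptides$subject_id <- peptides$sequence
  lib <- library[library$scope == "peptide", , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(peptides)), function(i) {
    s <- peptides$sequence[i]
    am <- isTRUE(peptides$amidated[i])
    len <- nchar(s)
    ncys <- stringr::str_count(s, stringr::fixed("C"))
    ok <- (!lib$requires_amidation | am) &
      len >= lib$min_len & len <= lib$max_len &
      (is.na(lib$cys_count) | ncys == lib$cys_count) &
      stringr::str_detect(s, lib$pattern)
    if (!any(ok)) return(tibble())
    tibble(subject_id = peptides$subject_id[i],
           family = lib$family[ok],
           evidence = "motif",
           detail = lib$pattern[ok])
  }) %>% empty_hits_if_none()
}

# typed zero-row hit table, so downstream code can rely on the columns
empty_hits_if_none <- function(x) {
  if (nrow(x) > 0L) return(x)
  tibble(subject_id = character(), family = character(),
         evidence = character(), detail = character())
}

#' Match a protein domain against cysteine scaffolds
#'
#' Several hormone families in this repertoire are defined not by a short
#' motif but by a disulfide scaffold: a characteristic cysteine count inside a
#' characteristic domain length (e.g. the ~71-74 aa, 6-cysteine CHH/MIH
#' superfamily domain). A family matches when both the cysteine count and the
#' domain length range agree; `tolerance` widens the length range on both
#' sides (0 = strict) for boundary diagnostics.
#'
#' @param domains Tibble with columns `sequence` and optionally `subject_id`,
#'   or a bare character vector of domain sequences (>= 20 aa each).
#' @param scaffolds Scaffold table, see [default_scaffolds()].
#' @param tolerance Residues added to each side of the length range.
#' @return Tibble `subject_id`, `family`, `evidence` (`"scaffold"`), `detail`,
#'   and `midpoint_dist` (distance from the domain length to the family's
#'   length-range midpoint, the ambiguity tie-break key).
#' @export
scan_cysteine_scaffold <- function(domains, scaffolds = default_scaffolds(),
                                   tolerance = 0L) {
  if (is.character(domains)) domains <- tibble(sequence = domains)
  if (is.null(domains[["subject_id"]])) domains$subject_id <- domains$sequence
  purrr::map_dfr(seq_len(nrow(domains)), function(i) {
    s <- domains$sequence[i]
    len <- nchar(s)
    if (len < 20L) stopf("domain '%s...' shorter than 20 aa", substr(s, 1, 10))
    ncys <- stringr::str_count(s, stringr::fixed("C"))
    ok <- scaffolds$cys_count == ncys &
      len >= scaffolds$min_len - tolerance &
      len <= scaffolds$max_len + tolerance
    if (!any(ok)) return(tibble())
    hit <- scaffolds[ok, , drop = FALSE]
    tibble(subject_id = domains$subject_id[i],
           family = hit$family,
           evidence = "scaffold",
           detail = sprintf("%dC/%d-%daa", hit$cys_count, hit$min_len, hit$max_len),
           midpoint_dist = abs(len - (hit$min_len + hit$max_len) / 2),
           strict = len >= hit$min_len & len <= hit$max_len) %>%
      distinct(.data$subject_id, .data$family, .keep_all = TRUE)
  }) %>% empty_hits_if_none()
}

#' Mine annotation descriptions for hormone keywords
#'
#' Emulates scanning an annotation list for names and abbreviations of known
#' neurohormones plus the generic term "hormone". Matching is case-insensitive
#' substring search over the description (and, when present, a curator
#' `comments` field). Records hit only by the generic term are flagged
#' `unassigned_hormone`.
#'
#' @param records Tibble with columns `transcript_id`, `description` and
#'   optionally `comments`.
#' @param keywords Keyword map tibble (`family`, `term`, `generic`), see
#'   [default_keyword_map()].
#' @return Tibble `subject_id`, `family`, `evidence` (`"keyword"`), `detail`
#'   (the matched term) and `generic`.
#' @export
keyword_mine <- function(records, keywords = default_keyword_map()) {
  if (length(keywords$term) == 0L) stopf("keyword map must be non-empty")
  text <- records$description
  if (!is.null(records[["comments"]])) {
    text <- paste(text, dplyr::coalesce(records$comments, ""))
  }
  text <- tolower(text)
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    ok <- stringr::str_detect(text[i], stringr::fixed(tolower(keywords$term)))
    if (!any(ok)) return(tibble())
    tibble(subject_id = records$transcript_id[i],
           family = keywords$family[ok],
           evidence = "keyword",
           detail = keywords$term[ok],
           generic = keywords$generic[ok]) %>%
      distinct(.data$subject_id, .data$family, .keep_all = TRUE)
  }) %>% empty_hits_if_none()
}

#' Resolve evidence into one primary family per subject
#'
#' Precedence is motif > scaffold > keyword: a sequence-level motif is direct
#' evidence about the mature peptide, a scaffold is structural, and a keyword
#' only inherits a database annotation. Within the motif level ties go to the
#' most specific pattern (most literal residues); within the scaffold level to
#' the family whose length-range midpoint is nearest; within the keyword level
#' specific terms beat the generic "hormone" and longer terms beat shorter.
#' Non-primary evidence is retained in `alternatives`, never dropped.
#'
#' @param motif_hits,scaffold_hits,keyword_hits Tibbles as produced by
#'   [match_peptide_motifs()], [scan_cysteine_scaffold()], [keyword_mine()];
#'   any may be `NULL` or empty.
#' @return Tibble with one row per subject: `subject_id`, `family`, `evidence`,
#'   `detail`, `alternatives` (collapsed `family(evidence)` strings, `""` if
#'   none). Subjects with no evidence at all get `family = "unclassified"`.
#' @export
assign_family <- function(motif_hits = NULL, scaffold_hits = NULL,
                          keyword_hits = NULL) {
  empty <- tibble(subject_id = character(), family = character(),
                  evidence = character(), detail = character())
  pad <- function(x) if (is.null(x) || nrow(x) == 0L) empty else x
  hits <- bind_rows(pad(motif_hits), pad(scaffold_hits), pad(keyword_hits))
  if (nrow(hits) == 0L) {
    stopf("no evidence supplied to assign_family()")
  }
  hits$level <- match(hits$evidence, c("motif", "scaffold", "keyword"))
  hits$rank2 <- 0
  m <- hits$evidence == "motif"
  hits$rank2[m] <- -pattern_specificity(hits$detail[m])
  s <- hits$evidence == "scaffold"
  if (any(s)) {
    strict <- hits[["strict"]][s]
    strict[is.na(strict)] <- FALSE
    mdist <- hits[["midpoint_dist"]][s]
    mdist[is.na(mdist)] <- 0
    hits$rank2[s] <- (!strict) * 100 + mdist
  }
  k <- hits$evidence == "keyword"
  if (any(k)) {
    gen <- hits[["generic"]]
    hits$rank2[k] <- ifelse(!is.na(gen[k]) & gen[k], 1000, 0) - nchar(hits$detail[k])
  }
  hits %>%
    group_by(.data$subject_id) %>%
    arrange(.data$level, .data$rank2, .data$family, .by_group = TRUE) %>%
    summarise(
      # secondary evidence first: summarise masks `family` once reassigned
      alternatives = paste(sprintf("%s(%s)", .data$family[-1], .data$evidence[-1]),
                           collapse = ";"),
      ambiguous = dplyr::n_distinct(.data$family) > 1L,
      family = dplyr::first(.data$family),
      evidence = dplyr::first(.data$evidence),
      detail = dplyr::first(.data$detail),
      .groups = "drop"
    ) %>%
    select("subject_id", "family", "evidence", "detail", "alternatives", "ambiguous")
}

#' Classify an annotated transcript table
#'
#' Convenience wrapper running [keyword_mine()] and [assign_family()] over a
#' transcript inventory shaped like the packaged `table1` fixture
#' (`transcript` or `transcript_id`, `best_hit` or `description`, optional
#' `comments`).
#'
#' @param annotations Annotated transcript tibble.
#' @param keywords Keyword map.
#' @param use_comments Also scan the curator `comments` field (default TRUE).
#' @return One row per transcript: the [assign_family()] columns, with
#'   unmatched transcripts reported as `family = "unclassified"`.
#' @export
classify_transcripts <- function(annotations, keywords = default_keyword_map(),
                                 use_comments = TRUE) {
  recs <- tibble(
    transcript_id = annotations[["transcript_id"]] %||% annotations[["transcript"]],
    description = annotations[["description"]] %||% annotations[["best_hit"]]
  )
  if (use_comments && !is.null(annotations[["comments"]])) {
    recs$comments <- annotations$comments
  }
  hits <- keyword_mine(recs, keywords)
  assigned <- if (nrow(hits) > 0L) assign_family(keyword_hits = hits) else
    tibble(subject_id = character(), family = character(), evidence = character(),
           detail = character(), alternatives = character(), ambiguous = logical())
  missing <- setdiff(recs$transcript_id, assigned$subject_id)
  bind_rows(assigned,
            tibble(subject_id = missing, family = "unclassified",
                   evidence = NA_character_, detail = NA_character_,
                   alternatives = "", ambiguous = FALSE)) %>%
    arrange(match(.data$subject_id, recs$transcript_id))
}
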