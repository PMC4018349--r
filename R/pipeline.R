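#' Validate a pipeline configuration
#'
#' Bundles every knob of the mining pipeline into one validated list:
#' input paths, the cleavage grammar, the classifier config files, the
#' contrast alpha and the seed. All referenced paths must exist at validation
#' time; an invalid grammar string fails here rather than mid-run.
#'
#' @param fasta Path to the transcript FASTA (required).
#' @param annotations Optional TSV with `transcript_id`, `description`
#'   (best-hit string) and optional `comments` and `evalue` columns.
#' @param signals Optional TSV with `transcript_id`, `signal_length`
#'   (external signal-peptide annotations; override the heuristic).
#' @param counts Optional TSV of read counts: `transcript_id` plus the sample
#'   columns `m_br`, `f_br`, `m_es`, `f_es`, with a first comment line
#'   `#lib_sizes m_br f_br m_es f_es` giving the totals (whitespace-separated
#'   numbers).
#' @param motif_library,keywords,scaffolds Optional alternative classifier
#'   config TSVs.
#' @param grammar Cleavage grammar (character vector of dibasic motifs).
#' @param monobasic_r Enable monobasic arginine cleavage.
#' @param min_aa Minimum ORF length for [find_orfs()].
#' @param alpha Contrast significance threshold.
#' @param seed Seed recorded in the manifest and used by any stochastic stage.
#' @param out_dir Output directory (created by [run_pipeline()]).
#' @return A validated config list of class `np_config`.
#' @export
pipeline_config <- function(fasta, annotations = NULL, signals = NULL,
                            counts = NULL, motif_library = NULL,
                            keywords = NULL, scaffolds = NULL,
                            grammar = DEFAULT_GRAMMAR, monobasic_r = FALSE,
                            min_aa = 40L, alpha = 0.05, seed = 42L,
                            out_dir = "npmine_out") {
  for (p in c(fasta, annotations, signals, counts, motif_library, keywords, scaffolds)) {
    if (!file.exists(p)) stopf("config path does not exist: %s", p)
  }
  if (!is.character(grammar) || length(grammar) == 0L || any(nchar(grammar) != 2L) ||
      any(!grepl("^[KR]{2}$", grammar))) {
    stopf("invalid cleavage grammar: %s", paste(grammar, collapse = ","))
  }
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must be in (0, 1)")
  structure(list(
    fasta = fasta, annotations = annotations, signals = signals, counts = counts,
    motif_library = motif_library, keywords = keywords, scaffolds = scaffolds,
    grammar = grammar, monobasic_r = monobasic_r, min_aa = as.integer(min_aa),
    alpha = alpha, seed = as.integer(seed), out_dir = out_dir
  ), class = "np_config")
}

#' Run the mining pipeline end to end
#'
#' Stages run in order: ORF calling, signal prediction (external annotations
#' taking precedence), maturation, family classification, per-family
#' consensus, and -- when a count matrix is configured -- RPKM quantification
#' with the eyestalk-versus-brain contrast. Every stage logs to stderr; a
#' failing stage aborts with the stage name. Outputs are plain TSV/GFF3 plus
#' a manifest of package version, seed and input checksums; a rerun with the
#' same config is byte-identical except for the manifest timestamp.
#'
#' @param config An `np_config` from [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return Invisibly, a named list of the stage tibbles.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "np_config"))
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    log_stage("[%s] done in %.2fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  tsv <- function(x, f) readr::write_tsv(x, out(f), progress = FALSE)

  transcripts <- stage("read", read_fasta(config$fasta))

  orfs <- stage("orfs", find_orfs(transcripts, min_aa = config$min_aa))
  tsv(orfs, "orfs.tsv")

  precursors <- stage("select", {
    orfs %>% group_by(.data$transcript_id) %>%
      dplyr::group_modify(~ select_precursor_orf(.x)) %>% ungroup()
  })

  ext <- if (!is.null(config$signals)) {
    readr::read_tsv(config$signals, show_col_types = FALSE, progress = FALSE)
  }
  signals <- stage("signals", {
    purrr::map_dfr(seq_len(nrow(precursors)), function(i) {
      tid <- precursors$transcript_id[i]
      pred <- (if (!is.null(ext)) signal_from_annotation(ext, tid)) %||%
        predict_signal_peptide(precursors$protein[i])
      tibble(transcript_id = tid, signal_length = pred$length_aa,
             source = pred$source, score = pred$score)
    })
  })
  tsv(signals, "signals.tsv")

  peptides <- stage("peptides", {
    purrr::map_dfr(seq_len(nrow(precursors)), function(i) {
      sig <- signals$signal_length[i]
      if (sig >= nchar(precursors$protein[i])) sig <- 0L
      pep <- process_precursor(precursors$protein[i], signal = sig,
                               grammar = config$grammar,
                               monobasic_r = config$monobasic_r)
      as_tibble(pep) %>% mutate(transcript_id = precursors$transcript_id[i],
                                .before = 1L)
    })
  })
  tsv(peptides, "peptides.tsv")
  stage("gff", write_gff3_features(
    precursors %>% left_join(signals %>% select("transcript_id", "signal_length"),
                             by = "transcript_id"),
    peptides %>% select("transcript_id", "start_aa", "end_aa", "sequence"),
    out("features.gff3")))

  families <- stage("classify", {
    motif_hits <- match_peptide_motifs(
      peptides %>% mutate(subject_id = paste0(.data$transcript_id, ":", .data$start_aa)),
      default_motif_library(config$motif_library))
    keyword_hits <- if (!is.null(config$annotations)) {
      ann <- readr::read_tsv(config$annotations, show_col_types = FALSE, progress = FALSE)
      keyword_mine(ann, default_keyword_map(config$keywords))
    }
    # peptide-level motif families are lifted to their transcript
    motif_tx <- motif_hits %>%
      mutate(subject_id = sub(":.*$", "", .data$subject_id)) %>%
      distinct(.data$subject_id, .data$family, .keep_all = TRUE)
    if (is.null(keyword_hits) && nrow(motif_tx) == 0L) {
      tibble(subject_id = character(), family = character(), evidence = character(),
             detail = character(), alternatives = character(), ambiguous = logical())
    } else {
      assign_family(motif_hits = motif_tx, keyword_hits = keyword_hits)
    }
  })
  tsv(families, "families.tsv")

  consensus <- stage("conserve", {
    classified <- peptides %>%
      left_join(families %>% select(transcript_id = "subject_id", "family"),
                by = "transcript_id") %>%
      filter(!is.na(.data$family))
    classified %>%
      group_by(.data$family) %>%
      dplyr::group_modify(function(df, key) {
        if (nrow(df) < 2L) return(tibble())
        cm <- tryCatch(consensus_motif(df$sequence, df$amidated),
                       error = function(e) NULL)
        if (is.null(cm)) return(tibble())
        tibble(consensus = cm$consensus, amide = cm$amide,
               n_members = length(cm$members), n_invariant = cm$n_invariant)
      }) %>% ungroup()
  })
  tsv(consensus, "consensus.tsv")

  if (!is.null(config$counts)) {
    quant <- stage("quant", {
      first <- readLines(config$counts, n = 1L)
      if (!startsWith(first, "#lib_sizes")) {
        stopf("counts TSV must start with a '#lib_sizes' header line")
      }
      libs <- as.numeric(strsplit(trimws(sub("^#lib_sizes", "", first)), "\\s+")[[1]])
      cts <- readr::read_tsv(config$counts, skip = 1L, show_col_types = FALSE,
                             progress = FALSE)
      samples <- tibble(sample = c("m_br", "f_br", "m_es", "f_es"),
                        tissue = c("brain", "brain", "eyestalk", "eyestalk"),
                        sex = c("M", "F", "M", "F"),
                        lib_size = libs)
      lengths <- transcripts %>% select(transcript_id = "id", "length_nt")
      rpkm <- rpkm_table(cts, lengths, samples)
      summarize_expression(rpkm, alpha = config$alpha)
    })
    tsv(quant, "expression.tsv")
  } else {
    log_stage("[quant] skipped: no count matrix configured")
    quant <- NULL
  }

  manifest <- tibble(
    key = c("npmine_version", "seed", "alpha", "grammar", "timestamp",
            paste0("md5_", basename(unlist(config[c("fasta", "annotations",
                                                    "signals", "counts")])))),
    value = c(as.character(utils::packageVersion("npmine")),
              as.character(config$seed), as.character(config$alpha),
              paste(config$grammar, collapse = ","),
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              unname(tools::md5sum(unlist(config[c("fasta", "annotations",
                                                   "signals", "counts")]))))
  )
  tsv(manifest, "manifest.tsv")

  invisible(list(transcripts = transcripts, orfs = orfs, precursors = precursors,
                 signals = signals, peptides = peptides, families = families,
                 consensus = consensus, expression = quant))
}
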