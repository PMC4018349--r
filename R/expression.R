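#' Reads per kilobase per million mapped reads
#'
#' `rpkm = counts * 1e9 / (length_nt * lib_size)`: the count normalised by
#' transcript length (per kilobase) and sequencing depth (per million mapped
#' reads). Vectorised over all arguments.
#'
#' @param counts Non-negative read counts.
#' @param length_nt Transcript length in nucleotides (>= 1).
#' @param lib_size Total mapped reads in the library (>= 1).
#' @return Numeric RPKM values.
#' @examples
#' compute_rpkm(1000, 1000, 1e6) # 1000
#' @export
compute_rpkm <- function(counts, length_nt, lib_size) {
  if (any(length_nt < 1)) stopf("transcript length must be >= 1 nt")
  if (any(lib_size < 1)) stopf("library size must be >= 1 read")
  if (any(counts < 0)) stopf("counts must be non-negative")
  counts * 1e9 / (length_nt * lib_size)
}

#' RPKM table from a count matrix
#'
#' @param counts Tibble with `transcript_id` plus one integer column per
#'   sample.
#' @param lengths Tibble with `transcript_id` and `length_nt`.
#' @param samples Tibble with `sample`, `tissue` (`"brain"`/`"eyestalk"`),
#'   `sex` (`"M"`/`"F"`) and `lib_size`.
#' @return Long tibble: `transcript_id`, `sample`, `tissue`, `sex`, `counts`,
#'   `rpkm`.
#' @export
rpkm_table <- function(counts, lengths, samples) {
  missing <- setdiff(samples$sample, names(counts))
  if (length(missing) > 0L) stopf("count matrix lacks sample column(s): %s",
                                  paste(missing, collapse = ", "))
  long <- counts %>%
    tidyr::pivot_longer(dplyr::all_of(samples$sample),
                        names_to = "sample", values_to = "counts") %>%
    left_join(samples, by = "sample") %>%
    left_join(lengths, by = "transcript_id")
  if (any(is.na(long$length_nt))) {
    stopf("missing transcript length for %s",
          long$transcript_id[is.na(long$length_nt)][1])
  }
  bad <- long %>% group_by(.data$sample) %>%
    summarise(tot = sum(.data$counts), .groups = "drop") %>%
    left_join(samples, by = "sample") %>%
    filter(.data$tot > .data$lib_size)
  if (nrow(bad) > 0L) {
    stopf("sample %s has more mapped reads than its library size", bad$sample[1])
  }
  long %>%
    mutate(rpkm = compute_rpkm(.data$counts, .data$length_nt, .data$lib_size)) %>%
    select("transcript_id", "sample", "tissue", "sex", "counts", "rpkm")
}

#' Eyestalk-versus-brain expression contrast
#'
#' One-way ANOVA on RPKM values per transcript, contrasting the two tissues;
#' with two groups this is equivalent to a two-sided pooled t-test, mirroring
#' how per-gene tissue contrasts are computed on pooled-sample designs. Each
#' tissue needs at least two values (a single sample per group leaves nothing
#' to test, as with male-versus-female in a one-animal-per-cell design).
#' When both groups have zero variance, p is 1 for equal means and 0
#' otherwise. RPKM is analysed untransformed by default; `log2_transform`
#' applies `log2(x + 1)` first.
#'
#' @param rpkm Long tibble as from [rpkm_table()]: `transcript_id`, `tissue`,
#'   `rpkm` (extra columns are kept for [summarize_expression()]).
#' @param alpha Significance threshold (default 0.05).
#' @param log2_transform Analyse `log2(rpkm + 1)` instead of raw RPKM.
#' @return Object of class `np_contrast`: tibble with `transcript_id`,
#'   `brain_mean`, `eyestalk_mean`, `p_value`, `significant`.
#' @export
tissue_contrast <- function(rpkm, alpha = 0.05, log2_transform = FALSE) {
  stopifnot(all(c("transcript_id", "tissue", "rpkm") %in% names(rpkm)))
  bad_tissue <- setdiff(unique(rpkm$tissue), c("brain", "eyestalk"))
  if (length(bad_tissue) > 0L) stopf("unknown tissue label: %s", bad_tissue[1])
  counts_per <- rpkm %>% dplyr::count(.data$transcript_id, .data$tissue)
  if (any(counts_per$n < 2L) || any(table(counts_per$transcript_id) < 2L)) {
    stopf("tissue contrast needs >= 2 values in each of the two tissue groups")
  }
  res <- rpkm %>%
    group_by(.data$transcript_id) %>%
    summarise(
      brain_mean = mean(.data$rpkm[.data$tissue == "brain"]),
      eyestalk_mean = mean(.data$rpkm[.data$tissue == "eyestalk"]),
      p_value = anova_p(if (log2_transform) log2(.data$rpkm + 1) else .data$rpkm,
                        .data$tissue),
      .groups = "drop"
    ) %>%
    mutate(significant = .data$p_value < alpha)
  structure(res, class = c("np_contrast", class(res)), alpha = alpha)
}

# One-way fixed-effects ANOVA p-value with explicit handling of the
# zero-residual-variance corner (lm's F statistic is 0/0 there).
anova_p <- function(y, g) {
  g <- factor(g)
  means <- tapply(y, g, mean)
  ss_within <- sum((y - means[g])^2)
  if (ss_within < 1e-12 * max(1, mean(y)^2)) {
    return(if (max(means) - min(means) < 1e-12) 1 else 0)
  }
  tab <- anova(lm(y ~ g))
  unname(tab$`Pr(>F)`[1L])
}

#' Table-shaped expression report
#'
#' Collapses a per-sample RPKM table and its tissue contrast into the report
#' layout used for per-transcript expression summaries: the four sample RPKMs
#' (male/female by brain/eyestalk), the two tissue means, and a significance
#' mark. Transcripts that cannot be tested (fewer than two values per tissue)
#' are kept and marked untestable rather than dropped.
#'
#' @param rpkm Long tibble from [rpkm_table()] (needs `sex` and `tissue`).
#' @param alpha Significance threshold.
#' @return Tibble with columns `transcript_id`, `m_br`, `f_br`, `m_es`,
#'   `f_es`, `br_mean`, `es_mean`, `p_value`, `significant`, `untestable`.
#' @export
summarize_expression <- function(rpkm, alpha = 0.05) {
  wide <- rpkm %>%
    mutate(cell = paste0(tolower(.data$sex), "_",
                         ifelse(.data$tissue == "brain", "br", "es"))) %>%
    group_by(.data$transcript_id, .data$cell) %>%
    summarise(rpkm = mean(.data$rpkm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "cell", values_from = "rpkm")
  for (col in c("m_br", "f_br", "m_es", "f_es")) {
    if (is.null(wide[[col]])) wide[[col]] <- NA_real_
  }
  contrast <- tryCatch(
    tissue_contrast(rpkm, alpha = alpha) %>%
      select("transcript_id", "p_value", "significant") %>%
      mutate(untestable = FALSE),
    error = function(e) {
      tibble(transcript_id = unique(rpkm$transcript_id),
             p_value = NA_real_, significant = NA, untestable = TRUE)
    }
  )
  wide %>%
    mutate(br_mean = rowMeans(cbind(.data$m_br, .data$f_br)),
           es_mean = rowMeans(cbind(.data$m_es, .data$f_es))) %>%
    left_join(contrast, by = "transcript_id") %>%
    select("transcript_id", "m_br", "f_br", "m_es", "f_es",
           "br_mean", "es_mean", "p_value", "significant", "untestable")
}

#' @export
print.np_contrast <- function(x, ...) {
  cat(sprintf("Eyestalk vs brain contrast (alpha = %g): %d/%d significant\n",
              attr(x, "alpha"), sum(x$significant), nrow(x)))
  NextMethod()
}

#' Tidy an expression contrast
#'
#' @param x An `np_contrast` object.
#' @param ... Unused.
#' @return One row per transcript with means, p-value, significance call.
#' @method tidy np_contrast
#' @export
tidy.np_contrast <- function(x, ...) {
  as_tibble(x)
}

#' One-line summary of an expression contrast
#'
#' @param x An `np_contrast` object.
#' @param ... Unused.
#' @return Tibble with `n_transcripts`, `n_significant`, `alpha`.
#' @method glance np_contrast
#' @export
glance.np_contrast <- function(x, ...) {
  tibble(n_transcripts = nrow(x),
         n_significant = sum(x$significant),
         alpha = attr(x, "alpha"))
}
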