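#' Consensus binding-site motif set
#'
#' The two SELEX-derived Csde1 consensus sites, expressed over the RNA
#' alphabet and expanded deterministically to DNA (U -> T) for scanning:
#' \itemize{
#'   \item M1: `[A/G]5 AAGUA [A/G]` (11 nt)
#'   \item M2: `[A/G]7 AAC [A/G]2` (12 nt)
#' }
#' A third 6-nt motif from melanoma iCLIP (`[C/G/U]AAG[A/U/G]A`) is available
#' with `include_iclip = TRUE` but excluded from defaults: it matches so
#' ubiquitously that it is uninformative for sequence-level scanning.
#'
#' @param include_iclip Include the short iCLIP 6-mer (default `FALSE`).
#' @return Data frame with columns `motif_id`, `pattern_rna`, `regex_dna`,
#'   `width`.
#' @export
motif_set <- function(include_iclip = FALSE) {
  m <- data.frame(
    motif_id    = c("M1", "M2"),
    pattern_rna = c("[AG]{5}AAGUA[AG]", "[AG]{7}AAC[AG]{2}"),
    regex_dna   = c("[AG]{5}AAGTA[AG]", "[AG]{7}AAC[AG]{2}"),
    width       = c(11L, 12L),
    stringsAsFactors = FALSE
  )
  if (include_iclip) {
    m <- rbind(m, data.frame(motif_id = "iCLIP6",
                             pattern_rna = "[CGU]AAG[AUG]A",
                             regex_dna = "[CGT]AAG[ATG]A", width = 6L))
  }
  m
}

#' Scan one transcript for consensus binding sites
#'
#' Reports every match start position, including overlapping matches, in
#' ascending order. A site is attributed to the region (5'UTR/CDS/3'UTR)
#' containing its start position, even when it spans a region boundary.
#' Matches are exact over `{A,C,G,T}`; a window containing `N` can never
#' match.
#'
#' @param t A [transcript_record()].
#' @param motifs Motif table from [motif_set()].
#' @return Data frame of hits with columns `transcript_id`, `motif_id`,
#'   `start` (0-based), `end` (exclusive), `matched_seq`, `region`. Zero rows
#'   when nothing matches.
#' @examples
#' t <- transcript_record("tx", "GGGGGAAGTAG", 0, 0)
#' scan_transcript(t)
#' @export
scan_transcript <- function(t, motifs = motif_set()) {
  stopifnot(inherits(t, "TranscriptRecord"))
  out <- empty_hits()
  if (!nzchar(t$sequence)) return(out)
  for (i in seq_len(nrow(motifs))) {
    # lookahead makes gregexpr report overlapping match starts
    starts1 <- gregexpr(paste0("(?=", motifs$regex_dna[i], ")"),
                        t$sequence, perl = TRUE)[[1]]
    if (starts1[1] == -1) next
    w <- motifs$width[i]
    start0 <- as.integer(starts1) - 1L
    out <- rbind(out, data.frame(
      transcript_id = t$transcript_id,
      motif_id      = motifs$motif_id[i],
      start         = start0,
      end           = start0 + w,
      matched_seq   = substring(t$sequence, start0 + 1L, start0 + w),
      region        = region_of_position(t, start0),
      stringsAsFactors = FALSE
    ))
  }
  out[order(out$start, out$motif_id), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(transcript_id = character(), motif_id = character(),
             start = integer(), end = integer(), matched_seq = character(),
             region = character(), stringsAsFactors = FALSE)
}

#' Scan a cohort of transcripts
#'
#' @param transcripts List of `TranscriptRecord`.
#' @param motifs Motif table from [motif_set()].
#' @return One combined hit data frame (see [scan_transcript()]).
#' @export
scan_cohort <- function(transcripts, motifs = motif_set()) {
  do.call(rbind, c(list(empty_hits()),
                   lapply(transcripts, scan_transcript, motifs = motifs)))
}

#' Summarize binding-site occurrence over a cohort
#'
#' Counts transcripts, not hits: a transcript contributes at most once per
#' region regardless of how many sites it carries there, which makes the
#' percentages insensitive to overlapping-match multiplicity. Transcripts
#' flagged as pseudogenes are excluded when `exclude_pseudogenes` is set, to
#' avoid double counting gene copies.
#'
#' @param hits Hit data frame from [scan_cohort()].
#' @param cohort List of the `TranscriptRecord`s that were scanned.
#' @param exclude_pseudogenes Drop `is_pseudogene` transcripts (default TRUE).
#' @return Object of class `CohortMotifSummary`: `n_transcripts`,
#'   `n_with_any_site`, `percent_any`, per-region counts/percentages,
#'   `total_hits`.
#' @export
summarize_cohort <- function(hits, cohort, exclude_pseudogenes = TRUE) {
  ids <- vapply(cohort, `[[`, "", "transcript_id")
  unknown <- setdiff(unique(hits$transcript_id), ids)
  if (length(unknown))
    stop_ripcor("hits reference transcripts not in the cohort: %s",
                paste(utils::head(unknown, 5), collapse = ", "))
  if (exclude_pseudogenes) {
    pseudo <- ids[vapply(cohort, `[[`, FALSE, "is_pseudogene")]
    ids <- setdiff(ids, pseudo)
    hits <- hits[!hits$transcript_id %in% pseudo, , drop = FALSE]
  }
  n <- length(ids)
  regions <- c("UTR5", "CDS", "UTR3")
  region_counts <- vapply(regions, function(r)
    length(unique(hits$transcript_id[hits$region == r])), 0L)
  pct <- function(k) if (n == 0) 0 else 100 * k / n
  structure(list(
    n_transcripts = n,
    n_with_any_site = length(unique(hits$transcript_id)),
    percent_any = pct(length(unique(hits$transcript_id))),
    region_counts = region_counts,
    region_percent = vapply(region_counts, pct, 0),
    total_hits = nrow(hits)
  ), class = "CohortMotifSummary")
}

#' @export
print.CohortMotifSummary <- function(x, ...) {
  cat(sprintf("CohortMotifSummary: %d transcripts, %d (%.1f%%) with >=1 site, %d total hits\n",
              x$n_transcripts, x$n_with_any_site, x$percent_any, x$total_hits))
  for (r in names(x$region_counts))
    cat(sprintf("  %-4s %4d (%.1f%%)\n", r, x$region_counts[[r]],
                x$region_percent[[r]]))
  invisible(x)
}

#' Sample a background transcript cohort
#'
#' Uniform sampling without replacement from a universe, after removing the
#' target cohort, reproducible by seed. Used to build the "random
#' transcripts" comparator for [compare_cohorts()].
#'
#' @param universe List of `TranscriptRecord` defining the sampling frame.
#' @param n Number of transcripts to draw.
#' @param seed Integer seed.
#' @param exclude Character vector of transcript ids to remove first
#'   (typically the target cohort).
#' @return List of `TranscriptRecord` of length `n`.
#' @export
sample_background <- function(universe, n, seed, exclude = character()) {
  ids <- vapply(universe, `[[`, "", "transcript_id")
  pool <- which(!ids %in% exclude)
  if (n > length(pool))
    stop_ripcor("cannot draw %d from a pool of %d transcripts", n, length(pool))
  idx <- with_seed(seed, sample(pool, n))
  universe[idx]
}

#' Compare site frequencies between two cohorts
#'
#' Per region (and for "any region"), a two-sided Fisher exact test on the
#' 2x2 table (with-site / without-site) x (target / background), with the
#' odds ratio and Benjamini-Hochberg adjustment across regions. When a table
#' margin is zero the odds ratio uses the Haldane-Anscombe 0.5 correction and
#' the row is flagged.
#'
#' @param target,background `CohortMotifSummary` objects.
#' @return Data frame with columns `region`, counts, `odds_ratio`, `p_value`,
#'   `fdr`, `or_corrected`.
#' @export
compare_cohorts <- function(target, background) {
  if (target$n_transcripts == 0 || background$n_transcripts == 0)
    stop_ripcor("both cohorts must be non-empty")
  rows <- lapply(c("any", names(target$region_counts)), function(r) {
    a <- if (r == "any") target$n_with_any_site else target$region_counts[[r]]
    b <- if (r == "any") background$n_with_any_site else background$region_counts[[r]]
    tab <- matrix(c(a, target$n_transcripts - a,
                    b, background$n_transcripts - b), nrow = 2)
    p <- stats::fisher.test(tab)$p.value
    corrected <- any(tab == 0)
    if (corrected) tab_or <- tab + 0.5 else tab_or <- tab
    or <- (tab_or[1, 1] * tab_or[2, 2]) / (tab_or[2, 1] * tab_or[1, 2])
    data.frame(region = r, target_with = a, target_n = target$n_transcripts,
               background_with = b, background_n = background$n_transcripts,
               odds_ratio = or, p_value = p, or_corrected = corrected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}
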