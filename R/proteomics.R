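#' Detection filter for protein intensities
#'
#' Keeps a protein only if there is at least one group in which it was
#' quantified in every replicate, and drops proteins flagged as reverse-
#' database matches, potential contaminants, or only identified by site when
#' marker columns (`"+"` convention) are present.
#'
#' @param im An [intensity_matrix()].
#' @return Filtered `IntensityMatrix`.
#' @export
filter_detection <- function(im) {
  keep <- rep(TRUE, nrow(im$intensities))
  if (!is.null(im$flags)) {
    for (col in intersect(c("Reverse", "Potential.contaminant",
                            "Only.identified.by.site"), names(im$flags)))
      keep <- keep & !(im$flags[[col]] %in% "+")
  }
  complete_in_some_group <- apply(im$missing_mask, 1, function(miss) {
    any(vapply(unique(im$groups), function(g)
      !any(miss[im$groups == g]), TRUE))
  })
  keep <- keep & complete_in_some_group
  subset_intensity(im, keep)
}

subset_intensity <- function(im, rows) {
  structure(list(intensities = im$intensities[rows, , drop = FALSE],
                 missing_mask = im$missing_mask[rows, , drop = FALSE],
                 groups = im$groups,
                 flags = if (is.null(im$flags)) NULL
                         else im$flags[rows, , drop = FALSE]),
            class = "IntensityMatrix")
}

#' Reference-sample scaling normalization
#'
#' Each sample's scaling factor is its intensity sum divided by the intensity
#' sum of the reference sample (missing cells contribute nothing); dividing
#' each sample by its factor brings all samples to the reference's total.
#'
#' @param im An [intensity_matrix()] on the raw (non-log) scale.
#' @param reference_sample Sample id of the reference column.
#' @return Normalized `IntensityMatrix`; the reference sample is unchanged.
#' @export
normalize_reference_scaling <- function(im, reference_sample) {
  if (!reference_sample %in% colnames(im$intensities))
    stop_ripcor("reference sample '%s' not found", reference_sample)
  totals <- colSums(im$intensities, na.rm = TRUE)
  if (any(totals == 0))
    stop_ripcor("sample(s) with zero total intensity: %s",
                paste(names(totals)[totals == 0], collapse = ", "))
  factors <- totals / totals[reference_sample]
  im$intensities <- sweep(im$intensities, 2, factors, "/")
  im
}

#' Log2-transform an intensity matrix
#'
#' Zeros are impossible by construction (they are masked as missing), so the
#' transform is defined on all observed cells.
#' @param im An [intensity_matrix()].
#' @return `IntensityMatrix` on the log2 scale.
#' @export
log2_transform <- function(im) {
  im$intensities <- log2(im$intensities)
  im
}

#' Left-censored imputation from a downshifted normal
#'
#' Column-wise imputation for intensities missing not at random: per sample,
#' with `m` and `s` the mean and SD of the observed log2 values, missing
#' cells are drawn i.i.d. from `Normal(m - downshift * s, (width * s)^2)`.
#' The defaults (width 0.3, downshift 1.8, in units of the per-sample SD)
#' place imputed values in the low-intensity tail where undetected proteins
#' are expected to lie. The returned record allows exact de-imputation for
#' visualization and correlation analyses.
#'
#' @param im An [intensity_matrix()] already on the log2 scale.
#' @param width Imputation SD as a fraction of the per-sample SD (default 0.3).
#' @param downshift Mean shift in units of the per-sample SD (default 1.8).
#' @param seed Integer seed; the draw is reproducible and does not disturb
#'   the caller's RNG state.
#' @return List with `imputed` (an `IntensityMatrix` with no missing cells)
#'   and `record` (the original mask plus parameters) for [de_impute()].
#' @export
impute_downshifted <- function(im, width = 0.3, downshift = 1.8, seed = NULL) {
  stopifnot(width > 0, downshift >= 0)
  mask <- im$missing_mask
  if (!any(mask))
    return(list(imputed = im,
                record = list(mask = mask, width = width,
                              downshift = downshift, seed = seed)))
  n_obs <- colSums(!mask)
  if (any(n_obs < 2))
    stop_ripcor("column(s) with < 2 observed values (SD undefined): %s",
                paste(colnames(mask)[n_obs < 2], collapse = ", "))
  out <- im$intensities
  with_seed(seed, {
    for (j in seq_len(ncol(out))) {
      obs <- out[!mask[, j], j]
      nmiss <- sum(mask[, j])
      if (nmiss == 0) next
      m <- mean(obs); s <- stats::sd(obs)
      out[mask[, j], j] <- stats::rnorm(nmiss, m - downshift * s, width * s)
    }
  })
  imputed <- im
  imputed$intensities <- out
  imputed$missing_mask <- matrix(FALSE, nrow(mask), ncol(mask),
                                 dimnames = dimnames(mask))
  list(imputed = imputed,
       record = list(mask = mask, width = width, downshift = downshift,
                     seed = seed))
}

#' Undo imputation
#'
#' Restores the original missingness mask recorded by [impute_downshifted()],
#' replacing imputed cells with `NA`.
#' @param im The imputed `IntensityMatrix`.
#' @param record The `record` returned by [impute_downshifted()].
#' @return `IntensityMatrix` with the original mask.
#' @export
de_impute <- function(im, record) {
  im$intensities[record$mask] <- NA_real_
  im$missing_mask <- record$mask
  im
}

#' S0-moderated differential test
#'
#' SAM-style statistics with an artificial variance offset `s0` added to the
#' denominator, damping the significance of proteins whose within-group
#' variance is accidentally tiny:
#' \itemize{
#'   \item `design = "two_group"`: `d = (mean1 - mean2) / (se_pooled + s0)`,
#'     two-sided p from a t distribution with pooled degrees of freedom.
#'   \item `design = "anova"`: F statistic with the within-group mean square
#'     inflated by `s0^2`, p from `F(k-1, N-k)`.
#' }
#' Because the offset can only shrink the statistic, the resulting p-values
#' are conservative. Benjamini-Hochberg adjustment runs across proteins; an
#' optional permutation mode estimates p-values from group-label permutations
#' of the moderated statistic instead.
#'
#' @param im Imputed, log2-scale [intensity_matrix()] with >= 2 replicates
#'   per group.
#' @param s0 Variance offset (0.5 is the convention for two-group t tests,
#'   0.4 for multi-group ANOVA).
#' @param design `"two_group"` or `"anova"`.
#' @param contrast For `two_group`: `c(group1, group2)`.
#' @param fdr_threshold Significance cutoff on the BH-adjusted p (default 0.05).
#' @param mode `"bh"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations in permutation mode.
#' @param seed Seed for permutation mode.
#' @return Data frame: `protein_id`, `stat`, `p_value`, `fdr`, `significant`
#'   (plus `mean_diff` for two-group).
#' @export
moderated_test <- function(im, s0, design = c("two_group", "anova"),
                           contrast = NULL, fdr_threshold = 0.05,
                           mode = c("bh", "permutation"), n_perm = 250,
                           seed = NULL) {
  design <- match.arg(design)
  mode <- match.arg(mode)
  stopifnot(s0 >= 0)
  x <- im$intensities
  if (anyNA(x))
    stop_ripcor("moderated_test expects an imputed matrix with no missing cells")
  groups <- im$groups
  tab <- table(groups)
  if (any(tab < 2)) stop_ripcor("every group needs >= 2 replicates")

  compute <- function(x, groups) {
    if (design == "two_group") {
      if (is.null(contrast) || length(contrast) != 2)
        stop_ripcor("two_group design needs contrast = c(group1, group2)")
      i1 <- groups == contrast[1]; i2 <- groups == contrast[2]
      n1 <- sum(i1); n2 <- sum(i2)
      m1 <- rowMeans(x[, i1, drop = FALSE])
      m2 <- rowMeans(x[, i2, drop = FALSE])
      v1 <- apply(x[, i1, drop = FALSE], 1, stats::var)
      v2 <- apply(x[, i2, drop = FALSE], 1, stats::var)
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      if (s0 == 0 && any(se == 0))
        stop_ripcor("zero within-group variance with s0 = 0; set s0 > 0")
      d <- (m1 - m2) / (se + s0)
      list(stat = d, p = 2 * stats::pt(-abs(d), df = n1 + n2 - 2),
           mean_diff = m1 - m2)
    } else {
      glev <- unique(groups)
      k <- length(glev); N <- length(groups)
      gm <- rowMeans(x)
      ssb <- 0; ssw <- 0
      for (g in glev) {
        xi <- x[, groups == g, drop = FALSE]
        mi <- rowMeans(xi)
        ssb <- ssb + ncol(xi) * (mi - gm)^2
        ssw <- ssw + rowSums((xi - mi)^2)
      }
      msb <- ssb / (k - 1)
      msw <- ssw / (N - k)
      if (s0 == 0 && any(msw == 0))
        stop_ripcor("zero within-group variance with s0 = 0; set s0 > 0")
      f <- msb / (msw + s0^2)
      list(stat = f,
           p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
    }
  }

  obs <- compute(x, groups)
  if (mode == "permutation") {
    exceed <- rep(1, nrow(x))  # +1 pseudo-permutation (the identity)
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        perm <- compute(x, sample(groups))
        exceed <- exceed + (abs(perm$stat) >= abs(obs$stat))
      }
    })
    p <- exceed / (n_perm + 1)
  } else p <- obs$p

  out <- data.frame(protein_id = rownames(x), stat = unname(obs$stat),
                    p_value = unname(p), stringsAsFactors = FALSE)
  if (design == "two_group") out$mean_diff <- unname(obs$mean_diff)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_threshold
  rownames(out) <- NULL
  out
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every K or R not followed by P. The base
#' (fully cleaved) peptides tile the sequence without gaps or overlaps; with
#' `missed_cleavages = k`, concatenations of up to `k + 1` adjacent base
#' peptides are also emitted.
#'
#' @param protein_seq Amino-acid string over the 20-letter alphabet.
#' @param missed_cleavages Maximum missed cleavages (default 0).
#' @return Object of class `PeptideMap`: the sequence plus a data frame of
#'   peptides with `start`/`end` (0-based half-open), `peptide`, `n_missed`,
#'   `observed`.
#' @examples
#' tryptic_digest("AKCR")$peptides$peptide  # "AK" "CR"
#' @export
tryptic_digest <- function(protein_seq, missed_cleavages = 0) {
  protein_seq <- toupper(protein_seq)
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", protein_seq)
  if (bad != -1)
    stop_ripcor("illegal amino acid '%s' at position %d",
                substring(protein_seq, bad, bad), bad)
  n <- nchar(protein_seq)
  aa <- strsplit(protein_seq, "")[[1]]
  # cleavage after position i (1-based) iff aa[i] in {K,R} and aa[i+1] != P
  cut_after <- which(aa %in% c("K", "R") & c(aa[-1], "") != "P")
  bounds <- c(0L, cut_after[cut_after < n], n)
  base <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  peps <- list()
  for (k in 0:missed_cleavages) {
    if (nrow(base) - k < 1) break
    for (i in seq_len(nrow(base) - k)) {
      s <- base$start[i]; e <- base$end[i + k]
      peps[[length(peps) + 1]] <-
        data.frame(start = s, end = e,
                   peptide = substring(protein_seq, s + 1, e), n_missed = k)
    }
  }
  peptides <- do.call(rbind, peps)
  peptides$observed <- FALSE
  structure(list(sequence = protein_seq, peptides = peptides),
            class = "PeptideMap")
}

#' Mark observed peptides on a digest map
#'
#' Marks `observed = TRUE` for peptides whose sequence exactly matches an
#' entry in `observed`; observed strings not produced by the digest are
#' returned in `unassigned`.
#'
#' @param pm A `PeptideMap` from [tryptic_digest()].
#' @param observed Character vector of detected peptide sequences.
#' @return `PeptideMap` with updated `observed` flags plus fields
#'   `n_observed`, `n_predicted`, `coverage` and `unassigned`.
#' @export
map_observed_peptides <- function(pm, observed) {
  pm$peptides$observed <- pm$peptides$peptide %in% observed
  pm$n_observed <- sum(pm$peptides$observed)
  pm$n_predicted <- nrow(pm$peptides)
  pm$coverage <- if (pm$n_predicted) pm$n_observed / pm$n_predicted else 0
  pm$unassigned <- setdiff(observed, pm$peptides$peptide)
  pm
}

#' @export
print.PeptideMap <- function(x, ...) {
  cat(sprintf("PeptideMap: %d aa, %d peptides", nchar(x$sequence),
              nrow(x$peptides)))
  if (!is.null(x$n_observed))
    cat(sprintf(", %d of %d observed", x$n_observed, x$n_predicted))
  cat("\n")
  invisible(x)
}
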