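#' Synthetic transcripts with planted consensus sites
#'
#' Generates self-contained mRNA records: i.i.d. uniform background sequence,
#' UTR/CDS boundaries drawn so the CDS is at least 30 nt and a multiple of 3,
#' and, independently per region with the given rate, one concrete motif
#' instance (M1 or M2, equal odds, degenerate positions resolved at random)
#' overwritten at a uniform in-region position. Planted sites are recorded in
#' the returned truth object; spontaneous background matches can only add to
#' what a scan recovers.
#'
#' @param n Number of transcripts.
#' @param length_mean,length_sd Transcript length distribution in nt
#'   (normal, truncated below at 300).
#' @param motif_rates Named planting probabilities, `c(UTR5=, CDS=, UTR3=)`.
#'   Defaults emulate the site frequencies seen in erythroid RIP cohorts:
#'   rare in the short 5'UTR, ~15% of transcripts with a CDS site, ~10% with
#'   a 3'UTR site.
#' @param seed Integer seed; identical seeds give identical records.
#' @return List with `transcripts` (list of [transcript_record()]) and
#'   `truth` (class `SyntheticTruth`): planting table, rates, seed.
#' @export
gen_transcripts <- function(n, length_mean = 1500, length_sd = 500,
                            motif_rates = c(UTR5 = 0.02, CDS = 0.15,
                                            UTR3 = 0.10),
                            seed = 1) {
  stopifnot(all(motif_rates >= 0 & motif_rates <= 1),
            all(c("UTR5", "CDS", "UTR3") %in% names(motif_rates)))
  motifs <- motif_set()
  with_seed(seed, {
    transcripts <- vector("list", n)
    planted <- list()
    for (i in seq_len(n)) {
      repeat {
        L <- max(300L, as.integer(round(stats::rnorm(1, length_mean, length_sd))))
        utr5 <- as.integer(round(stats::runif(1, 0.05, 0.20) * L))
        cds <- as.integer(round(stats::runif(1, 0.40, 0.60) * L))
        cds <- max(30L, cds - cds %% 3L)
        if (utr5 + cds >= L) next
        seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
        bounds <- list(UTR5 = c(0L, utr5), CDS = c(utr5, utr5 + cds),
                       UTR3 = c(utr5 + cds, L))
        ok <- TRUE
        rows <- list()
        for (reg in names(motif_rates)) {
          if (stats::runif(1) >= motif_rates[[reg]]) next
          mi <- sample(nrow(motifs), 1)
          w <- motifs$width[mi]
          lo <- bounds[[reg]][1]; hi <- bounds[[reg]][2] - w
          if (hi < lo) { ok <- FALSE; break }  # region too short: regenerate
          start <- lo + sample.int(hi - lo + 1L, 1) - 1L
          inst <- instantiate_motif(motifs$regex_dna[mi])
          seq_chars[(start + 1):(start + w)] <- strsplit(inst, "")[[1]]
          rows[[length(rows) + 1]] <- data.frame(
            transcript_id = sprintf("SYNT%05d", i), motif_id = motifs$motif_id[mi],
            region = reg, start = start, instance = inst,
            stringsAsFactors = FALSE)
        }
        if (!ok) next
        transcripts[[i]] <- transcript_record(
          sprintf("SYNT%05d", i), paste(seq_chars, collapse = ""),
          utr5, utr5 + cds, gene_symbol = sprintf("Gene%05d", i))
        planted <- c(planted, rows)
        break
      }
    }
    truth <- structure(list(
      planted = if (length(planted)) do.call(rbind, planted) else
        data.frame(transcript_id = character(), motif_id = character(),
                   region = character(), start = integer(),
                   instance = character()),
      motif_rates = as.list(motif_rates), n = n, seed = seed),
      class = "SyntheticTruth")
    list(transcripts = transcripts, truth = truth)
  })
}

# draw one concrete sequence matching a fixed-length character-class regex
instantiate_motif <- function(regex) {
  out <- character()
  i <- 1
  chars <- strsplit(regex, "")[[1]]
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      cls <- chars[(i + 1):(j - 1)]
      reps <- 1L
      if (j < length(chars) && chars[j + 1] == "{") {
        k <- which(chars == "}" & seq_along(chars) > j)[1]
        reps <- as.integer(paste(chars[(j + 2):(k - 1)], collapse = ""))
        j <- k
      }
      out <- c(out, sample(cls, reps, replace = TRUE))
      i <- j + 1
    } else {
      out <- c(out, chars[i])
      i <- i + 1
    }
  }
  paste(out, collapse = "")
}

#' Synthetic pulldown count matrix with planted enrichment
#'
#' Per-gene baseline means are log-normal; a planted fraction of genes
#' carries a true log2 fold change in the first group (the pulldown); counts
#' are negative-binomial with shared dispersion, scaled by sample-level size
#' factors drawn log-uniform in `[0.5, 2]`. The default 3 vs 3 design mirrors
#' a triplicate pulldown against a triplicate control.
#'
#' @param n_genes Number of genes.
#' @param group_sizes Named integer vector of replicates per group; first
#'   group is the pulldown.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters
#'   (natural log scale).
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#' @param enriched_frac Fraction of genes planted as enriched.
#' @param true_lfc Planted log2 fold change.
#' @param lengths_range Range for uniformly drawn transcript lengths (nt).
#' @param seed Integer seed.
#' @return List with `cm` (a [count_matrix()] with lengths) and `truth`
#'   (`SyntheticTruth`: enriched gene ids, per-gene true lfc, size factors,
#'   dispersion, seed).
#' @export
gen_counts <- function(n_genes = 2000,
                       group_sizes = c(pulldown = 3, control = 3),
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       dispersion = 0.05, enriched_frac = 0.1, true_lfc = 2,
                       lengths_range = c(500, 4000), seed = 1) {
  stopifnot(enriched_frac >= 0, enriched_frac <= 1, dispersion > 0)
  with_seed(seed, {
    samples <- unlist(lapply(names(group_sizes), function(g)
      paste0(g, "_", seq_len(group_sizes[[g]]))))
    groups <- stats::setNames(rep(names(group_sizes), group_sizes), samples)
    genes <- sprintf("gene%05d", seq_len(n_genes))
    baseline <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    n_enr <- round(enriched_frac * n_genes)
    lfc <- stats::setNames(rep(0, n_genes), genes)
    if (n_enr > 0) lfc[sample(n_genes, n_enr)] <- true_lfc
    sf <- exp(stats::runif(length(samples), log(0.5), log(2)))
    names(sf) <- samples
    pull <- groups == names(group_sizes)[1]
    mu <- outer(baseline, sf) * 2^(outer(lfc, as.numeric(pull)))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = n_genes, dimnames = list(genes, samples))
    lengths <- stats::setNames(
      round(stats::runif(n_genes, lengths_range[1], lengths_range[2])), genes)
    truth <- structure(list(
      enriched = genes[lfc != 0], true_lfc = lfc, size_factors = sf,
      dispersion = dispersion, seed = seed), class = "SyntheticTruth")
    list(cm = count_matrix(counts, groups, lengths = lengths), truth = truth)
  })
}

#' Synthetic proteome coupled to an RNA count matrix
#'
#' For each gene, a latent RNA-protein correlation `rho_g` is drawn from a
#' truncated normal on `[-1, 1]`; the log2 protein profile across samples is
#' `rho_g * z + sqrt(1 - rho_g^2) * eps + offset_g`, where `z` is the
#' Z-scored log2 depth-normalized RNA profile and `eps` is standard normal
#' scaled by `noise_sd` (the default 1 makes `rho_g` the exact latent
#' correlation). Cells then go missing with probability
#' `plogis(b0 - b1 * log2intensity)`, so low-abundance proteins are
#' preferentially lost (MNAR, left-censoring). Intensities are returned on
#' the raw (iBAQ-like) scale, `2^log2intensity`.
#'
#' @param cm A [count_matrix()], e.g. from [gen_counts()]; the default study
#'   design is 7 groups x 3 replicates = 21 samples.
#' @param rho_mean,rho_sd Parameters of the truncated-normal `rho`
#'   distribution (defaults 0.1 and 0.3, centred on the modal RNA-protein
#'   correlation reported for erythroid cells).
#' @param noise_sd SD multiplier of the orthogonal noise term.
#' @param missing_model `c(b0, b1)` of the logistic missingness model; at the
#'   defaults a protein 5 log2 units below a typical offset of 25 is missing
#'   about half the time.
#' @param offset_mean,offset_sd Per-gene log2 abundance offsets.
#' @param seed Integer seed.
#' @return List with `im` (an [intensity_matrix()]) and `truth`
#'   (`SyntheticTruth`: per-gene `rho`, offsets, model parameters, seed).
#' @export
gen_proteome <- function(cm, rho_mean = 0.1, rho_sd = 0.3, noise_sd = 1,
                         missing_model = c(b0 = 20, b1 = 1),
                         offset_mean = 25, offset_sd = 3, seed = 1) {
  if (ncol(cm$counts) < 2) stop_ripcor("count matrix needs >= 2 samples")
  with_seed(seed, {
    n <- nrow(cm$counts)
    # truncated-normal draw on [-1, 1]
    rho <- stats::rnorm(n, rho_mean, rho_sd)
    while (any(bad <- abs(rho) > 1))
      rho[bad] <- stats::rnorm(sum(bad), rho_mean, rho_sd)
    cpm <- sweep(cm$counts, 2, colSums(cm$counts) / 1e6, "/")
    z <- zscore_rows(log2(cpm + 1))
    eps <- matrix(stats::rnorm(length(z), 0, noise_sd), nrow = n)
    offsets <- stats::rnorm(n, offset_mean, offset_sd)
    log2int <- rho * z + sqrt(1 - rho^2) * eps + offsets
    pmiss <- stats::plogis(missing_model[["b0"]] - missing_model[["b1"]] * log2int)
    miss <- matrix(stats::runif(length(log2int)) < pmiss, nrow = n)
    raw <- 2^log2int
    raw[miss] <- NA_real_
    dimnames(raw) <- dimnames(cm$counts)
    truth <- structure(list(
      rho = stats::setNames(rho, rownames(cm$counts)), offsets = offsets,
      noise_sd = noise_sd, missing_model = as.list(missing_model),
      seed = seed), class = "SyntheticTruth")
    list(im = intensity_matrix(raw, cm$groups), truth = truth)
  })
}

#' Synthetic qPCR Ct table with a planted fold change
#'
#' Case-condition target Cts are shifted by `-log2(fold)` relative to the
#' control condition; all Cts carry i.i.d. normal noise. The layout matches
#' [qpcr_fold_change()].
#'
#' @param fold Planted fold enrichment (> 0).
#' @param ct_ref Reference Ct level.
#' @param noise_sd Ct noise SD.
#' @param n_reps Replicates per condition (default 3).
#' @param seed Integer seed.
#' @return List with `q` (Ct data frame) and `truth` (`SyntheticTruth`).
#' @export
gen_qpcr <- function(fold, ct_ref = 20, noise_sd = 0.1, n_reps = 3, seed = 1) {
  stopifnot(fold > 0)
  with_seed(seed, {
    noise <- function(k) stats::rnorm(k, 0, noise_sd)
    q <- rbind(
      data.frame(condition = "case", gene = "target", replicate = seq_len(n_reps),
                 ct = ct_ref - log2(fold) + noise(n_reps)),
      data.frame(condition = "case", gene = "reference", replicate = seq_len(n_reps),
                 ct = ct_ref + noise(n_reps)),
      data.frame(condition = "control", gene = "target", replicate = seq_len(n_reps),
                 ct = ct_ref + noise(n_reps)),
      data.frame(condition = "control", gene = "reference", replicate = seq_len(n_reps),
                 ct = ct_ref + noise(n_reps)))
    truth <- structure(list(fold = fold, ct_ref = ct_ref, noise_sd = noise_sd,
                            n_reps = n_reps, seed = seed),
                       class = "SyntheticTruth")
    list(q = q, truth = truth)
  })
}

#' Serialize a synthetic ground truth to JSON
#'
#' Every generator's truth can be written next to its dataset so recovery
#' tests read only data plus truth.
#' @param truth A `SyntheticTruth`.
#' @param path Output JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
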