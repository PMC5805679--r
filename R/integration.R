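#' Reads per kilobase per million mapped reads
#'
#' `rpkm[g,s] = count[g,s] / (length_kb[g] * total_s / 1e6)` with `total_s`
#' the sample's column sum, the within-sample RNA abundance normalization
#' used throughout the RNA-protein comparisons.
#'
#' @param cm A [count_matrix()] with `lengths` (nt) present.
#' @return Numeric matrix, genes x samples.
#' @export
rpkm <- function(cm) {
  if (is.null(cm$lengths))
    stop_ripcor("count matrix has no transcript lengths; rpkm needs them")
  if (any(cm$lengths <= 0)) stop_ripcor("transcript lengths must be > 0")
  totals <- colSums(cm$counts)
  if (any(totals == 0))
    stop_ripcor("sample(s) with zero total counts: %s",
                paste(colnames(cm$counts)[totals == 0], collapse = ", "))
  sweep(cm$counts / (cm$lengths / 1000), 2, totals / 1e6, "/")
}

#' Z-scores (sample-SD convention)
#'
#' `(x - mean) / sd` with the n-1 denominator. A zero-SD vector maps to
#' all zeros and carries attribute `flagged = TRUE`.
#'
#' @param values Numeric vector, length >= 2.
#' @return Z-score vector (mean 0, SD 1 when the input varies).
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop_ripcor("zscore needs >= 2 values")
  s <- stats::sd(values)
  if (s == 0) return(structure(rep(0, length(values)), flagged = TRUE))
  (values - mean(values)) / s
}

#' Row-wise Z-scores of a matrix
#' @param m Numeric matrix; rows are standardized independently.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  t(apply(m, 1, zscore))
}

#' Per-gene RNA-protein Pearson correlation
#'
#' For each gene present in both layers, the Pearson correlation across
#' samples between its RNA values and its protein values (pairwise-complete:
#' samples where the protein is missing are dropped for that gene). Pearson
#' is affine-invariant, so Z-scored and raw inputs give identical
#' coefficients.
#'
#' @param rna Numeric matrix genes x samples (e.g. RPKM or Z-scores).
#' @param prot Numeric matrix genes x samples (may contain `NA`), same
#'   sample columns.
#' @param min_pairs Minimum complete pairs per gene (default 3).
#' @return Data frame: `gene_id`, `r`, `n_pairs`, `flagged` (undefined
#'   correlation, excluded from distribution summaries).
#' @export
per_gene_correlation <- function(rna, prot, min_pairs = 3) {
  if (!identical(colnames(rna), colnames(prot)))
    stop_ripcor("rna and prot must have identical sample columns")
  genes <- intersect(rownames(rna), rownames(prot))
  if (!length(genes)) stop_ripcor("no shared genes between layers")
  res <- lapply(genes, function(g) {
    x <- rna[g, ]; y <- prot[g, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_pairs)
      return(data.frame(gene_id = g, r = NA_real_, n_pairs = sum(ok),
                        flagged = TRUE))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(gene_id = g, r = NA_real_, n_pairs = sum(ok),
                        flagged = TRUE))
    data.frame(gene_id = g, r = stats::cor(x[ok], y[ok]),
               n_pairs = sum(ok), flagged = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-sample RNA-protein Spearman correlation
#'
#' Within each sample, the Spearman rank correlation over genes between
#' `log10(RPKM)` and `log10(iBAQ)`. Genes with RPKM 0 or missing protein
#' intensity in that sample are excluded (no pseudocount).
#'
#' @param rpkm_mat Genes x samples RPKM matrix.
#' @param ibaq_mat Genes x samples normalized intensity matrix (`NA` =
#'   missing); rows matched by name.
#' @param min_genes Minimum complete genes per sample (default 10); below it
#'   the sample gets `NA` with a warning.
#' @return Data frame: `sample_id`, `rho`, `n_genes`.
#' @export
per_sample_correlation <- function(rpkm_mat, ibaq_mat, min_genes = 10) {
  if (!identical(colnames(rpkm_mat), colnames(ibaq_mat)))
    stop_ripcor("matrices must have identical sample columns")
  genes <- intersect(rownames(rpkm_mat), rownames(ibaq_mat))
  if (!length(genes)) stop_ripcor("no shared genes between layers")
  r <- rpkm_mat[genes, , drop = FALSE]
  p <- ibaq_mat[genes, , drop = FALSE]
  res <- lapply(colnames(r), function(s) {
    ok <- !is.na(r[, s]) & r[, s] > 0 & !is.na(p[, s]) & p[, s] > 0
    if (sum(ok) < min_genes) {
      warning(sprintf("sample '%s': only %d complete genes (< %d); rho = NA",
                      s, sum(ok), min_genes))
      return(data.frame(sample_id = s, rho = NA_real_, n_genes = sum(ok)))
    }
    rho <- stats::cor(log10(r[ok, s]), log10(p[ok, s]), method = "spearman")
    data.frame(sample_id = s, rho = rho, n_genes = sum(ok))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Distribution of correlation coefficients, split by cohort
#'
#' Histogram over `[-1, 1]` with bin width 0.1 (edges at -1.0, -0.9, ...),
#' modal bin reported as the leftmost maximum, and a two-sample
#' Kolmogorov-Smirnov comparison between the splits (e.g. RBP-bound
#' transcripts vs background).
#'
#' @param r Numeric vector of correlation coefficients (`NA` dropped).
#' @param split Logical or factor of the same length: `TRUE`/first level =
#'   bound cohort. `NULL` for a single-cohort histogram (no KS test).
#' @return List: `breaks`, `counts` (per split and overall), `modal_bin`
#'   (`c(lo, hi)` of the overall leftmost-maximum bin), `ks` (htest or NULL).
#' @export
correlation_distribution <- function(r, split = NULL) {
  keep <- !is.na(r)
  r <- pmin(pmax(r[keep], -1), 1)
  breaks <- seq(-1, 1, by = 0.1)
  bin <- function(v) {
    # left-closed bins [lo, hi); the final bin includes 1.0
    idx <- pmin(findInterval(v, breaks), length(breaks) - 1)
    tabulate(idx, nbins = length(breaks) - 1)
  }
  counts_all <- bin(r)
  modal_idx <- which.max(counts_all)  # which.max returns the leftmost max
  out <- list(breaks = breaks, counts = counts_all,
              modal_bin = c(breaks[modal_idx], breaks[modal_idx + 1]))
  if (!is.null(split)) {
    split <- split[keep]
    f <- as.logical(split)
    if (sum(f) < 2 || sum(!f) < 2)
      stop_ripcor("each split needs >= 2 coefficients")
    out$counts_split <- list(bound = bin(r[f]), background = bin(r[!f]))
    out$ks <- suppressWarnings(stats::ks.test(r[f], r[!f]))
  }
  out
}

#' Venn partition of named gene sets
#'
#' Exact counts of every membership pattern (2^k - 1 regions for k sets),
#' after normalizing ids (trim whitespace, case-fold).
#'
#' @param sets Named list of character vectors.
#' @return List with `partition` (data frame: one row per membership
#'   pattern, columns per set plus `count`), `pairwise` intersection count
#'   matrix, and `union_size`.
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, function(s) unique(toupper(trimws(s))))
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 1) member <- matrix(member, nrow = 1,
                                             dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, paste, collapse = "")
  pats <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))[-2^length(sets), ,
                                                               drop = FALSE]
  names(pats) <- names(sets)
  pats$count <- vapply(seq_len(nrow(pats)), function(i) {
    key <- paste(unlist(pats[i, seq_along(sets)]), collapse = "")
    sum(pattern == key)
  }, 0L)
  rownames(pats) <- NULL
  pw <- outer(seq_along(sets), seq_along(sets), Vectorize(function(i, j)
    length(intersect(sets[[i]], sets[[j]]))))
  dimnames(pw) <- list(names(sets), names(sets))
  list(partition = pats, pairwise = pw, union_size = length(all_ids))
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test of a query gene set against each
#' category, within a stated universe; categories are intersected with the
#' universe first, and the Benjamini-Hochberg adjustment runs across
#' categories.
#'
#' @param query Character vector (must be a subset of `universe`).
#' @param categories Named list of character vectors (e.g. read from GMT).
#' @param universe Character vector of all testable genes.
#' @return Data frame: `category`, `universe_size`, `category_size`,
#'   `query_size`, `overlap`, `p_value`, `fdr`, sorted by p.
#' @export
hypergeometric_ora <- function(query, categories, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_ripcor("empty universe")
  query <- unique(query)
  if (!all(query %in% universe))
    stop_ripcor("query contains %d gene(s) outside the universe",
                sum(!query %in% universe))
  rows <- lapply(names(categories), function(nm) {
    cat_set <- intersect(unique(categories[[nm]]), universe)
    k <- length(intersect(cat_set, query))
    # P(X >= k), X ~ Hypergeom(|category|, |universe|-|category|, |query|)
    p <- stats::phyper(k - 1, length(cat_set),
                       length(universe) - length(cat_set), length(query),
                       lower.tail = FALSE)
    data.frame(category = nm, universe_size = length(universe),
               category_size = length(cat_set), query_size = length(query),
               overlap = k, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Read gene-set categories from a GMT file
#'
#' One set per line: name, description, then member ids, tab-separated.
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1)
  sets
}
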