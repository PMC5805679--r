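#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth correction: for each sample, the median over
#' genes (restricted to rows positive in every sample) of the ratio
#' count / geometric-mean(row), then rescaled so the factors multiply to 1.
#'
#' @param cm A [count_matrix()].
#' @param pseudocount Added to every count before forming ratios; the default
#'   0 is the standard estimator. Set a small positive value when no gene row
#'   is positive in all samples.
#' @return Named numeric vector of positive factors (product 1), class
#'   `SizeFactors`.
#' @examples
#' cm <- count_matrix(matrix(c(4, 8, 16, 32), 2,
#'                    dimnames = list(c("g1","g2"), c("a","b"))),
#'                    groups = c(a = "x", b = "y"))
#' estimate_size_factors(cm)
#' @export
estimate_size_factors <- function(cm, pseudocount = 0) {
  k <- cm$counts + pseudocount
  allpos <- rowSums(k <= 0) == 0
  if (!any(allpos))
    stop_ripcor(paste0("no gene has positive counts in every sample; ",
                       "re-run with pseudocount > 0"))
  logk <- log(k[allpos, , drop = FALSE])
  loggeo <- rowMeans(logk)
  sf <- apply(logk, 2, function(col) exp(stats::median(col - loggeo)))
  sf <- sf / gmean(sf)
  structure(sf, class = "SizeFactors")
}

# signed pooled within-group method-of-moments NB dispersion on normalized
# counts; NA when the gene has no signal
mom_dispersion_signed <- function(norm, group) {
  mu_hat <- mean(norm)
  if (mu_hat <= 0) return(NA_real_)
  groups <- unique(group)
  ss <- 0; df <- 0
  for (g in groups) {
    x <- norm[group == g]
    if (length(x) >= 2) {
      ss <- ss + sum((x - mean(x))^2)
      df <- df + length(x) - 1
    }
  }
  if (df == 0) return(NA_real_)
  (ss / df - mu_hat) / mu_hat^2
}

# Moderate per-gene MoM dispersions toward the cross-gene mean. At the small
# replicate numbers typical of pulldown designs the raw per-gene estimate is
# so noisy that many genes hit the floor and their Wald statistics blow up;
# weighting by within-group df against a prior df (edgeR convention) restores
# type-I control while leaving genuinely high-dispersion genes penalized.
moderate_dispersions <- function(mom, df_within, prior_df,
                                 floor = 1e-8, ceiling = 10) {
  alpha0 <- mean(mom, na.rm = TRUE)
  if (!is.finite(alpha0)) alpha0 <- floor
  alpha <- (df_within * mom + prior_df * alpha0) / (df_within + prior_df)
  alpha[is.na(alpha)] <- max(alpha0, floor)
  pmin(pmax(alpha, floor), ceiling)
}

#' Negative-binomial Wald test for pulldown enrichment
#'
#' Per-gene test of the contrast `groupA` vs `groupB` on size-factor
#' normalized counts, under the NB variance model `mu + alpha * mu^2`:
#' dispersion `alpha` is estimated by pooled within-group method of moments,
#' moderated toward the cross-gene mean dispersion with `prior_df` prior
#' degrees of freedom and then floored/capped; the log2 fold change uses a
#' 0.5 pseudocount on the normalized group means, the standard error comes
#' from the delta method, and the Wald statistic is referred to a standard
#' normal. Benjamini-Hochberg adjustment runs across the genes that pass
#' independent filtering (`base_mean >= min_base_mean`); filtered genes keep
#' their p-value but get `fdr = NA`.
#'
#' @param cm A [count_matrix()] with group labels.
#' @param sf Size factors; estimated from `cm` when `NULL`.
#' @param contrast Character vector `c(groupA, groupB)`; positive `log2fc`
#'   means higher in `groupA`.
#' @param min_base_mean Independent-filtering threshold on the normalized
#'   mean count (default 1).
#' @param prior_df Prior degrees of freedom for dispersion moderation
#'   (default 20; 0 disables moderation).
#' @param dispersion_floor,dispersion_ceiling Bounds on the per-gene
#'   dispersion estimate.
#' @return Data frame (one row per gene): `gene_id`, `base_mean`, `log2fc`,
#'   `se_log2fc`, `wald_stat`, `p_value`, `fdr`, `direction`.
#' @export
nb_wald_test <- function(cm, sf = NULL, contrast,
                         min_base_mean = 1, prior_df = 20,
                         dispersion_floor = 1e-8, dispersion_ceiling = 10) {
  if (length(contrast) != 2)
    stop_ripcor("contrast must be c(groupA, groupB)")
  if (!all(contrast %in% cm$groups))
    stop_ripcor("contrast groups not found in sample groups")
  ia <- which(cm$groups == contrast[1])
  ib <- which(cm$groups == contrast[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop_ripcor("both contrast groups need >= 2 samples")
  if (is.null(sf)) sf <- estimate_size_factors(cm)
  norm <- sweep(cm$counts, 2, unclass(sf), "/")
  sel <- c(ia, ib)
  grp <- c(rep("A", length(ia)), rep("B", length(ib)))
  sfa <- unclass(sf)[ia]; sfb <- unclass(sf)[ib]

  nsub <- norm[, sel, drop = FALSE]
  mom <- apply(nsub, 1, mom_dispersion_signed, group = grp)
  df_within <- length(sel) - 2
  alphas <- moderate_dispersions(mom, df_within, prior_df,
                                 dispersion_floor, dispersion_ceiling)

  res <- t(vapply(seq_len(nrow(nsub)), function(i) {
    x <- nsub[i, ]
    ma <- mean(x[grp == "A"]); mb <- mean(x[grp == "B"])
    base_mean <- mean(x)
    if (ma == 0 && mb == 0)
      return(c(base_mean, 0, NA, NA, NA))
    alpha <- alphas[i]
    lfc <- log2(ma + 0.5) - log2(mb + 0.5)
    # delta method: var of a normalized-count group mean under NB(mu, alpha),
    # mu_s = m * sf_s, var(K_s/sf_s) = m/sf_s + alpha m^2
    var_ma <- sum(ma / sfa + alpha * ma^2) / length(sfa)^2
    var_mb <- sum(mb / sfb + alpha * mb^2) / length(sfb)^2
    ln2 <- log(2)
    se <- sqrt(var_ma / ((ma + 0.5)^2 * ln2^2) +
               var_mb / ((mb + 0.5)^2 * ln2^2))
    stat <- lfc / se
    p <- 2 * stats::pnorm(-abs(stat))
    c(base_mean, lfc, se, stat, p)
  }, numeric(5)))
  out <- data.frame(
    gene_id = rownames(cm$counts),
    base_mean = res[, 1], log2fc = res[, 2], se_log2fc = res[, 3],
    wald_stat = res[, 4], p_value = res[, 5],
    stringsAsFactors = FALSE
  )
  out$fdr <- NA_real_
  keep <- !is.na(out$p_value) & out$base_mean >= min_base_mean
  out$fdr[keep] <- stats::p.adjust(out$p_value[keep], method = "BH")
  out$direction <- ifelse(out$log2fc >= 0, "enriched", "depleted")
  rownames(out) <- NULL
  out
}

# NB log-likelihood of counts k with means q * sf, dispersion alpha,
# maximized over q (profile over a 1-parameter mean on the log scale)
nb_profile_loglik <- function(k, sf, alpha) {
  size <- 1 / alpha
  f <- function(logq) -sum(stats::dnbinom(k, size = size,
                                          mu = exp(logq) * sf, log = TRUE))
  q0 <- max(mean(k / sf), 1e-8)
  opt <- stats::optimize(f, interval = log(q0) + c(-8, 8))
  list(loglik = -opt$objective, q = exp(opt$minimum))
}

#' Negative-binomial likelihood-ratio test across groups
#'
#' Analysis-of-deviance style test that a gene's expression differs anywhere
#' across >= 3 groups: the NB log-likelihood (shared per-gene dispersion,
#' size-factor offsets) is maximized under the full model (one mean per
#' group) and the reduced model (a single mean); `2 * (l_full - l_reduced)`
#' is referred to a chi-squared distribution with `k - 1` degrees of freedom.
#'
#' @inheritParams nb_wald_test
#' @return Data frame: `gene_id`, `stat`, `df`, `p_value`, `fdr`, `converged`.
#' @export
nb_lrt_test <- function(cm, sf = NULL, prior_df = 20,
                        dispersion_floor = 1e-8, dispersion_ceiling = 10) {
  groups <- unique(cm$groups)
  if (length(groups) < 3)
    stop_ripcor("LRT needs >= 3 groups; use nb_wald_test for two")
  if (is.null(sf)) sf <- estimate_size_factors(cm)
  sfv <- unclass(sf)
  norm <- sweep(cm$counts, 2, sfv, "/")
  df_test <- length(groups) - 1

  mom <- apply(norm, 1, mom_dispersion_signed, group = cm$groups)
  df_within <- ncol(norm) - length(groups)
  alphas <- moderate_dispersions(mom, df_within, prior_df,
                                 dispersion_floor, dispersion_ceiling)

  res <- t(vapply(seq_len(nrow(cm$counts)), function(i) {
    k <- cm$counts[i, ]
    if (all(k == 0)) return(c(NA, NA, 0))
    alpha <- alphas[i]
    ok <- TRUE
    ll_full <- tryCatch(
      sum(vapply(groups, function(g) {
        s <- cm$groups == g
        nb_profile_loglik(k[s], sfv[s], alpha)$loglik
      }, 0)),
      error = function(e) { ok <<- FALSE; NA_real_ })
    ll_red <- tryCatch(nb_profile_loglik(k, sfv, alpha)$loglik,
                       error = function(e) { ok <<- FALSE; NA_real_ })
    if (!ok) return(c(NA, NA, 0))
    stat <- max(2 * (ll_full - ll_red), 0)
    c(stat, stats::pchisq(stat, df_test, lower.tail = FALSE), 1)
  }, numeric(3)))

  out <- data.frame(gene_id = rownames(cm$counts),
                    stat = res[, 1], df = df_test, p_value = res[, 2],
                    converged = res[, 3] == 1, stringsAsFactors = FALSE)
  out$fdr <- NA_real_
  keep <- !is.na(out$p_value)
  out$fdr[keep] <- stats::p.adjust(out$p_value[keep], method = "BH")
  out
}

#' qPCR fold-change enrichment (delta-delta-Ct)
#'
#' Standard relative quantification: per condition, `dCt = Ct_target -
#' Ct_reference`; `ddCt = dCt_case - dCt_control`; fold change `2^-ddCt`.
#' The SD is propagated by computing a fold change per case replicate
#' against the mean control `dCt` and taking mean and SD over replicates.
#'
#' @param q Data frame with columns `condition`, `gene`, `replicate`, `ct`.
#' @param target_gene,reference_gene Gene ids in `q$gene`.
#' @param case_condition,control_condition Condition labels in `q$condition`.
#' @return List with `fold` (mean), `sd`, `n`, `per_replicate` folds.
#' @examples
#' q <- data.frame(condition = c("case","case","ctrl","ctrl"),
#'                 gene = c("Vim","Actb","Vim","Actb"),
#'                 replicate = 1, ct = c(20, 20, 24, 20))
#' qpcr_fold_change(q, "Vim", "Actb", "case", "ctrl")$fold  # 16
#' @export
qpcr_fold_change <- function(q, target_gene, reference_gene,
                             case_condition, control_condition) {
  pick <- function(cond, gene) q$ct[q$condition == cond & q$gene == gene]
  tc <- pick(case_condition, target_gene)
  rc <- pick(case_condition, reference_gene)
  tk <- pick(control_condition, target_gene)
  rk <- pick(control_condition, reference_gene)
  if (!length(rc) || !length(rk))
    stop_ripcor("missing reference-gene Ct for condition '%s'",
                if (!length(rc)) case_condition else control_condition)
  if (!length(tc) || !length(tk))
    stop_ripcor("missing target-gene Ct values")
  if (any(!is.finite(c(tc, rc, tk, rk))))
    stop_ripcor("Ct values must be finite")
  dct_control <- mean(tk) - mean(rk)
  # pair case target replicates with matched reference when counts agree
  ref_case <- if (length(rc) == length(tc)) rc else mean(rc)
  ddct <- (tc - ref_case) - dct_control
  folds <- 2^(-ddct)
  list(fold = mean(folds),
       sd = if (length(folds) > 1) stats::sd(folds) else 0,
       n = length(folds), per_replicate = folds)
}
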