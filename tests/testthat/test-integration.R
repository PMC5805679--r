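test_that("RPKM follows the closed form and is depth-invariant", {
  m <- matrix(c(10, 0, 5, 25), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  # force column totals 1e6 and 5e6 via a filler gene
  m <- rbind(m, filler = c(1e6 - 10, 5e6 - 30))
  cm <- quick_cm(m, groups = c(s1 = "A", s2 = "B"),
                 lengths = c(g1 = 1000, g2 = 500, filler = 1000))
  r <- rpkm(cm)
  expect_equal(r["g1", "s1"], 10)           # 10 / (1kb * 1)
  expect_equal(r["g2", "s1"], 0)
  expect_equal(r["g2", "s2"], 25 / (0.5 * 5))

  # doubling all counts in a sample leaves its RPKM unchanged
  cm2 <- quick_cm(m * 2, groups = c(s1 = "A", s2 = "B"),
                  lengths = c(g1 = 1000, g2 = 500, filler = 1000))
  expect_equal(rpkm(cm2), r)

  expect_error(rpkm(quick_cm(m, groups = c(s1 = "A", s2 = "B"))), "lengths")
})

test_that("Z-scores use the sample-SD convention and flag degenerate input", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  z <- zscore(c(4, 4, 4))
  expect_equal(unclass(z), c(0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(z, "flagged"))
  expect_error(zscore(5), ">= 2")

  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(sample(2:30, 1), sd = runif(1, 0.1, 10))
    z <- zscore(v)
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(stats::sd(z) - 1), 1e-12)
  }
})

test_that("per-gene Pearson hits the exact limits and is affine-invariant", {
  rna <- matrix(rnorm(30), 3, 10, dimnames = list(paste0("g", 1:3),
                                                  paste0("s", 1:10)))
  prot <- rna
  prot[2, ] <- -rna[2, ]
  r <- per_gene_correlation(rna, prot)
  expect_equal(r$r[1], 1)
  expect_equal(r$r[2], -1)

  # Pearson on Z-scores equals Pearson on raw values
  raw_prot <- rna * 3.7 + 11
  r_raw <- per_gene_correlation(rna, raw_prot)
  r_z <- per_gene_correlation(zscore_rows(rna), zscore_rows(raw_prot))
  expect_equal(r_raw$r, r_z$r, tolerance = 1e-12)

  # missing cells are dropped pairwise; too few pairs flags the gene
  prot[3, 1:8] <- NA
  r3 <- per_gene_correlation(rna, prot)
  expect_true(r3$flagged[3])
  expect_identical(r3$n_pairs[3], 2L)

  colnames(prot) <- rev(colnames(prot))
  expect_error(per_gene_correlation(rna, prot), "identical sample columns")
})

test_that("planted per-gene correlations are recovered on average", {
  gs <- stats::setNames(rep(3, 7), paste0("cl", 1:7))
  gc <- gen_counts(800, group_sizes = gs, baseline_meanlog = log(300),
                   baseline_sdlog = 1, dispersion = 0.05, enriched_frac = 0,
                   seed = 61)
  gp <- gen_proteome(gc$cm, rho_mean = 0.6, rho_sd = 0, noise_sd = 1,
                     missing_model = c(b0 = -20, b1 = 0), seed = 62)
  pg <- per_gene_correlation(log2(rpkm(gc$cm) + 1),
                             log2(gp$im$intensities))
  expect_lt(abs(mean(pg$r, na.rm = TRUE) - 0.6), 0.05)
})

test_that("per-sample Spearman matches a rank-then-Pearson oracle", {
  set.seed(9)
  n <- 200
  rp <- matrix(rlnorm(n * 2, 3, 1), n, 2,
               dimnames = list(paste0("g", 1:n), c("s1", "s2")))
  ib <- rp^1.7 * 5     # strictly increasing transform -> rho = 1
  r <- per_sample_correlation(rp, ib)
  expect_equal(r$rho, c(1, 1))

  ib2 <- matrix(rlnorm(n * 2, 8, 2), n, 2, dimnames = dimnames(rp))
  r2 <- per_sample_correlation(rp, ib2)
  oracle <- stats::cor(rank(log10(rp[, 1])), rank(log10(ib2[, 1])))
  expect_equal(r2$rho[1], oracle, tolerance = 1e-12)

  # zero-RPKM genes are excluded; too few genes -> NA with warning
  rp_small <- rp[1:8, 1, drop = FALSE]
  expect_warning(r3 <- per_sample_correlation(rp_small, ib2[1:8, 1, drop = FALSE]),
                 "rho = NA")
  expect_true(all(is.na(r3$rho)))
})

test_that("correlation histograms use 0.1 bins with leftmost-maximum mode", {
  d <- correlation_distribution(rep(0.05, 10))
  expect_equal(d$modal_bin, c(0.0, 0.1))
  expect_equal(sum(d$counts), 10)

  # KS of a sample against itself is 0
  set.seed(12)
  r <- runif(100, -1, 1)
  ks <- correlation_distribution(c(r, r), rep(c(TRUE, FALSE), each = 100))$ks
  expect_equal(unname(ks$statistic), 0)

  # ties between bins resolve to the leftmost
  d2 <- correlation_distribution(c(-0.55, 0.25))
  expect_equal(d2$modal_bin, c(-0.6, -0.5))

  expect_error(correlation_distribution(runif(5), c(TRUE, rep(FALSE, 4))),
               ">= 2")
})

test_that("set overlaps reproduce brute-force membership enumeration", {
  o <- overlap_sets(list(x = "A", y = "A"))
  expect_equal(o$pairwise["x", "y"], 1)

  o2 <- overlap_sets(list(x = c("A", "B"), y = c("C", "D"), z = c("E")))
  expect_true(all(o2$pairwise[upper.tri(o2$pairwise)] == 0))

  set.seed(23)
  uni <- sprintf("G%04d", 1:1000)
  sets <- list(a = sample(uni, 100), b = sample(uni, 100),
               c = sample(uni, 100))
  o3 <- overlap_sets(sets)
  expect_equal(sum(o3$partition$count), o3$union_size)
  # brute force: count each membership pattern directly
  ids <- unique(unlist(sets))
  for (i in seq_len(nrow(o3$partition))) {
    inx <- o3$partition$a[i]; iny <- o3$partition$b[i]; inz <- o3$partition$c[i]
    n_direct <- sum(vapply(ids, function(g)
      (g %in% toupper(sets$a)) == inx && (g %in% toupper(sets$b)) == iny &&
        (g %in% toupper(sets$c)) == inz, TRUE))
    expect_identical(o3$partition$count[i], as.integer(n_direct))
  }

  # id normalization: case and whitespace
  o4 <- overlap_sets(list(x = " abc ", y = "ABC"))
  expect_equal(o4$pairwise["x", "y"], 1)
})

test_that("hypergeometric ORA matches exact tail enumeration", {
  uni <- sprintf("g%02d", 1:10)
  res <- hypergeometric_ora(uni[1:4], list(cat1 = uni[1:5]), uni)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)

  # query = universe: overlap = category size, p = 1
  res2 <- hypergeometric_ora(uni, list(cat1 = uni[1:5], cat2 = uni[6:7]), uni)
  expect_equal(res2$overlap, res2$category_size)
  expect_equal(res2$p_value, c(1, 1))

  expect_error(hypergeometric_ora("zz", list(c1 = "zz"), uni), "outside")
  expect_error(hypergeometric_ora(character(), list(), character()), "empty")

  set.seed(41)
  for (i in 1:25) {
    N <- sample(5:25, 1)
    uni <- sprintf("u%02d", seq_len(N))
    cat_set <- sample(uni, sample(1:N, 1))
    query <- sample(uni, sample(1:N, 1))
    res <- hypergeometric_ora(query, list(k = cat_set), uni)
    expect_equal(res$p_value,
                 oracle_hyper_p(res$overlap, res$category_size, N,
                                res$query_size),
                 tolerance = 1e-10)
  }
})
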