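make_im <- function(m, groups, flags = NULL, zero_is_missing = TRUE) {
  if (is.null(rownames(m))) rownames(m) <- paste0("p", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- names(groups)
  intensity_matrix(m, groups, zero_is_missing = zero_is_missing, flags = flags)
}

test_that("detection filter keeps complete-in-one-group proteins and drops flagged rows", {
  groups <- stats::setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  m <- rbind(
    c(5, 6, 7, NA, NA, NA),    # complete in A -> kept
    c(5, NA, 7, 5, NA, 7),     # 2/3 in every group -> dropped
    c(5, 6, 7, 5, 6, 7))       # complete everywhere -> kept (unless flagged)
  colnames(m) <- names(groups)
  im <- make_im(m, groups)
  f <- filter_detection(im)
  expect_identical(rownames(f$intensities), c("p1", "p3"))

  flags <- data.frame(Potential.contaminant = c("", "", "+"))
  imf <- make_im(m, groups, flags = flags)
  expect_identical(rownames(filter_detection(imf)$intensities), "p1")
})

test_that("reference scaling brings every sample to the reference total", {
  groups <- c(s1 = "A", s2 = "A", s3 = "B")
  m <- cbind(s1 = c(60, 40), s2 = c(150, 50), s3 = c(20, 30))
  rownames(m) <- c("p1", "p2")
  im <- make_im(m, groups)
  norm <- normalize_reference_scaling(im, "s1")
  expect_equal(unname(colSums(norm$intensities, na.rm = TRUE)),
               c(100, 100, 100))
  expect_equal(norm$intensities[, "s1"], im$intensities[, "s1"])
  # identical sample: factor 1 (unchanged)
  im2 <- make_im(cbind(s1 = c(60, 40), s2 = c(60, 40), s3 = c(20, 30)), groups)
  expect_equal(normalize_reference_scaling(im2, "s1")$intensities[, "s2"],
               im2$intensities[, "s2"])
})

test_that("downshifted imputation has the configured moments and is reversible", {
  groups <- c(s1 = "A", s2 = "A")
  set.seed(5)
  n_obs <- 20000; n_miss <- 5000
  col <- c(rnorm(n_obs, 25, 1), rep(NA_real_, n_miss))
  m <- cbind(s1 = col, s2 = rnorm(n_obs + n_miss, 25, 1))
  rownames(m) <- paste0("p", seq_len(nrow(m)))
  im <- make_im(m, groups, zero_is_missing = FALSE)
  res <- impute_downshifted(im, seed = 42)

  imp_vals <- res$imputed$intensities[, "s1"][res$record$mask[, "s1"]]
  expect_lt(abs(mean(imp_vals) - (25 - 1.8)), 0.05)
  expect_lt(abs(sd(imp_vals) - 0.3), 0.02)

  # observed cells bit-identical, no missing left
  expect_identical(res$imputed$intensities[!res$record$mask],
                   im$intensities[!res$record$mask])
  expect_false(anyNA(res$imputed$intensities))

  # de-imputation restores the original mask exactly
  back <- de_impute(res$imputed, res$record)
  expect_identical(back$missing_mask, im$missing_mask)
  expect_identical(back$intensities, im$intensities)

  # same seed reproduces identical draws
  res2 <- impute_downshifted(im, seed = 42)
  expect_identical(res$imputed$intensities, res2$imputed$intensities)

  # no missing cells: unchanged with empty record
  im_full <- make_im(cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6)), groups,
                     zero_is_missing = FALSE)
  r0 <- impute_downshifted(im_full, seed = 1)
  expect_identical(r0$imputed$intensities, im_full$intensities)

  # column with < 2 observed values errors
  bad <- make_im(cbind(s1 = c(5, NA, NA), s2 = c(1, 2, 3)), groups,
                 zero_is_missing = FALSE)
  expect_error(impute_downshifted(bad, seed = 1), "SD undefined")
})

test_that("S0-moderated statistics: limits, antisymmetry and s0 monotonicity", {
  groups <- stats::setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  m <- rbind(p1 = c(5, 5, 5, 5, 5, 5),
             p2 = c(6.2, 6.1, 6.3, 5.1, 5.0, 5.2),
             p3 = c(9, 8, 10, 3, 4, 2))
  colnames(m) <- names(groups)
  im <- make_im(m, groups, zero_is_missing = FALSE)

  r <- moderated_test(im, s0 = 0.5, design = "two_group",
                      contrast = c("A", "B"))
  expect_equal(r$stat[1], 0)
  expect_equal(r$p_value[1], 1)

  # limit case: zero pooled variance, mean difference 0.4, s0 = 0.4 -> d = 1
  m2 <- rbind(p1 = c(1.4, 1.4, 1.4, 1.0, 1.0, 1.0))
  colnames(m2) <- names(groups)
  im2 <- make_im(m2, groups, zero_is_missing = FALSE)
  r2 <- moderated_test(im2, s0 = 0.4, design = "two_group",
                       contrast = c("A", "B"))
  expect_equal(r2$stat, 1)
  expect_error(moderated_test(im2, s0 = 0, design = "two_group",
                              contrast = c("A", "B")), "s0")

  r_swap <- moderated_test(im, s0 = 0.5, design = "two_group",
                           contrast = c("B", "A"))
  expect_equal(r$stat, -r_swap$stat)

  # increasing s0 strictly shrinks |d| when the mean difference is nonzero
  d1 <- moderated_test(im, s0 = 0.1, design = "two_group",
                       contrast = c("A", "B"))$stat
  d2 <- moderated_test(im, s0 = 0.8, design = "two_group",
                       contrast = c("A", "B"))$stat
  expect_true(all(abs(d2[2:3]) < abs(d1[2:3])))
})

test_that("moderated ANOVA controls the FDR under a multi-group null", {
  groups <- stats::setNames(rep(paste0("cl", 1:7), each = 3), paste0("s", 1:21))
  set.seed(88)
  m <- matrix(rnorm(2000 * 21, 25, 1), 2000, 21,
              dimnames = list(paste0("p", 1:2000), names(groups)))
  im <- make_im(m, groups, zero_is_missing = FALSE)
  r <- moderated_test(im, s0 = 0.4, design = "anova")
  expect_lte(mean(r$significant), 0.05 * 1.1)

  # a genuinely shifted protein is found
  m[1, 1:3] <- m[1, 1:3] + 12
  im2 <- make_im(m, groups, zero_is_missing = FALSE)
  r2 <- moderated_test(im2, s0 = 0.4, design = "anova")
  expect_true(r2$significant[r2$protein_id == "p1"])

  # permutation mode gives a sane p for the shifted protein
  rp <- moderated_test(im2, s0 = 0.4, design = "anova", mode = "permutation",
                       n_perm = 50, seed = 4)
  expect_lt(rp$p_value[rp$protein_id == "p1"], 0.05)
})

test_that("tryptic digestion applies the no-P rule and tiles the sequence", {
  expect_identical(tryptic_digest("AKCR")$peptides$peptide, c("AK", "CR"))
  expect_identical(tryptic_digest("AKRP")$peptides$peptide, c("AK", "RP"))
  expect_identical(tryptic_digest("MMMM")$peptides$peptide, "MMMM")
  expect_error(tryptic_digest("AKBZ"), "illegal amino acid 'B' at position 3")

  set.seed(19)
  for (i in 1:100) {
    s <- random_protein(sample(5:200, 1))
    pm <- tryptic_digest(s)
    base <- pm$peptides[pm$peptides$n_missed == 0, ]
    # peptides tile: concatenation restores the sequence, bounds abut
    expect_identical(paste(base$peptide, collapse = ""), s)
    expect_identical(base$start[-1], base$end[-nrow(base)])
    # agreement with the regex-based rule oracle
    expect_identical(base$peptide, oracle_digest(s))
  }

  # missed cleavages: k=1 adds concatenations of adjacent pairs
  pm1 <- tryptic_digest("AKCRDK", missed_cleavages = 1)
  expect_setequal(pm1$peptides$peptide,
                  c("AK", "CR", "DK", "AKCR", "CRDK"))
})

test_that("observed-peptide mapping computes coverage and unassigned lists", {
  pm <- tryptic_digest("AKCRDK")
  all_p <- pm$peptides$peptide
  expect_equal(map_observed_peptides(pm, all_p)$coverage, 1)
  expect_equal(map_observed_peptides(pm, character())$n_observed, 0)

  r <- map_observed_peptides(pm, c("CR", "XX"))
  expect_identical(r$n_observed, 1L)
  expect_identical(r$n_predicted, 3L)
  expect_identical(r$unassigned, "XX")
})
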