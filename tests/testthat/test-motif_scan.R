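test_that("constructed exact matches and non-matches behave as expected", {
  t1 <- transcript_record("t1", "GGGGGAAGTAG", 0, 0)
  h1 <- scan_transcript(t1)
  expect_identical(nrow(h1), 1L)
  expect_identical(h1$motif_id, "M1")
  expect_identical(h1$start, 0L)
  expect_identical(h1$matched_seq, "GGGGGAAGTAG")

  expect_identical(nrow(scan_transcript(
    transcript_record("t2", "CCCCCCCCCCCC", 0, 0))), 0L)

  h2 <- scan_transcript(transcript_record("t3", "GAGAGAGAACGA", 0, 0))
  expect_identical(h2$motif_id, "M2")
  expect_identical(h2$start, 0L)

  # oracle-derived: GGGGGGAAGTAG has exactly one M1 hit, at start 1
  t4 <- transcript_record("t4", "GGGGGGAAGTAG", 0, 0)
  o <- oracle_scan(t4$sequence)
  expect_identical(o$start, 1L)
  expect_identical(scan_transcript(t4)$start, o$start)

  # overlapping hits across motifs are all reported
  t5 <- transcript_record("t5", "GGAGAGAAGTAAGAACAA", 0, 0)
  h5 <- scan_transcript(t5)
  o5 <- oracle_scan(t5$sequence)
  expect_identical(h5$start, o5$start)
  expect_identical(h5$motif_id, o5$motif_id)

  # N can never be inside a match
  expect_identical(nrow(scan_transcript(
    transcript_record("t6", "GGGGNAAGTAG", 0, 0))), 0L)
})

test_that("regex scan equals the sliding-window oracle on random sequences", {
  set.seed(101)
  for (i in 1:300) {
    L <- sample(12:500, 1)
    alphabet <- if (i %% 5 == 0) c("A", "G") else c("A", "C", "G", "T", "N")
    s <- random_dna(L, alphabet)
    t <- transcript_record("r", s, 0, 0)
    hits <- scan_transcript(t)
    o <- oracle_scan(s)
    expect_identical(hits$start, o$start)
    expect_identical(hits$motif_id, o$motif_id)
    # matched_seq really is sequence[start:end)
    if (nrow(hits))
      expect_identical(hits$matched_seq,
                       substring(s, hits$start + 1, hits$end))
  }
})

test_that("hits are attributed to the region containing their start", {
  # M1 hit starting in CDS but spanning into the 3'UTR
  s <- paste0("CCCCC", "GGGGGAAGTAG", "CCCC")
  t <- transcript_record("t", s, 2, 10)   # hit start 5 is inside CDS [2,10)
  h <- scan_transcript(t)
  expect_identical(h$region, "CDS")
  expect_true(h$end > 10)  # spans the boundary
})

test_that("cohort summaries count transcripts once per region and handle pseudogenes", {
  t1 <- transcript_record("a", "CCGGGGGAAGTAGGGGGAAGTAGGGGGAAGTAGCC", 1, 34)
  t2 <- transcript_record("b", "CCCCCCCCCCCC", 1, 11)
  hits <- scan_cohort(list(t1, t2))
  s <- summarize_cohort(hits, list(t1, t2))
  expect_identical(s$n_transcripts, 2L)
  expect_identical(unname(s$region_counts["CDS"]), 1L)
  expect_equal(unname(s$region_percent["CDS"]), 50)
  expect_true(s$total_hits >= 3)

  # empty cohort: zero counts, percentages defined as 0
  s0 <- summarize_cohort(scan_cohort(list()), list())
  expect_identical(s0$n_transcripts, 0L)
  expect_equal(s0$percent_any, 0)

  # pseudogene exclusion
  t3 <- transcript_record("c", t1$sequence, 1, 34, is_pseudogene = TRUE)
  hits3 <- scan_cohort(list(t1, t3))
  s3 <- summarize_cohort(hits3, list(t1, t3))
  expect_identical(s3$n_transcripts, 1L)
  s3b <- summarize_cohort(hits3, list(t1, t3), exclude_pseudogenes = FALSE)
  expect_identical(s3b$n_transcripts, 2L)

  expect_error(summarize_cohort(hits, list(t2)), "not in the cohort")
})

test_that("background sampling is seed-reproducible, exclusive and uniform", {
  tx <- gen_transcripts(40, seed = 9)$transcripts
  ids <- vapply(tx, `[[`, "", "transcript_id")
  b1 <- sample_background(tx, 5, seed = 11, exclude = ids[1:10])
  b2 <- sample_background(tx, 5, seed = 11, exclude = ids[1:10])
  got <- vapply(b1, `[[`, "", "transcript_id")
  expect_identical(got, vapply(b2, `[[`, "", "transcript_id"))
  expect_length(unique(got), 5)
  expect_length(intersect(got, ids[1:10]), 0)
  expect_error(sample_background(tx, 40, seed = 1, exclude = ids[1:10]),
               "cannot draw")

  # inclusion frequency ~ n/|pool| over many seeds
  pool <- ids[11:40]
  freq <- stats::setNames(numeric(length(pool)), pool)
  n_draws <- 400
  for (s in seq_len(n_draws)) {
    g <- vapply(sample_background(tx, 6, seed = s, exclude = ids[1:10]),
                `[[`, "", "transcript_id")
    freq[g] <- freq[g] + 1
  }
  p <- 6 / 30
  se <- sqrt(p * (1 - p) / n_draws)
  expect_true(all(abs(freq / n_draws - p) < 4 * se))
})

test_that("cohort comparison matches exact-enumeration Fisher oracles", {
  # equal proportions: OR exactly 1
  t1 <- transcript_record("a", "GGGGGAAGTAG", 0, 11)
  t2 <- transcript_record("b", "CCCCCCCCCCC", 0, 11)
  s <- summarize_cohort(scan_cohort(list(t1, t2)), list(t1, t2))
  res <- compare_cohorts(s, s)
  expect_equal(res$odds_ratio[res$region == "any"], 1)
  expect_equal(res$p_value[res$region == "any"], 1)

  # extreme 10/10 vs 0/10 table: p from enumerating C(20,10) tables
  mk <- function(with, total) {
    tpl <- transcript_record("x", "GGGGGAAGTAG", 0, 11)
    neg <- transcript_record("y", "CCCCCCCCCCC", 0, 11)
    lapply(seq_len(total), function(i) {
      t <- if (i <= with) tpl else neg
      t$transcript_id <- paste0("tx", i)
      t
    })
  }
  ct <- mk(10, 10); cb <- mk(0, 10)
  st <- summarize_cohort(scan_cohort(ct), ct)
  sb <- summarize_cohort(scan_cohort(cb), cb)
  res2 <- compare_cohorts(st, sb)
  any_row <- res2[res2$region == "any", ]
  expect_equal(any_row$p_value, oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-12)
  expect_equal(any_row$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(any_row$or_corrected)
  expect_true(is.finite(any_row$odds_ratio))  # Haldane-Anscombe corrected

  # random small tables against the enumeration oracle
  set.seed(7)
  for (i in 1:20) {
    a <- sample(0:8, 1); b <- sample(1:8, 1)
    c <- sample(0:8, 1); d <- sample(1:8, 1)
    p_pkg <- stats::fisher.test(matrix(c(a, b, c, d), 2))$p.value
    expect_equal(p_pkg, oracle_fisher_p(a, b, c, d), tolerance = 1e-9)
  }
})

test_that("planted motifs are always recovered and CDS rate is respected", {
  g <- gen_transcripts(300, motif_rates = c(UTR5 = 0, CDS = 0.3, UTR3 = 0),
                       seed = 77)
  hits <- scan_cohort(g$transcripts)
  pl <- g$truth$planted
  # every planted (transcript, start) pair appears among the scan hits
  key_hits <- paste(hits$transcript_id, hits$start)
  key_pl <- paste(pl$transcript_id, pl$start)
  expect_true(all(key_pl %in% key_hits))

  s <- summarize_cohort(hits, g$transcripts)
  p_hat <- s$region_counts[["CDS"]] / s$n_transcripts
  se <- sqrt(0.3 * 0.7 / 300)
  expect_gte(p_hat, 0.3 - 3 * se)  # spontaneous matches can only add
})
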