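# Independent oracles used across tests. These deliberately avoid the code
# paths they check: position-by-position pattern tests instead of regex
# scanning, exhaustive enumeration instead of phyper, the step-min definition
# of BH instead of p.adjust.

# Sliding-window motif oracle: test every start against the pattern by
# explicit per-position character-class membership.
oracle_scan <- function(sequence, motifs = motif_set()) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  classes <- list(
    M1 = c(rep(list(c("A", "G")), 5), as.list(strsplit("AAGTA", "")[[1]]),
           list(c("A", "G"))),
    M2 = c(rep(list(c("A", "G")), 7), as.list(strsplit("AAC", "")[[1]]),
           rep(list(c("A", "G")), 2)),
    iCLIP6 = list(c("C", "G", "T"), "A", "A", "G", c("A", "T", "G"), "A")
  )
  hits <- list()
  for (m in motifs$motif_id) {
    cls <- classes[[m]]
    w <- length(cls)
    if (length(chars) < w) next
    for (s in 0:(length(chars) - w)) {
      ok <- TRUE
      for (k in seq_len(w)) {
        if (!chars[s + k] %in% cls[[k]]) { ok <- FALSE; break }
      }
      if (ok) hits[[length(hits) + 1]] <- data.frame(motif_id = m, start = s)
    }
  }
  if (!length(hits)) return(data.frame(motif_id = character(), start = integer()))
  out <- do.call(rbind, hits)
  out[order(out$start, out$motif_id), , drop = FALSE]
}

# Benjamini-Hochberg by its definition: adj_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric p by exact enumeration of the tail terms.
oracle_hyper_p <- function(overlap, category_size, universe_size, query_size) {
  jmax <- min(category_size, query_size)
  if (overlap > jmax) return(0)
  sum(vapply(overlap:jmax, function(j)
    choose(category_size, j) * choose(universe_size - category_size,
                                      query_size - j), 0)) /
    choose(universe_size, query_size)
}

# Two-sided Fisher p for a 2x2 table by enumerating all tables with the same
# margins and summing probabilities <= the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  probs <- vapply(max(0, c1 - (n - r1)):min(r1, c1), function(x)
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1), 0)
  obs <- choose(r1, a) * choose(n - r1, c1 - a) / choose(n, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Tryptic digest oracle: regex-based cut-point insertion, independent of the
# index arithmetic in tryptic_digest().
oracle_digest <- function(seq) {
  strsplit(gsub("(?<=[KR])(?!P)", "\r", seq, perl = TRUE), "\r")[[1]]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# small CountMatrix from a plain matrix with a 2-group layout
quick_cm <- function(m, groups = NULL, lengths = NULL) {
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(groups)) {
    h <- ncol(m) %/% 2
    groups <- stats::setNames(rep(c("A", "B"), c(h, ncol(m) - h)), colnames(m))
  }
  count_matrix(m, groups, lengths = lengths)
}
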