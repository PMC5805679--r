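#' Construct a transcript record
#'
#' A `TranscriptRecord` is a self-contained mRNA: the sense-strand sequence
#' plus the coding-region coordinates that partition it into 5'UTR, CDS and
#' 3'UTR. Coordinates are 0-based, half-open: the 5'UTR is `[0, cds_start)`,
#' the CDS `[cds_start, cds_end)` and the 3'UTR `[cds_end, length)`.
#'
#' @param transcript_id Accession string, e.g. `"NM_144901"`.
#' @param sequence DNA string over `A`,`C`,`G`,`T`,`N` (case-insensitive;
#'   stored upper-case).
#' @param cds_start,cds_end 0-based half-open CDS bounds. Non-coding records
#'   use `cds_start = cds_end = 0`, which places the whole sequence in the
#'   3'UTR partition and sets `non_coding = TRUE`.
#' @param gene_symbol Gene symbol (defaults to the transcript id).
#' @param is_pseudogene Flag used by cohort summaries to avoid double counting
#'   pseudogene copies.
#' @return An object of class `TranscriptRecord`.
#' @examples
#' t <- transcript_record("tx1", "AAAATGGCCTAAGGG", cds_start = 3, cds_end = 12)
#' transcript_regions(t)
#' @export
transcript_record <- function(transcript_id, sequence, cds_start, cds_end,
                              gene_symbol = transcript_id,
                              is_pseudogene = FALSE) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop_ripcor("transcript '%s': sequence contains characters outside {A,C,G,T,N}",
                transcript_id)
  n <- nchar(sequence)
  if (!(cds_start >= 0 && cds_start <= cds_end && cds_end <= n))
    stop_ripcor("transcript '%s': CDS [%d,%d) outside sequence bounds [0,%d)",
                transcript_id, cds_start, cds_end, n)
  structure(list(
    transcript_id = transcript_id,
    gene_symbol   = gene_symbol,
    sequence      = sequence,
    cds_start     = as.integer(cds_start),
    cds_end       = as.integer(cds_end),
    is_pseudogene = isTRUE(is_pseudogene),
    non_coding    = cds_start == 0L && cds_end == 0L
  ), class = "TranscriptRecord")
}

#' Region lengths of a transcript
#'
#' @param t A `TranscriptRecord`.
#' @return Named integer vector with components `UTR5`, `CDS`, `UTR3`; the
#'   three always sum to the sequence length.
#' @export
transcript_regions <- function(t) {
  n <- nchar(t$sequence)
  c(UTR5 = t$cds_start, CDS = t$cds_end - t$cds_start, UTR3 = n - t$cds_end)
}

# Region label of a 0-based position.
region_of_position <- function(t, pos) {
  ifelse(pos < t$cds_start, "UTR5", ifelse(pos < t$cds_end, "CDS", "UTR3"))
}

#' @export
print.TranscriptRecord <- function(x, ...) {
  r <- transcript_regions(x)
  cat(sprintf("TranscriptRecord %s (%s)%s: %d nt [5'UTR %d | CDS %d | 3'UTR %d]\n",
              x$transcript_id, x$gene_symbol,
              if (x$is_pseudogene) " [pseudogene]" else "",
              nchar(x$sequence), r["UTR5"], r["CDS"], r["UTR3"]))
  invisible(x)
}

reverse_complement <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Parse a GenBank location string for a CDS. Returns c(start, end) 1-based
# inclusive on the stored strand, plus whether it was a complement feature.
parse_gb_location <- function(loc, record_id) {
  complemented <- grepl("complement", loc)
  nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (length(nums) < 2)
    stop_ripcor("GenBank record '%s': cannot parse CDS location '%s'",
                record_id, loc)
  list(start = min(nums), end = max(nums), complement = complemented)
}

#' Read transcripts from a GenBank flat file
#'
#' Parses LOCUS, ACCESSION, gene and CDS features and the ORIGIN sequence of
#' each record. GenBank's 1-based inclusive CDS coordinates are converted to
#' the internal 0-based half-open convention exactly once, here. CDS features
#' on the complement strand are resolved by reverse-complementing the
#' sequence, so downstream code only ever sees the sense strand. Records
#' without a CDS feature are returned with `cds_start = cds_end = 0` and
#' flagged `non_coding`.
#'
#' @param path Path to a GenBank flat file (one or more records, each
#'   terminated by `//`).
#' @return List of [transcript_record()] objects, in file order.
#' @examples
#' gb <- system.file("extdata", "synthetic_transcripts.gb", package = "ripcor")
#' read_genbank(gb)
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_idx <- grep("^LOCUS", lines)
  if (length(locus_idx) == 0)
    stop_ripcor("'%s' is not a GenBank flat file: no LOCUS line found", path)
  end_idx <- grep("^//\\s*$", lines)
  if (length(end_idx) < length(locus_idx))
    stop_ripcor("'%s': record starting at line %d has no terminating '//'",
                path, locus_idx[length(end_idx) + 1])
  records <- vector("list", length(locus_idx))
  for (i in seq_along(locus_idx)) {
    block <- lines[locus_idx[i]:end_idx[i]]
    records[[i]] <- parse_gb_record(block, path)
  }
  records
}

parse_gb_record <- function(block, path) {
  locus_name <- strsplit(trimws(sub("^LOCUS", "", block[1])), "\\s+")[[1]][1]
  id <- locus_name
  acc <- grep("^ACCESSION", block, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
    if (!is.na(a) && nzchar(a)) id <- a
  }

  origin_at <- grep("^ORIGIN", block)
  if (length(origin_at) != 1)
    stop_ripcor("GenBank record '%s' in '%s': missing ORIGIN sequence block", id, path)
  seq_lines <- block[(origin_at + 1):(length(block) - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  sequence <- gsub("U", "T", sequence)
  if (!nzchar(sequence))
    stop_ripcor("GenBank record '%s' in '%s': empty ORIGIN sequence", id, path)

  feat_at <- grep("^FEATURES", block)
  cds_loc <- NULL; gene_symbol <- id; pseudo <- FALSE
  if (length(feat_at) == 1) {
    feats <- block[(feat_at + 1):(origin_at - 1)]
    # feature keys start at column 6; qualifiers are indented further
    key_rows <- grep("^ {5}\\S", feats)
    for (k in seq_along(key_rows)) {
      row <- feats[key_rows[k]]
      key <- strsplit(trimws(row), "\\s+")[[1]][1]
      to <- if (k < length(key_rows)) key_rows[k + 1] - 1 else length(feats)
      body <- feats[key_rows[k]:to]
      if (key == "CDS" && is.null(cds_loc)) {
        loc <- trimws(sub("^\\s*CDS", "", body[1]))
        # location may wrap onto continuation lines before the first qualifier
        j <- 2
        while (j <= length(body) && !grepl("^\\s*/", body[j])) {
          loc <- paste0(loc, trimws(body[j])); j <- j + 1
        }
        cds_loc <- loc
        if (any(grepl("/pseudo\\b", body))) pseudo <- TRUE
      }
      if (key == "gene" || key == "CDS") {
        g <- regmatches(body, regexpr('/gene="[^"]*"', body))
        g <- g[lengths(regmatches(body, regexpr('/gene="[^"]*"', body))) > 0]
        if (length(g) && gene_symbol == id)
          gene_symbol <- sub('/gene="([^"]*)"', "\\1", g[1])
        if (any(grepl("/pseudo\\b", body))) pseudo <- TRUE
      }
    }
  }

  if (is.null(cds_loc)) {
    return(transcript_record(id, sequence, 0, 0, gene_symbol = gene_symbol,
                             is_pseudogene = pseudo))
  }
  loc <- parse_gb_location(cds_loc, id)
  n <- nchar(sequence)
  if (loc$end > n)
    stop_ripcor("GenBank record '%s': CDS end %d exceeds sequence length %d",
                id, loc$end, n)
  if (loc$complement) {
    sequence <- reverse_complement(sequence)
    new_start <- n - loc$end + 1
    new_end <- n - loc$start + 1
    loc$start <- new_start; loc$end <- new_end
  }
  # 1-based inclusive -> 0-based half-open
  transcript_record(id, sequence, loc$start - 1, loc$end,
                    gene_symbol = gene_symbol, is_pseudogene = pseudo)
}

#' Read transcripts from FASTA plus a region table
#'
#' Alternative input path to [read_genbank()]: sequences from a FASTA file
#' and CDS bounds from a tab-delimited table with columns
#' `transcript_id`, `cds_start`, `cds_end`, `gene_symbol` (0-based half-open,
#' i.e. already in the internal convention).
#'
#' @param fasta_path FASTA file of transcript sequences.
#' @param region_path Tab-delimited region table.
#' @return List of [transcript_record()] objects in FASTA order.
#' @export
read_fasta_regions <- function(fasta_path, region_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  reg <- utils::read.delim(region_path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "cds_start", "cds_end", "gene_symbol")
  if (!all(need %in% names(reg)))
    stop_ripcor("region table must have columns: %s", paste(need, collapse = ", "))
  missing <- setdiff(ids, reg$transcript_id)
  if (length(missing))
    stop_ripcor("no region entry for transcript(s): %s",
                paste(utils::head(missing, 5), collapse = ", "))
  lapply(seq_along(seqs), function(i) {
    r <- reg[match(ids[i], reg$transcript_id), ]
    transcript_record(ids[i], as.character(seqs[[i]]), r$cds_start, r$cds_end,
                      gene_symbol = r$gene_symbol)
  })
}

#' Write transcripts to FASTA plus region table
#'
#' Inverse of [read_fasta_regions()].
#' @param transcripts List of `TranscriptRecord`.
#' @param fasta_path,region_path Output paths.
#' @export
write_fasta_regions <- function(transcripts, fasta_path, region_path) {
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, "", "sequence"))
  names(seqs) <- vapply(transcripts, `[[`, "", "transcript_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  reg <- data.frame(
    transcript_id = names(seqs),
    cds_start = vapply(transcripts, `[[`, 0L, "cds_start"),
    cds_end   = vapply(transcripts, `[[`, 0L, "cds_end"),
    gene_symbol = vapply(transcripts, `[[`, "", "gene_symbol")
  )
  utils::write.table(reg, region_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Construct a count matrix
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param groups Named character vector mapping every sample (column) to a
#'   group label.
#' @param lengths Optional named numeric vector of transcript lengths in nt
#'   (needed for [rpkm()]).
#' @return Object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, groups, lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_ripcor("counts must have gene rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_ripcor("counts must be non-negative integers")
  if (anyNA(counts)) stop_ripcor("counts must have no missing cells")
  if (!all(colnames(counts) %in% names(groups)))
    stop_ripcor("every sample needs a group label; missing: %s",
                paste(setdiff(colnames(counts), names(groups)), collapse = ", "))
  groups <- groups[colnames(counts)]
  if (!is.null(lengths)) {
    if (!all(rownames(counts) %in% names(lengths)))
      stop_ripcor("lengths missing for some genes")
    lengths <- lengths[rownames(counts)]
  }
  storage.mode(counts) <- "double"
  structure(list(counts = counts, groups = groups, lengths = lengths),
            class = "CountMatrix")
}

#' Construct an intensity matrix
#'
#' Protein intensities with an explicit missingness mask. `NA` cells, and by
#' default zero cells (the MaxQuant convention for "not quantified"), are
#' treated as missing.
#'
#' @param intensities Numeric matrix, proteins x samples, with dimnames.
#' @param groups Named character vector mapping samples to group labels.
#' @param zero_is_missing Treat exact zeros as missing (default `TRUE`).
#' @param flags Optional data.frame of marker columns (`Reverse`,
#'   `Potential.contaminant`, `Only.identified.by.site`; `"+"` marks a hit)
#'   indexed like the rows of `intensities`.
#' @return Object of class `IntensityMatrix` with fields `intensities`
#'   (missing cells `NA`), `missing_mask`, `groups`, `flags`.
#' @export
intensity_matrix <- function(intensities, groups, zero_is_missing = TRUE,
                             flags = NULL) {
  m <- as.matrix(intensities)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_ripcor("intensities must have protein rownames and sample colnames")
  if (any(m < 0, na.rm = TRUE)) stop_ripcor("intensities must be non-negative")
  mask <- is.na(m)
  if (zero_is_missing) mask <- mask | (!is.na(m) & m == 0)
  m[mask] <- NA_real_
  if (!all(colnames(m) %in% names(groups)))
    stop_ripcor("every sample needs a group label")
  structure(list(intensities = m, missing_mask = mask,
                 groups = groups[colnames(m)], flags = flags),
            class = "IntensityMatrix")
}

#' Read a feature-by-sample TSV matrix
#'
#' Header row holds sample ids, first column the feature ids. `kind =
#' "counts"` parses strict non-negative integers into a [count_matrix()];
#' `kind = "intensities"` maps empty cells, `NA`, `NaN` and (by default)
#' literal `0` to missing and builds an [intensity_matrix()].
#'
#' @param path TSV path (tab-delimited, UTF-8, `.` decimal separator).
#' @param kind `"counts"` or `"intensities"`.
#' @param groups Named group labels for the samples; by default every sample
#'   is labelled `"all"` and must be relabelled before testing.
#' @param zero_is_missing For intensities: treat 0 as missing (default TRUE).
#' @param lengths Optional gene lengths passed through to [count_matrix()].
#' @return A `CountMatrix` or `IntensityMatrix`.
#' @export
read_matrix <- function(path, kind = c("counts", "intensities"), groups = NULL,
                        zero_is_missing = TRUE, lengths = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop_ripcor("'%s' is empty", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expect <- length(cells[[1]])
  ragged <- which(lengths(cells) != ncol_expect)
  if (length(ragged))
    stop_ripcor("'%s': ragged row at line %d (%d fields, expected %d)",
                path, ragged[1], lengths(cells)[ragged[1]], ncol_expect)
  samples <- cells[[1]][-1]
  ids <- vapply(cells[-1], `[[`, "", 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_ripcor("'%s': duplicate feature ids: %s", path,
                paste(utils::head(dup, 10), collapse = ", "))
  body <- t(vapply(cells[-1], function(r) r[-1], character(length(samples))))
  if (length(samples) == 1) body <- matrix(body, ncol = 1)
  dimnames(body) <- list(ids, samples)

  if (is.null(groups)) groups <- stats::setNames(rep("all", length(samples)), samples)

  if (kind == "counts") {
    bad <- which(!grepl("^[0-9]+$", body))
    if (length(bad)) {
      i <- (bad[1] - 1) %% nrow(body) + 1
      j <- (bad[1] - 1) %/% nrow(body) + 1
      stop_ripcor("'%s': non-integer count '%s' at line %d, column %d",
                  path, body[bad[1]], i + 1, j + 1)
    }
    m <- matrix(as.numeric(body), nrow = nrow(body), dimnames = dimnames(body))
    count_matrix(m, groups, lengths = lengths)
  } else {
    miss <- body == "" | toupper(body) %in% c("NA", "NAN")
    vals <- suppressWarnings(as.numeric(body))
    vals[miss] <- NA_real_
    bad <- which(is.na(vals) & !miss)
    if (length(bad)) {
      i <- (bad[1] - 1) %% nrow(body) + 1
      j <- (bad[1] - 1) %/% nrow(body) + 1
      stop_ripcor("'%s': unparseable intensity '%s' at line %d, column %d",
                  path, body[bad[1]], i + 1, j + 1)
    }
    m <- matrix(vals, nrow = nrow(body), dimnames = dimnames(body))
    intensity_matrix(m, groups, zero_is_missing = zero_is_missing)
  }
}

#' Write a matrix object back to canonical TSV
#'
#' Canonical dialect: tab-delimited, header row of sample ids, first column
#' `id`, missing intensity cells written as `NA`. Round-trips with
#' [read_matrix()].
#'
#' @param x `CountMatrix` or `IntensityMatrix`.
#' @param path Output path.
#' @export
write_matrix <- function(x, path) {
  m <- if (inherits(x, "CountMatrix")) x$counts else x$intensities
  fmt <- if (inherits(x, "CountMatrix"))
    function(v) format(v, scientific = FALSE, trim = TRUE)
  else function(v) ifelse(is.na(v), "NA", format(v, trim = TRUE))
  header <- paste(c("id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"), "")
  writeLines(c(header, rows), path)
  invisible(path)
}
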