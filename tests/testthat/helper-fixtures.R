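# GenBank flat-file fixture built in code: three records exercising a plain
# CDS, a non-coding record, and a complement CDS with a gene qualifier.
write_genbank_fixture <- function(path) {
  gb_seq_block <- function(s) {
    # 60 nt per ORIGIN line, 1-based offset label, groups of 10
    out <- character()
    for (i in seq(1, nchar(s), by = 60)) {
      chunk <- substring(s, i, min(i + 59, nchar(s)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", i, paste(tolower(tens), collapse = " ")))
    }
    out
  }
  seq1 <- "ACGTATGGCCTGAACGTACG"              # 20 nt, CDS 5..13
  seq2 <- "GGGGCCCCAAAATTTT"                  # no CDS
  seq3 <- "TTACTTGGCCATACGT"                  # complement(5..13)
  lines <- c(
    "LOCUS       TX_ONE                20 bp    mRNA    linear   ROD 01-JAN-2020",
    "DEFINITION  synthetic record one.",
    "ACCESSION   TX_ONE",
    "FEATURES             Location/Qualifiers",
    "     source          1..20",
    "     gene            1..20",
    '                     /gene="GeneOne"',
    "     CDS             5..13",
    '                     /gene="GeneOne"',
    "ORIGIN",
    gb_seq_block(seq1),
    "//",
    "LOCUS       TX_TWO                16 bp    mRNA    linear   ROD 01-JAN-2020",
    "DEFINITION  synthetic non-coding record.",
    "ACCESSION   TX_TWO",
    "FEATURES             Location/Qualifiers",
    "     source          1..16",
    "ORIGIN",
    gb_seq_block(seq2),
    "//",
    "LOCUS       TX_THREE              16 bp    mRNA    linear   ROD 01-JAN-2020",
    "DEFINITION  synthetic complement-CDS record.",
    "ACCESSION   TX_THREE",
    "FEATURES             Location/Qualifiers",
    "     source          1..16",
    "     CDS             complement(5..13)",
    '                     /gene="GeneThree"',
    "ORIGIN",
    gb_seq_block(seq3),
    "//")
  writeLines(unlist(lines), path)
  list(seq1 = seq1, seq2 = seq2, seq3 = seq3)
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
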