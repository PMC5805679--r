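LOCUS       TX_ONE                20 bp    mRNA    linear   ROD 01-JAN-2020
DEFINITION  synthetic record one.
ACCESSION   TX_ONE
FEATURES             Location/Qualifiers
     source          1..20
     gene            1..20
                     /gene="GeneOne"
     CDS             5..13
                     /gene="GeneOne"
ORIGIN
        1 acgtatggcc tgaacgtacg
//
LOCUS       TX_TWO                16 bp    mRNA    linear   ROD 01-JAN-2020
DEFINITION  synthetic non-coding record.
ACCESSION   TX_TWO
FEATURES             Location/Qualifiers
     source          1..16
ORIGIN
        1 ggggccccaa aatttt
//
LOCUS       TX_THREE              16 bp    mRNA    linear   ROD 01-JAN-2020
DEFINITION  synthetic complement-CDS record.
ACCESSION   TX_THREE
FEATURES             Location/Qualifiers
     source          1..16
     CDS             complement(5..13)
                     /gene="GeneThree"
ORIGIN
        1 ttacttggcc atacgt
//
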