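LOCUS       synctg                    60 bp    DNA     linear   BCT 01-JAN-2026
DEFINITION  Synthetic three-gene mini contig (hand-written test fixture).
ACCESSION   SYNCTG001
FEATURES             Location/Qualifiers
     source          1..60
     CDS             4..9
                     /locus_tag="gA"
                     /product="demo protein A"
     CDS             complement(13..21)
                     /locus_tag="gB"
                     /product="demo protein B"
     CDS             join(25..30,34..36)
                     /locus_tag="gC"
                     /product="demo spliced protein C"
ORIGIN
        1 cccatgtaac cctcacgcca tgggatgaaa ttttagacgt acgtacgtac gtacgtacgt
//
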