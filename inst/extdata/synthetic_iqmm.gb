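LOCUS       Synthetica_duplicata            17162 bp    DNA     circular VRT 01-JAN-2020
DEFINITION  Synthetica duplicata mitochondrion, complete genome (synthetic fixture).
SOURCE      mitochondrion
  ORGANISM  Synthetica duplicata
            Chordata; Amphibia; Anura; Dicroglossidae.
FEATURES             Location/Qualifiers
     source          1..99999
     tRNA            1..70
                     /product="tRNA-Phe"
     tRNA            71..1020
                     /product="12S ribosomal RNA"
     tRNA            1021..1090
                     /product="tRNA-Val"
     tRNA            1091..2690
                     /product="16S ribosomal RNA"
     tRNA            2691..2760
                     /product="tRNA-Leu(UUR)"
     CDS             2761..3660
                     /gene="ND1"
     tRNA            3661..3730
                     /product="tRNA-Ile"
     tRNA            3731..3800
                     /product="tRNA-Gln"
     tRNA            3801..3870
                     /product="tRNA-Met"
     tRNA            3871..3940
                     /product="tRNA-Met"
     CDS             3941..4840
                     /gene="ND2"
     tRNA            4841..4910
                     /product="tRNA-Trp"
     tRNA            4911..4980
                     /product="tRNA-Ala"
     tRNA            4981..5050
                     /product="tRNA-Asn"
     rep_origin      5051..5081
                     /note="origin of L-strand replication"
     tRNA            5082..5151
                     /product="tRNA-Cys"
     tRNA            5152..5221
                     /product="tRNA-Tyr"
     tRNA            5222..5291
                     /product="tRNA-Trp"
                     /pseudo
     CDS             5292..6191
                     /gene="COX1"
     tRNA            6192..6261
                     /product="tRNA-Ser(UCN)"
     tRNA            6262..6331
                     /product="tRNA-Asp"
     CDS             6332..7231
                     /gene="COX2"
     tRNA            7232..7301
                     /product="tRNA-Lys"
     CDS             7302..8201
                     /gene="ATP8"
     CDS             8202..9101
                     /gene="ATP6"
     CDS             9102..10001
                     /gene="COX3"
     tRNA            10002..10071
                     /product="tRNA-Gly"
     CDS             10072..10971
                     /gene="ND3"
     tRNA            10972..11041
                     /product="tRNA-Arg"
     CDS             11042..11941
                     /gene="ND4L"
     CDS             11942..12841
                     /gene="ND4"
     tRNA            12842..12911
                     /product="tRNA-His"
     tRNA            12912..12981
                     /product="tRNA-Ser(AGY)"
     tRNA            12982..13051
                     /product="tRNA-Leu(CUN)"
     CDS             13052..13951
                     /gene="ND5"
     CDS             complement(13952..14851)
                     /gene="ND6"
     tRNA            14852..14921
                     /product="tRNA-Glu"
     CDS             14922..15821
                     /gene="CYTB"
     tRNA            15822..15891
                     /product="tRNA-Thr"
     tRNA            15892..15961
                     /product="tRNA-Pro"
     D-loop          15962..17061
                     /note="control region"
ORIGIN
//
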