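LOCUS       Synthetica_typica            17022 bp    DNA     circular VRT 01-JAN-2020
DEFINITION  Synthetica typica mitochondrion, complete genome (synthetic fixture).
SOURCE      mitochondrion
  ORGANISM  Synthetica typica
            Chordata; Amphibia; Anura; Ranidae.
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
     CDS             3871..4770
                     /gene="ND2"
     tRNA            4771..4840
                     /product="tRNA-Trp"
     tRNA            4841..4910
                     /product="tRNA-Ala"
     tRNA            4911..4980
                     /product="tRNA-Asn"
     rep_origin      4981..5011
                     /note="origin of L-strand replication"
     tRNA            5012..5081
                     /product="tRNA-Cys"
     tRNA            5082..5151
                     /product="tRNA-Tyr"
     CDS             5152..6051
                     /gene="COX1"
     tRNA            6052..6121
                     /product="tRNA-Ser(UCN)"
     tRNA            6122..6191
                     /product="tRNA-Asp"
     CDS             6192..7091
                     /gene="COX2"
     tRNA            7092..7161
                     /product="tRNA-Lys"
     CDS             7162..8061
                     /gene="ATP8"
     CDS             8062..8961
                     /gene="ATP6"
     CDS             8962..9861
                     /gene="COX3"
     tRNA            9862..9931
                     /product="tRNA-Gly"
     CDS             9932..10831
                     /gene="ND3"
     tRNA            10832..10901
                     /product="tRNA-Arg"
     CDS             10902..11801
                     /gene="ND4L"
     CDS             11802..12701
                     /gene="ND4"
     tRNA            12702..12771
                     /product="tRNA-His"
     tRNA            12772..12841
                     /product="tRNA-Ser(AGY)"
     tRNA            12842..12911
                     /product="tRNA-Leu(CUN)"
     CDS             12912..13811
                     /gene="ND5"
     CDS             complement(13812..14711)
                     /gene="ND6"
     tRNA            14712..14781
                     /product="tRNA-Glu"
     CDS             14782..15681
                     /gene="CYTB"
     tRNA            15682..15751
                     /product="tRNA-Thr"
     tRNA            15752..15821
                     /product="tRNA-Pro"
     D-loop          15822..16921
                     /note="control region"
ORIGIN
//
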