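# SYNTHETIC STAND-IN module flat file.
# Curated offline approximations of KEGG module DEFINITION strings for the
# energy-metabolism pathways screened by the pipeline (nitrogen, methane,
# sulfur metabolism and photosynthesis). Module accessions reuse real KEGG
# ids for readability, but the definitions are approximations written from
# the DEFINITION grammar; they are NOT fetched from KEGG. The nitrogenase
# module M00175 carries the canonical nifH/nifD/nifK subunit KOs
# (K02588, K02586, K02591).
ENTRY       M00175            Pathway   Module
NAME        Nitrogen fixation, nitrogen => ammonia
DEFINITION  K02588+K02586+K02591-K00531
///
ENTRY       M00531            Pathway   Module
NAME        Assimilatory nitrate reduction, nitrate => ammonia
DEFINITION  (K00367,K10534,K00372-K00360) (K00366,K17877)
///
ENTRY       M00530            Pathway   Module
NAME        Dissimilatory nitrate reduction, nitrate => ammonia
DEFINITION  (K00370+K00371+K00374,K02567+K02568)
            (K00362+K00363,K03385+K15876)
///
ENTRY       M00529            Pathway   Module
NAME        Denitrification, nitrate => nitrogen
DEFINITION  (K00370+K00371+K00374,K02567+K02568) (K00368,K15864)
            (K04561+K02305) K00376
///
ENTRY       M00176            Pathway   Module
NAME        Assimilatory sulfate reduction, sulfate => H2S
DEFINITION  (K13811,K00958+K00860,K00955+K00957,K00956+K00957+K00860)
            (K00390,K05907) (K00380+K00381,K00392)
///
ENTRY       M00345            Pathway   Module
NAME        Formaldehyde assimilation, ribulose monophosphate pathway
DEFINITION  (K08093,K13812) (K08094,K13831)
///
ENTRY       M00378            Pathway   Module
NAME        F420 biosynthesis
DEFINITION  K11779 K11780 K11781 K12234 K14941
///
ENTRY       M00935            Pathway   Module
NAME        Methanofuran biosynthesis
DEFINITION  K09733 K18933 K07144 -- K18935
///
ENTRY       M00597            Pathway   Module
NAME        Anoxygenic photosystem II
DEFINITION  K08928+K08929-K13991-K13992
///
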