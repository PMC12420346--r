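>ANT1 SYN-ANT1 synthetic stand-in for the human ADP/ATP translocase isoform 1 (not real sequence data)
MGDHAWSFLKDFLAGGVAAAISKEQGVLSFWRTAVAPIERVTLLLQVQHASKGLVDHAQE
FNGLGDCLVKQISAEKSDGILGLYRQYTGIIDCVVRGYFPTQALNFAFKDEGAGAFFKTQ
FWGLVDVYRQATVEAYRYFAGNLASGGAAGATSLCFVYPLDFARGTGGALVLVIYDEIKQ
IFLGGVDKLFRDEGGKNVHIFVSWLIAQSVTAVAGLTSYPFDTVRAADSLSTHLIVKGAD
LVTHDELLKGAWSNVIRMQSGEAVKADTLGSEFHQSVLGTQKYDQLQGWFHSAPLGGQ
>ANT2 SYN-ANT2 synthetic stand-in for the human ADP/ATP translocase isoform 2 (not real sequence data)
MTDAAVSFAKDFLAGGVAAAISKEQGILSFWRTAVAPIERVTLLLQVQHASKGLVDHAQE
FNGLGDCLTKQISAEKSDGIMGLYRQYTGIIDCVVRGYFPTQALNFAFKDEGASAFFKTQ
FWGLVDVYRQATVEAYRYFAGNLASGGAAGATSLCFVYPLDFARGTGGALVLVLYDEIKQ
IFLGGVDKLFRDEGGKNVHIFVSWLIAQSVTAVAGLTSYPFDTVRAADSLSTHLLVKGAD
LVTHDELLKGAWSNVIRMQSGEAVKADTLGSEFHQSVLGTQKYDQLQGWFHSAPLGGQ
>ANT3 SYN-ANT3 synthetic stand-in for the human ADP/ATP translocase isoform 3 (not real sequence data)
MTEQAISFAKDFLAGGVAAAISKEQGILSFWRTAVAPIERVTLLLQVQHASKGLVDHAQE
FNGLGDCLTKQISAEKSDGILGLYRQYTGIIDCVVRGYFPTQALNFAFKDEGASAFFKTQ
FWGLVDVYRQATVDAYRYFAGNLASGGAAGATSLCFVYPLDFARGTGGALVLVIYDEIKQ
IFLGGVDKIFRDEGGKNVHIFVSWLIAQSVTAVAGLTSYPFDTVRAADSLSTHLIVKGAD
LVTHDELLKGAWSNVLRMQSGEAVKADTLGSEFHQSVLGTQKYDQLQGWFHSAPLGGQ
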