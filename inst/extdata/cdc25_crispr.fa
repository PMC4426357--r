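>guide cdc-25.2 Cas9 guide, targets the non-coding strand
ATGTCTCTCAATGTTTCGG
>rescue_oligo HDR template reverting the ts lesion (wild-type base) with silent PAM edit
ATGGGTAGCGGCAATCAATGAGAATATACTTGTCATCAAATTCTTTTTCAGAGAGTCGGA
AAAAGATGTCTCTCAATGTTTCGGCCGTGATTCTTCTGAAGCCTTTCGAGGATTCCTTTG
CAACAGTTTTGAGGTGG
>recreation_oligo HDR template installing the ts lesion into wild type with silent PAM edit
ATGGGTAGCGGCAATCAATGAGAATATACTTGTCATCAAATTCTTTTTCAAAGAGTCGGA
AAAAGATGTCTCTCAATGTTTCGGCCGTGATTCTTCTGAAGCCTTTCGAGGATTCCTTTG
CAACAGTTTTGAGGTGG
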