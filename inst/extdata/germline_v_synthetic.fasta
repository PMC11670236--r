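>VH1-72 cdr1_start=26 cdr1_end=33
TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEWPFECVDTVGGCYDCGLIFATHEPLKNY
KMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSML
>VH1-12 cdr1_start=26 cdr1_end=33
LAWTQQRGRMFSTTVCGGGYRCLNKACCMQCCTFLTTFDQQAFDPMYTYEYMTKTPTYAT
ACISDFPNAWFRGSLHKKDVRRYSAGMKYPFMRCGAQS
>VH1-53 cdr1_start=26 cdr1_end=33
MVCLEYRHTFYVKMGLKWKMWELTNGRKLVHQNWLFCDCQSEGYYMAQAEPGNHNFVHPC
DARYMKLHWVNLKWRQDYLCTVWQTLFPVWWLSCEHAQ
>VH2-2 cdr1_start=26 cdr1_end=33
YWNWGNLHWCGKMGFQLRAKLTNAMEDGFLYCEYKQQDVLAIYFGQEKISNLQMCSQRTG
WLPGAMPLPRTRIEGLYSNSWDHDLLHWPLQMPDLWCH
>VH3-6 cdr1_start=26 cdr1_end=33
YMMAGLKNPVRAMIPQCGPDPSWSPPIPGGIFKLMAREHMLIDPYSIDKSMPHVHFYVHT
DSIWVLRNDYSLCIAPHMMPFCRFQFTVTVHPCNDYIY
>VH5-17 cdr1_start=26 cdr1_end=33
QAQVCFLNDVVVRAIWIYWCYWMRVILCETNYVHKWMMNTCYHTEPWATECIDPCEKMLQ
AAQYMKWFCKDNCSVTYIIWRGDAREKAMGYQKGNTMK
>VH6-3 cdr1_start=26 cdr1_end=33
MWAMTTIMVAGCQFAVERHQLDHFGFVKDDKPHLTCYTNGWLSALHCEYIRQTFTTSYGD
QKNKQDEDHAFEINNNRKDDKHNPTRRYDPWCFKVAEV
>VH7-3 cdr1_start=26 cdr1_end=33
FDLHQLLKHGYIFWYMTHLNEYDASFWTMAAVDFHGSPAWVLQLCSKTCRIDCTDMFADQ
GSLIKDCGCSKFTNYEGCDVTVMIHYAWSIYVLLWPNI
>VH9-3 cdr1_start=26 cdr1_end=33
GHHFAWMCVLGENGTQAMYWFDPWVYQCAQHRGNYMLTLWLKIWHSISMLYVSIFVRCAL
KATPGNWAMSQWFIWSNRHARIGMCAYFFMTTTWPVLD
>VH14-3 cdr1_start=26 cdr1_end=33
TLAMPQPHIEQFYWQWRSDCGHLPLLDYTVTLFIPIYFTKIWPANAGWPWFPQQYNYIMQ
CQLCLDCLRWNVVMKIKIDILLCMLSYCLQWESRMWLC
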