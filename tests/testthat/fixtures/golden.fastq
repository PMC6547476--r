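@SRR554369.1 1/1
AAACCTGGTGACCCGCAGCTCTCCTGCGGCGAGTTATGGCTGGTGTTACG
+SRR554369.1 1/1
<::93;9;766776:95885666:5455054DDCBFB@C>E@CBAE=BDC
@SRR554369.2 2/1
TGTTCCGTCTCGTCCTCATATATGCAAGGCCCAATGTCAGCGCAACTCGG
+SRR554369.2 2/1
:;9ADDBDBE:@;==:>C?BB@F>@<:=;:=<:<=>;=8>?8@<;C?<<>
@SRR554369.3 3/1
GAGAGAGAACAGAGGTCGTNGGTGCAACGCTACTTATTCTTTGGCCCACC
+SRR554369.3 3/1
95;4:77966767;989<866888;987<9687;<;;9=<<:>8=<<>7<
@SRR554369.4 4/1
GTTGTCGCGACCGAACCGACTAGATCCAGATGGACCAGCTAGGCAAACGT
+SRR554369.4 4/1
95378877::686:66;7969=;796::856678;;:59:87986789:8
@SRR554369.5 5/1
CCTTCATTCCGACCTCTCGGTACCCATAGTAAATGCTGCGGTGTTACATA
+SRR554369.5 5/1
@B>>@BAB>ABG:39758636;EEHHFIGFHHFHFHDIGIIHGHFFIIGG
@SRR554369.6 6/1
CAAATAGGCGGTTCACGTTTTTTTGAGGCTATACATAGTTTAAGGAGGTC
+SRR554369.6 6/1
9897789>;<9:9=BDDBBAA?BC@?B@;A@AAA@?A@BB?A=<@?<BCC
@SRR554369.7 7/1
TTGATGGGACANGATTTCGACATACAACCATCTACTGCGCGGCCTGCGCG
+SRR554369.7 7/1
>B@GCC>B??B>>DBABABB?C?FED??CACB?BCECF=CBCBDDIEGID
@SRR554369.8 8/1
TGGGGTCGCGCTTCATTATTACGTGGTTACTTATATATTGGGAGCAGAAA
+SRR554369.8 8/1
;>;;9<;9;:;?AA>;=>@?=>B>A@=??<@=<;;9:==;==;?:=<;<;
@SRR554369.9 9/1
GGTATGGCAAGCGTAAAAGGAATCGTCTGTTAGGTCGGCGGCTGCCCTAA
+SRR554369.9 9/1
:?<:><A?<=>?<@::?><<?<>>=99;=;9<;78858779868727656
@SRR554369.10 10/1
AAGAAAGGTTAGCCTGATCGGAGCAGTTGGNACTGAGCTTTTTTCCGCGA
+SRR554369.10 10/1
8766957744569563684353545GFG4645>?B?@;?>=9?<@>=>=B
@SRR554369.11 11/1
CAGGTCCAANCATACGGACAGTAAGATCCGANCACCTACCACTCACACTN
+SRR554369.11 11/1
?C=?HCFEFI5686576555493341783436726562776FFEDEEFFC
@SRR554369.12 12/1
CTCAAACATAACATCCTCGCCAACAGGTTGGTTAAGCAAGGGNCGTGTGG
+SRR554369.12 12/1
?BC@A@AA@@DAA@D@A=@?B??@@>@B>@>@?<<B@7<8677:=7;889
@SRR554369.13 13/1
CTTTAGTGACGAATCTGGTATTGCTTTCTTAAAAGAGCGTATACTTCCCT
+SRR554369.13 13/1
@999;>>8<;;9;:<;<99689798:5::58976;:9748;77498:979
@SRR554369.14 14/1
TACTCAGCTGATGGACCAACGGTCGTTNAGCNTTGGAAGTGGAGCGCACT
+SRR554369.14 14/1
;89DAAECBC9766>:?CCA?AD?C@@D>CB@@AAB?B=C>BA?CDEGGD
@SRR554369.15 15/1
GGAGTGGTCGAAAAAGTCTCNGTTGAGCGCACATGGGCTTTGCGACGCGT
+SRR554369.15 15/1
6:45:GE@FBB??DFGD:9=;;;;<?A>A@D@AAA;@AAA?@DB>>A<IF
@SRR554369.16 16/1
TTGCACGACGCGCATTTTGTACGTTTATCTTCGCATAAGAAGTGCAGCCA
+SRR554369.16 16/1
46585576696656998:785;957HDHGF9<986965<04425582586
@SRR554369.17 17/1
AGCACCGCTGTGCCCATTGGNGTATACTGCCAAACCACATGCGCCGATCA
+SRR554369.17 17/1
DHGEHCGDGBGCGDHCDEEFAFDEBFF9<<67959796467:84483749
@SRR554369.18 18/1
CCAGTCTCAGTTATCTCACCCTCNTACACCAGATCATCCTGTGTCTGCGA
+SRR554369.18 18/1
68753786656659664545586285274/62541025242BAFDAFECE
@SRR554369.19 19/1
TTCGTTGGACCACTGGACAGAGCATCACGTATGCTATGCACCCCGACGGA
+SRR554369.19 19/1
FDDFEEFDIIGGHFIIGGIHHEDCDBF>BCCGD@BBCADHEAEB>>=8;<
@SRR554369.20 20/1
TTTGGAAGCGCCTTGGCGATGGGTCATGAGAGTCGGATCGGTAACATGCG
+SRR554369.20 20/1
ED@@D@CAD@BCACBCB@?DCBEACB<@?18:7606496666;5764654
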