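H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
R PMID:7108955
A Kyte, J. and Doolittle, R.F.
T A simple method for displaying the hydropathic character of a protein
J J. Mol. Biol. 157, 105-132 (1982)
C HOPT810101 -0.770
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.800  -4.500  -3.500  -3.500   2.500  -3.500  -3.500  -0.400  -3.200   4.500
    3.800  -3.900   1.900   2.800  -1.600  -0.800  -0.700  -0.900  -1.300   4.200
//
H HOPT810101
D Hydrophilicity value (Hopp-Woods, 1981)
R PMID:6167991
A Hopp, T.P. and Woods, K.R.
T Prediction of protein antigenic determinants from amino acid sequences
J Proc. Natl. Acad. Sci. USA 78, 3824-3828 (1981)
C KYTJ820101 -0.770
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   -0.500   3.000   0.200   3.000  -1.000   0.200   3.000   0.000  -0.500  -1.800
   -1.800   3.000  -1.300  -2.500   0.000   0.300  -0.400  -3.400  -2.300  -1.500
//
H FASG760101
D Molecular weight (Fasman, 1976)
R
A Fasman, G.D., ed.
T Molecular weight of the amino acid
J Handbook of Biochemistry and Molecular Biology, CRC Press (1976)
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   89.090 174.200 132.120 133.100 121.150 146.150 147.130  75.070 155.160 131.170
  131.170 146.190 149.210 165.190 115.130 105.090 119.120 204.230 181.190 117.150
//
H SYNTHNA01
D Synthetic incomplete index (fabricated for this package's test fixture;
  contains NA values and is excluded by the reader)
R
A none
T none
J none
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.100      NA   0.300   0.400   0.500   0.600   0.700   0.800   0.900   1.000
    1.100   1.200      NA   1.400   1.500   1.600   1.700   1.800   1.900   2.000
//
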