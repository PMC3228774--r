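H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
   3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H FAUJ880103
D Normalized van der Waals volume (Fauchere et al., 1988)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  1.00    6.13    2.95    2.78    2.43    3.95    3.78    0.00    4.66    4.00
  4.00    4.77    4.43    5.89    2.72    1.60    2.60    8.08    6.47    3.00
//
H GRAR740102
D Polarity (Grantham, 1974)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   8.1    10.5    11.6    13.0     5.5    10.5    12.3     9.0    10.4     5.2
   4.9    11.3     5.7     5.2     8.0     9.2     8.6     5.4     6.2     5.9
//
H FASG760101
D Molecular weight (Fasman, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  89.09  174.20  132.12  133.10  121.15  146.15  147.13   75.07  155.16  131.17
 131.17  146.19  149.21  165.19  115.13  105.09  119.12  204.24  181.19  117.15
//
H HOPT810101
D Hydrophilicity value (Hopp-Woods, 1981)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  -0.5     3.0     0.2     3.0    -1.0     0.2     3.0     0.0    -0.5    -1.8
  -1.8     3.0    -1.3    -2.5     0.0     0.3    -0.4    -3.4    -2.3    -1.5
//
H CHOP780201
D Normalized frequency of alpha-helix (Chou-Fasman, 1978)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  1.42    0.98    0.67    1.01    0.70    1.11    1.51    0.57    1.00    1.08
  1.21    1.16    1.45    1.13    0.57    0.77    0.83    1.08    0.69    1.06
//
H CHOP780202
D Normalized frequency of beta-sheet (Chou-Fasman, 1978)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  0.83    0.93    0.89    0.54    1.19    1.10    0.37    0.75    0.87    1.60
  1.30    0.74    1.05    1.38    0.55    0.75    1.19    1.37    1.47    1.70
//
H EISD840101
D Consensus normalized hydrophobicity scale (Eisenberg, 1984)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  0.62   -2.53   -0.78   -0.90    0.29   -0.85   -0.74    0.48   -0.40    1.38
  1.06   -1.50    0.64    1.19    0.12   -0.18   -0.05    0.81    0.26    1.08
//
H ZIMJ680104
D Isoelectric point (Zimmerman et al., 1968)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  6.00   10.76    5.41    2.77    5.05    5.65    3.22    5.97    7.59    6.02
  5.98    9.74    5.74    5.48    6.30    5.68    5.66    5.89    5.66    5.96
//
H XATM000101
D Number of side-chain heavy atoms (synthetic reference scale)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1       7       4       4       2       5       5       0       6       4
     4       5       4       7       3       2       3      10       8       3
//
H XCHG000101
D Side-chain net charge at neutral pH (synthetic reference scale)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0       1       0      -1       0       0      -1       0       0       0
     0       1       0       0       0       0       0       0       0       0
//
H XNAX000101
D Demonstration scale with missing values (synthetic)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   1.0      NA     0.5     0.5     1.5      NA     0.5     2.0     0.5     1.0
   1.0     0.5     1.0     1.5     0.5     1.0     1.0      NA     1.5     1.0
//
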