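H MCMT640101
D Refractivity (McMeekin et al., 1964), Cited by Jones (1975)
R LIT:2004003b
A McMeekin, T.L., Groves, M.L. and Hipp, N.J.
T Refractive indices of amino acids, proteins, and related substances
J In "Amino Acids and Serum Proteins" (Stekol, J.A., ed.), American Chemical
  Society, Washington, D.C., p.54 (1964)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    4.34   26.66   13.28   12.00   35.77   17.56   17.26    0.00   21.81   19.06
   18.78   21.29   21.64   29.40   10.93    6.35   11.01   13.92   42.53   31.53
//
H SYNEXT2141
D Molar extinction coefficient of free amino acids at 214 nm (synthetic demo
  record for this package, values as published by Kuipers and Gruppen 2007)
R
A synthetic
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     32.    102.    136.     58.    225.    142.     78.     21.   5125.     45.
     45.     41.    980.   5200.     30.     34.     41.     43.  29050.   5375.
//
H SYNNA00001
D Synthetic demo record containing NA values (excluded from screening)
R
A synthetic
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.10    0.20      NA    0.40    0.50    0.60    0.70    0.80    0.90    1.00
    1.10    1.20    1.30    1.40    1.50    1.60    1.70    1.80    1.90    2.00
//
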