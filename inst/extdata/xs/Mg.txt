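# element photon data: Mg (Z=12)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 12
# A: 24.30500
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 836.33 0.017152 2.1481 836.33
1.12202 612.81 0.020288 2.1025 612.81
1.25893 448.56 0.023782 2.0502 448.56
1.30435 407.37 0.024927 2.0327 407.37
1.30565 5244.7 0.02496 2.0322 5244.7
1.41254 4733.9 0.027616 1.9913 4733.9
1.58489 3504.8 0.03177 1.9263 3504.8
1.77828 2600 0.036238 1.8561 2600
1.99526 1929.7 0.041041 1.7818 1929.7
2.23872 1425.7 0.046224 1.7046 1425.7
2.51189 1048.6 0.051844 1.6253 1048.6
2.81838 767.51 0.057946 1.544 767.51
3.16228 559.14 0.064546 1.4605 559.14
3.54813 405.66 0.071615 1.3739 405.67
3.98107 293.49 0.079084 1.2833 293.49
4.46684 211.73 0.086839 1.1883 211.73
5.01187 152.32 0.094731 1.0893 152.32
5.62341 109.26 0.10258 0.98744 109.27
6.30957 78.083 0.11021 0.88475 78.084
7.07946 55.673 0.11741 0.78354 55.675
7.94328 39.607 0.12403 0.68628 39.61
8.91251 28.115 0.12994 0.59516 28.117
10 19.863 0.1351 0.51181 19.866
11.2202 14.01 0.13955 0.4372 14.014
12.5893 9.8661 0.14339 0.3716 9.8698
14.1254 6.9363 0.14668 0.31472 6.9405
15.8489 4.8685 0.14951 0.26589 4.8732
17.7828 3.4115 0.15193 0.2242 3.4167
19.9526 2.3866 0.154 0.18869 2.3925
22.3872 1.6668 0.15573 0.15848 1.6734
25.1189 1.1622 0.15713 0.13284 1.1695
28.1838 0.80897 0.1582 0.11146 0.81717
31.6228 0.5623 0.15889 0.093679 0.57139
35.4813 0.39031 0.15916 0.078788 0.40035
39.8107 0.27055 0.15898 0.066259 0.28159
44.6684 0.18728 0.15834 0.055677 0.19937
50.1187 0.12946 0.15727 0.046705 0.14263
56.2341 0.089371 0.15579 0.039079 0.10365
63.0957 0.061609 0.15392 0.032591 0.077031
70.7946 0.042412 0.1517 0.027077 0.058997
79.4328 0.029157 0.14914 0.022408 0.046915
89.1251 0.020017 0.14628 0.018478 0.038947
100 0.013723 0.14313 0.015193 0.033813
112.202 0.0093946 0.13972 0.012465 0.03062
125.893 0.0064227 0.13609 0.010215 0.028745
141.254 0.0043849 0.13226 0.0083675 0.027753
158.489 0.0029895 0.12826 0.0068574 0.027343
177.828 0.0020353 0.12414 0.0056273 0.027303
199.526 0.0013838 0.11991 0.0046293 0.027486
223.872 0.00093948 0.11562 0.0038235 0.027789
251.189 0.00063696 0.11129 0.003177 0.028143
281.838 0.00043125 0.10694 0.0026623 0.028496
316.228 0.00029157 0.10259 0.0022561 0.028816
354.813 0.00019686 0.098281 0.0019387 0.02908
398.107 0.00013273 0.094013 0.0016931 0.029273
446.684 8.9365e-05 0.089803 0.0015045 0.029384
501.187 6.0085e-05 0.085664 0.0013607 0.029407
562.341 4.0343e-05 0.081603 0.0012513 0.029339
630.957 2.7049e-05 0.07763 0.0011679 0.029179
707.946 1.8111e-05 0.073747 0.0011044 0.028927
794.328 1.2109e-05 0.069961 0.001055 0.028584
891.251 8.0853e-06 0.066275 0.0010172 0.028153
1000 5.391e-06 0.062691 0.00098723 0.027639
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 11.9865
0.01 11.9661
0.0130782 11.9517
0.0171039 11.9272
0.0223689 11.8858
0.0292545 11.8163
0.0382596 11.7012
0.0500366 11.5147
0.0654389 11.2237
0.0855824 10.7963
0.111926 10.2249
0.14638 9.55252
0.191438 8.84674
0.250367 8.08134
0.327435 7.10654
0.428225 5.84681
0.560042 4.42181
0.732434 3.09652
0.957892 2.13149
1.25275 1.59747
1.63837 1.3026
2.1427 1.10148
2.80226 0.979831
3.66485 0.813893
4.79297 0.613771
6.26834 0.408951
8.19787 0.236762
10.7213 0.119262
14.0216 0.0532561
18.3377 0.0216764
23.9824 0.00826782
31.3647 0.00302193
41.0194 0.00107537
53.646 0.000376483
70.1593 0.00013052
91.7557 4.49871e-05
120 1.54528e-05
# incoherent scattering function S(x), same x grid
@sf 37
0 0.0269093
0.01 0.0673637
0.0130782 0.0957872
0.0171039 0.143795
0.0223689 0.224185
0.0292545 0.356818
0.0382596 0.570302
0.0500366 0.900269
0.0654389 1.37867
0.0855824 2.011
0.111926 2.76223
0.14638 3.60725
0.191438 4.6137
0.250367 5.84955
0.327435 7.2254
0.428225 8.52945
0.560042 9.53072
0.732434 10.1196
0.957892 10.4515
1.25275 10.7504
1.63837 11.0862
2.1427 11.4333
2.80226 11.6961
3.66485 11.8334
4.79297 11.9027
6.26834 11.9503
8.19787 11.9811
10.7213 11.9948
14.0216 11.9989
18.3377 11.9998
23.9824 12
31.3647 12
41.0194 12
53.646 12
70.1593 12
91.7557 12
120 12
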