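# element photon data: K (Z=19)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 19
# A: 39.09830
# kedge_keV: 3.6074
# kjump: 9.6842
# kyield: 0.1400
# klines_keV: 3.314 3.590
# klines_w: 0.8800 0.1200
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 3900.1 0.017835 3.3474 3900.1
1.12202 2900.8 0.021031 3.2818 2900.8
1.25893 2149.9 0.024584 3.2079 2149.9
1.41254 1588.7 0.028497 3.1254 1588.7
1.58489 1171.2 0.032776 3.0336 1171.2
1.77828 861.29 0.037433 2.9319 861.29
1.99526 632.2 0.042481 2.8193 632.2
2.23872 463.2 0.047917 2.6951 463.2
2.51189 338.75 0.053712 2.559 338.75
2.81838 247.3 0.059799 2.4117 247.3
3.16228 180.04 0.06608 2.2547 180.04
3.54813 130.75 0.072442 2.0907 130.75
3.6056 125.03 0.07333 2.0675 125.03
3.6092 1211.7 0.073385 2.0661 1070.6
3.98107 938.03 0.078777 1.9234 839.02
4.46684 696.04 0.085011 1.7568 630.56
5.01187 514.55 0.091116 1.595 471.41
5.62341 378.94 0.09711 1.4417 350.62
6.30957 277.97 0.10303 1.2991 259.46
7.07946 203.11 0.1089 1.1684 191.06
7.94328 147.79 0.11469 1.0488 139.97
8.91251 107.18 0.12034 0.93883 102.13
10 77.373 0.12575 0.83646 74.125
11.2202 55.719 0.13082 0.74027 53.635
12.5893 40.025 0.13546 0.64959 38.693
14.1254 28.68 0.1396 0.56454 27.831
15.8489 20.495 0.14319 0.48574 19.957
17.7828 14.596 0.1462 0.41407 14.256
19.9526 10.375 0.14865 0.35026 10.162
22.3872 7.3603 0.15057 0.29464 7.2286
25.1189 5.2118 0.15202 0.24706 5.1318
28.1838 3.6766 0.15304 0.20786 3.6297
31.6228 2.5849 0.15365 0.17555 2.5594
35.4813 1.8155 0.1539 0.14854 1.8037
39.8107 1.2738 0.15377 0.12584 1.271
44.6684 0.89277 0.15328 0.10674 0.89608
50.1187 0.62506 0.15242 0.09064 0.63259
56.2341 0.43715 0.15119 0.077043 0.44777
63.0957 0.30541 0.14959 0.06551 0.3184
70.7946 0.21314 0.14764 0.055674 0.22807
79.4328 0.14858 0.14533 0.047237 0.16516
89.1251 0.10347 0.1427 0.039968 0.12152
100 0.071973 0.13977 0.033691 0.091361
112.202 0.05001 0.13657 0.028278 0.070642
125.893 0.034711 0.13313 0.023631 0.056504
141.254 0.024066 0.12948 0.019672 0.046943
158.489 0.016667 0.12566 0.01633 0.04055
177.828 0.01153 0.12169 0.013535 0.036338
199.526 0.0079675 0.11761 0.011218 0.033614
223.872 0.0054996 0.11346 0.0093115 0.031895
251.189 0.003792 0.10925 0.0077529 0.030841
281.838 0.0026116 0.10502 0.0064843 0.030218
316.228 0.0017967 0.10079 0.005455 0.02986
354.813 0.0012347 0.09658 0.0046215 0.029654
398.107 0.00084756 0.092408 0.0039475 0.029522
446.684 0.00058115 0.08829 0.0034033 0.029409
501.187 0.00039804 0.084235 0.0029657 0.029279
562.341 0.00027232 0.080255 0.0026159 0.029107
630.957 0.0001861 0.076357 0.0023385 0.028877
707.946 0.00012704 0.072546 0.0021216 0.028579
794.328 8.6627e-05 0.068827 0.0019517 0.028208
891.251 5.9004e-05 0.065205 0.0018231 0.027761
1000 4.0144e-05 0.061683 0.0017232 0.027238
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 18.999
0.01 18.9621
0.0130782 18.9362
0.0171039 18.8925
0.0223689 18.8194
0.0292545 18.6988
0.0382596 18.5048
0.0500366 18.2046
0.0654389 17.7649
0.0855824 17.1627
0.111926 16.3786
0.14638 15.3534
0.191438 13.9849
0.250367 12.2588
0.327435 10.3642
0.428225 8.66434
0.560042 7.40612
0.732434 6.341
0.957892 5.07722
1.25275 3.62815
1.63837 2.35247
2.1427 1.74241
2.80226 1.65885
3.66485 1.52925
4.79297 1.34028
6.26834 1.08944
8.19787 0.798126
10.7213 0.513727
14.0216 0.286889
18.3377 0.139859
23.9824 0.0608401
31.3647 0.0243004
41.0194 0.00915249
53.646 0.00331857
70.1593 0.00117513
91.7557 0.000410188
120 0.000141954
# incoherent scattering function S(x), same x grid
@sf 37
0 0.00199879
0.01 0.0755996
0.0130782 0.127115
0.0171039 0.213773
0.0223689 0.3579
0.0292545 0.593053
0.0382596 0.965072
0.0500366 1.52597
0.0654389 2.31516
0.0855824 3.3359
0.111926 4.56647
0.14638 6.01799
0.191438 7.69434
0.250367 9.43159
0.327435 10.993
0.428225 12.3841
0.560042 13.8044
0.732434 15.1912
0.957892 16.3036
1.25275 17.0382
1.63837 17.4752
2.1427 17.8203
2.80226 18.1678
3.66485 18.4878
4.79297 18.7281
6.26834 18.8689
8.19787 18.9403
10.7213 18.9761
14.0216 18.9924
18.3377 18.9982
23.9824 18.9996
31.3647 18.9999
41.0194 19
53.646 19
70.1593 19
91.7557 19
120 19
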