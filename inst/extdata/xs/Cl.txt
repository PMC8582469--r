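# element photon data: Cl (Z=17)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 17
# A: 35.45300
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 2687.3 0.013198 3.034 2687.3
1.12202 1990.4 0.016141 2.9804 1990.4
1.25893 1470.5 0.019612 2.9161 1470.5
1.41254 1084.2 0.023644 2.8399 1084.2
1.58489 797.82 0.028251 2.7509 797.82
1.77828 585.96 0.03341 2.6485 585.96
1.99526 429.55 0.03906 2.5328 429.55
2.23872 314.29 0.045103 2.4048 314.29
2.51189 229.52 0.051409 2.2661 229.52
2.81838 167.28 0.057842 2.1196 167.28
2.82099 166.86 0.057894 2.1184 166.86
2.82381 1720.4 0.05795 2.1171 1720.4
3.16228 1294 0.064281 1.9686 1294
3.54813 960.1 0.070649 1.8167 960.1
3.98107 710.25 0.076923 1.6676 710.25
4.46684 523.54 0.083131 1.5244 523.54
5.01187 384.44 0.089323 1.3892 384.44
5.62341 281.19 0.095537 1.2633 281.19
6.30957 204.65 0.10177 1.1463 204.65
7.07946 148.49 0.10797 1.037 148.49
7.94328 107.4 0.11405 0.93393 107.41
8.91251 77.447 0.1199 0.83556 77.45
10 55.625 0.12541 0.74124 55.628
11.2202 39.856 0.13048 0.65113 39.859
12.5893 28.476 0.13503 0.56603 28.479
14.1254 20.275 0.139 0.48711 20.279
15.8489 14.409 0.14237 0.41548 14.414
17.7828 10.221 0.14516 0.35191 10.226
19.9526 7.2371 0.14742 0.29659 7.2428
22.3872 5.1144 0.1492 0.24914 5.1208
25.1189 3.6075 0.15056 0.2088 3.6146
28.1838 2.5376 0.15153 0.17531 2.5454
31.6228 1.7805 0.15214 0.14755 1.7892
35.4813 1.2476 0.1524 0.12431 1.2572
39.8107 0.87296 0.1523 0.10481 0.88354
44.6684 0.60997 0.15183 0.088421 0.62156
50.1187 0.42561 0.15098 0.074633 0.43826
56.2341 0.29655 0.14975 0.063003 0.3103
63.0957 0.20633 0.14814 0.053155 0.22121
70.7946 0.14335 0.14617 0.044782 0.15938
79.4328 0.099457 0.14385 0.037638 0.11664
89.1251 0.068903 0.14121 0.031532 0.087235
100 0.047667 0.13827 0.026319 0.067134
112.202 0.032929 0.13507 0.021885 0.053505
125.893 0.022715 0.13164 0.018139 0.044362
141.254 0.015646 0.128 0.014998 0.038315
158.489 0.010762 0.12419 0.012387 0.034392
177.828 0.0073917 0.12025 0.010233 0.031914
199.526 0.0050695 0.1162 0.0084673 0.030406
223.872 0.0034719 0.11208 0.007027 0.029538
251.189 0.0023743 0.10791 0.0058566 0.02908
281.838 0.0016213 0.10371 0.0049079 0.028872
316.228 0.0011056 0.099525 0.0041402 0.028804
354.813 0.00075278 0.095359 0.0035201 0.028801
398.107 0.00051183 0.091232 0.003021 0.02881
446.684 0.0003475 0.087158 0.0026213 0.028796
501.187 0.00023559 0.08315 0.0023038 0.028736
562.341 0.00015949 0.079217 0.0020541 0.028613
630.957 0.00010781 0.075365 0.0018598 0.02842
707.946 7.2775e-05 0.0716 0.0017111 0.028148
794.328 4.9054e-05 0.067928 0.0015969 0.027798
891.251 3.3017e-05 0.064351 0.0015118 0.027368
1000 2.219e-05 0.060874 0.0014461 0.02686
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 17.0005
0.01 16.9802
0.0130782 16.9659
0.0171039 16.9414
0.0223689 16.8997
0.0292545 16.8289
0.0382596 16.7096
0.0500366 16.5103
0.0654389 16.1827
0.0855824 15.6591
0.111926 14.8583
0.14638 13.717
0.191438 12.2529
0.250367 10.6263
0.327435 9.10958
0.428225 7.90187
0.560042 6.8763
0.732434 5.68911
0.957892 4.26245
1.25275 2.87162
1.63837 1.90198
2.1427 1.48702
2.80226 1.39917
3.66485 1.26598
4.79297 1.07847
6.26834 0.842016
8.19787 0.58562
10.7213 0.355219
14.0216 0.186987
18.3377 0.0865971
23.9824 0.0362116
31.3647 0.0140684
41.0194 0.00520331
53.646 0.00186528
70.1593 0.000655932
91.7557 0.000228005
120 7.8711e-05
# incoherent scattering function S(x), same x grid
@sf 37
0 1e-12
0.01 0.0394887
0.0130782 0.0681203
0.0171039 0.116847
0.0223689 0.199447
0.0292545 0.338631
0.0382596 0.570686
0.0500366 0.950734
0.0654389 1.55484
0.0855824 2.46883
0.111926 3.7462
0.14638 5.32829
0.191438 6.99188
0.250367 8.48016
0.327435 9.78688
0.428225 11.1362
0.560042 12.5572
0.732434 13.8178
0.957892 14.7297
1.25275 15.2741
1.63837 15.6299
2.1427 15.9688
2.80226 16.3195
3.66485 16.6165
4.79297 16.8115
6.26834 16.9128
8.19787 16.9619
10.7213 16.9859
14.0216 16.996
18.3377 16.9991
23.9824 16.9998
31.3647 17
41.0194 17
53.646 17
70.1593 17
91.7557 17
120 17
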