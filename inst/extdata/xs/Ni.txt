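# element photon data: Ni (Z=28)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 28
# A: 58.69340
# kedge_keV: 8.3328
# kjump: 8.1704
# kyield: 0.4060
# klines_keV: 7.472 8.265
# klines_w: 0.8700 0.1300
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 65
1 9606.6 0.010476 5.0535 9606.6
1.0076 9428.6 0.010615 5.0495 9428.6
1.0086 10693 0.010633 5.049 10693
1.12202 8305.8 0.012767 4.9874 8305.8
1.25893 6309.3 0.015472 4.9088 6309.3
1.41254 4764.6 0.018626 4.8165 4764.6
1.58489 3577.2 0.022252 4.7095 3577.2
1.77828 2675 0.026359 4.5873 2675
1.99526 1993.5 0.030938 4.4494 1993.5
2.23872 1480 0.035971 4.296 1480
2.51189 1095.3 0.04143 4.1274 1095.3
2.81838 808.17 0.047286 3.9436 808.17
3.16228 594.29 0.05351 3.7447 594.29
3.54813 435.66 0.060068 3.5309 435.66
3.98107 318.52 0.066902 3.3029 318.52
4.46684 232.49 0.073922 3.0626 232.5
5.01187 169.36 0.081002 2.8133 169.36
5.62341 123.2 0.088 2.5595 123.2
6.30957 89.505 0.094779 2.3067 89.506
7.07946 64.937 0.10123 2.0603 64.938
7.94328 47.048 0.10729 1.8254 47.05
8.32863 41.188 0.10966 1.7331 41.19
8.33697 336.89 0.10971 1.7312 227.83
8.91251 279.17 0.11293 1.6062 194.63
10 206.82 0.11819 1.4059 151
11.2202 152.58 0.1231 1.2259 115.88
12.5893 112.07 0.12766 1.0666 88.046
14.1254 82.041 0.13189 0.92635 66.368
15.8489 59.855 0.13575 0.80297 49.666
17.7828 43.487 0.13918 0.6938 36.891
19.9526 31.487 0.14214 0.59656 27.233
22.3872 22.736 0.14459 0.50966 20.001
25.1189 16.371 0.14652 0.43224 14.619
28.1838 11.752 0.1479 0.36825 10.634
31.6228 8.4128 0.14875 0.31656 7.7034
35.4813 6.0097 0.1491 0.27387 5.5621
39.8107 4.274 0.149 0.23826 3.9946
44.6684 3.0342 0.14848 0.20841 2.8623
50.1187 2.1513 0.14759 0.18327 2.0478
56.2341 1.5233 0.14635 0.16199 1.4636
63.0957 1.0772 0.14478 0.1438 1.0457
70.7946 0.76073 0.14289 0.12804 0.74739
79.4328 0.5365 0.1407 0.11418 0.53508
89.1251 0.37786 0.13822 0.10176 0.38437
100 0.26576 0.13547 0.09046 0.27768
112.202 0.18666 0.13247 0.080034 0.20239
125.893 0.13093 0.12924 0.070346 0.14942
141.254 0.091705 0.1258 0.061342 0.1123
158.489 0.064144 0.12219 0.053029 0.086377
177.828 0.044804 0.11844 0.045445 0.068362
199.526 0.031252 0.11457 0.038636 0.055901
223.872 0.021769 0.11061 0.032627 0.047327
251.189 0.015143 0.10659 0.027414 0.041456
281.838 0.010519 0.10254 0.022957 0.037454
316.228 0.0072966 0.098471 0.019194 0.034731
354.813 0.0050545 0.094414 0.016045 0.032873
398.107 0.0034966 0.090383 0.01343 0.031589
446.684 0.0024156 0.086395 0.011271 0.030675
501.187 0.0016665 0.082463 0.0094951 0.029989
562.341 0.0011482 0.078596 0.0080415 0.029433
630.957 0.00078998 0.074803 0.0068545 0.02894
707.946 0.00054281 0.071091 0.0058919 0.028463
794.328 0.00037248 0.067464 0.005104 0.02797
891.251 0.00025526 0.063928 0.0044754 0.027443
1000 0.0001747 0.060486 0.0039621 0.02687
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 27.9875
0.01 27.9612
0.0130782 27.9426
0.0171039 27.9108
0.0223689 27.857
0.0292545 27.7659
0.0382596 27.6133
0.0500366 27.3611
0.0654389 26.9537
0.0855824 26.3191
0.111926 25.3832
0.14638 24.0977
0.191438 22.4479
0.250367 20.3854
0.327435 17.8049
0.428225 14.7713
0.560042 11.6634
0.732434 8.9979
0.957892 7.16251
1.25275 5.93881
1.63837 4.69742
2.1427 3.63256
2.80226 3.55004
3.66485 3.41526
4.79297 3.20189
6.26834 2.88062
8.19787 2.43314
10.7213 1.87732
14.0216 1.28647
18.3377 0.76769
23.9824 0.397833
31.3647 0.181841
41.0194 0.0752954
53.646 0.029056
70.1593 0.0106998
91.7557 0.00382528
120 0.00134296
# incoherent scattering function S(x), same x grid
@sf 37
0 0.0249928
0.01 0.0775361
0.0130782 0.11469
0.0171039 0.177875
0.0223689 0.284951
0.0292545 0.465212
0.0382596 0.76535
0.0500366 1.25597
0.0654389 2.03423
0.0855824 3.2114
0.111926 4.87064
0.14638 7.00284
0.191438 9.49773
0.250367 12.2506
0.327435 15.1511
0.428225 17.8568
0.560042 20.0089
0.732434 21.6709
0.957892 23.1635
1.25275 24.5299
1.63837 25.5635
2.1427 26.207
2.80226 26.5521
3.66485 26.8403
4.79297 27.1491
6.26834 27.4407
8.19787 27.6661
10.7213 27.8197
14.0216 27.9175
18.3377 27.9704
23.9824 27.9919
31.3647 27.9983
41.0194 27.9997
53.646 28
70.1593 28
91.7557 28
120 28
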