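# element photon data: Ir (Z=77)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 77
# A: 192.21700
# kedge_keV: 76.1110
# kjump: 4.9905
# kyield: 0.9580
# klines_keV: 64.896 63.287 73.560 75.620
# klines_w: 0.4600 0.2700 0.2100 0.0600
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 77
1 4036.6 0.0059471 11.896 4036.6
1.12202 3237.8 0.0072947 11.791 3237.8
1.25893 2573.1 0.0089197 11.664 2573.1
1.41254 2029.7 0.010861 11.512 2029.7
1.58489 1597.1 0.013155 11.331 1597.1
1.77828 1253 0.015832 11.12 1253
1.99526 979.8 0.018914 10.876 979.8
2.03938 934.64 0.019546 10.826 934.64
2.04142 14774 0.019575 10.824 14774
2.11504 3519.8 0.020632 10.74 3519.8
2.11716 12651 0.020662 10.737 12651
2.23872 3283.4 0.022408 10.598 3283.4
2.51189 2475.1 0.026311 10.286 2475.1
2.54942 2384.7 0.026843 10.244 2384.7
2.55198 2787.4 0.026879 10.241 2787.4
2.81838 2173.2 0.030607 9.9409 2173.2
2.90725 2014.3 0.03183 9.8422 2014.3
2.91015 2148.4 0.03187 9.8389 2148.4
3.16228 1748.5 0.035273 9.5631 1748.5
3.54813 1387 0.040282 9.1545 1387
3.98107 1050.2 0.045603 8.7164 1050.2
4.46684 791.49 0.051198 8.251 791.5
5.01187 594.64 0.057011 7.7617 594.64
5.62341 445.48 0.062963 7.2539 445.48
6.30957 332.83 0.068958 6.7345 332.83
7.07946 248.12 0.074898 6.2107 248.12
7.94328 184.63 0.080696 5.6889 184.63
8.91251 137.13 0.086285 5.174 137.14
10 101.53 0.091612 4.6699 101.54
11.2096 75.279 0.09658 4.1847 75.281
11.2202 198.81 0.09662 4.1808 198.81
11.2208 198.78 0.096622 4.1805 198.78
12.5893 145.5 0.10125 3.712 145.5
12.8177 138.52 0.10193 3.641 138.53
12.8305 192.7 0.10197 3.6371 192.7
13.4118 171.02 0.10361 3.4653 171.02
13.4252 197.29 0.10364 3.4615 197.29
14.1254 173.45 0.10543 3.2701 173.45
15.8489 128.93 0.10911 2.8613 128.93
17.7828 95.589 0.11228 2.4901 95.593
19.9526 70.7 0.11493 2.1583 70.705
22.3872 52.174 0.1171 1.8652 52.179
25.1189 38.413 0.11881 1.6086 38.419
28.1838 28.202 0.12007 1.3962 28.208
31.6228 20.659 0.12089 1.2226 20.666
35.4813 15.115 0.12135 1.0785 15.123
39.8107 11.045 0.12146 0.95847 11.054
44.6684 8.0611 0.12122 0.85865 8.0704
50.1187 5.8743 0.12066 0.77592 5.8845
56.2341 4.2736 0.11976 0.70754 4.2846
63.0957 3.103 0.11854 0.65108 3.1149
70.7946 2.2513 0.11701 0.60437 2.2642
76.0729 1.842 0.1159 0.57927 1.8555
76.1491 9.1982 0.11589 0.57895 3.0191
79.4328 8.2804 0.11519 0.56549 2.95
89.1251 6.1323 0.1131 0.53276 2.6196
100 4.5293 0.11078 0.50474 2.2229
112.202 3.3334 0.10826 0.48017 1.8268
125.893 2.4509 0.10556 0.45793 1.4702
141.254 1.8003 0.10272 0.43708 1.1651
158.489 1.3176 0.099752 0.41677 0.9104
177.828 0.96018 0.096693 0.39632 0.70313
199.526 0.70062 0.093563 0.37512 0.54107
223.872 0.51189 0.090381 0.35278 0.41577
251.189 0.37448 0.087168 0.32903 0.31972
281.838 0.27431 0.083938 0.30385 0.24659
316.228 0.20121 0.080708 0.27743 0.19118
354.813 0.14778 0.07749 0.25017 0.14937
398.107 0.10869 0.074293 0.2227 0.1179
446.684 0.080054 0.071127 0.19571 0.094256
501.187 0.059046 0.067998 0.16992 0.076493
562.341 0.043615 0.064912 0.14596 0.063137
630.957 0.032266 0.061874 0.12426 0.053069
707.946 0.023906 0.058889 0.10505 0.045443
794.328 0.017741 0.055961 0.088339 0.039625
891.251 0.013188 0.053096 0.074033 0.03514
1000 0.0098191 0.050296 0.061876 0.031636
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 76.952
0.01 76.906
0.0130782 76.8733
0.0171039 76.8177
0.0223689 76.723
0.0292545 76.5623
0.0382596 76.2912
0.0500366 75.8381
0.0654389 75.0927
0.0855824 73.8977
0.111926 72.0585
0.14638 69.3928
0.191438 65.813
0.250367 61.335
0.327435 55.9317
0.428225 49.6141
0.560042 42.7714
0.732434 35.7106
0.957892 28.4481
1.25275 21.8164
1.63837 16.9365
2.1427 14.4448
2.80226 14.4008
3.66485 14.3258
4.79297 14.1991
6.26834 13.9861
8.19787 13.6328
10.7213 13.0587
14.0216 12.1576
18.3377 10.8189
23.9824 8.99155
31.3647 6.78568
41.0194 4.52529
53.646 2.6224
70.1593 1.32212
91.7557 0.590809
120 0.240597
# incoherent scattering function S(x), same x grid
@sf 37
0 0.0960349
0.01 0.187963
0.0130782 0.253087
0.0171039 0.364083
0.0223689 0.552827
0.0292545 0.872468
0.0382596 1.41006
0.0500366 2.30364
0.0654389 3.76043
0.0855824 6.06134
0.111926 9.51953
0.14638 14.3533
0.191438 20.5127
0.250367 27.6831
0.327435 35.5474
0.428225 43.6569
0.560042 51.1376
0.732434 57.4712
0.957892 62.5775
1.25275 66.1284
1.63837 68.3537
2.1427 69.9181
2.80226 71.1324
3.66485 72.2629
4.79297 73.056
6.26834 73.4893
8.19787 73.7807
10.7213 74.1433
14.0216 74.639
18.3377 75.2209
23.9824 75.8124
31.3647 76.3328
41.0194 76.7034
53.646 76.9
70.1593 76.9745
91.7557 76.9949
120 76.9992
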