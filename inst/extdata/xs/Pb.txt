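# element photon data: Pb (Z=82)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 82
# A: 207.20000
# kedge_keV: 88.0050
# kjump: 4.7597
# kyield: 0.9670
# klines_keV: 74.969 72.805 84.936 87.320
# klines_w: 0.4600 0.2700 0.2100 0.0600
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 77
1 5006.1 0.0058892 12.514 5006.1
1.12202 4011.9 0.0072194 12.404 4011.9
1.25893 3202.1 0.0088216 12.271 3202.1
1.41254 2544.6 0.010733 12.111 2544.6
1.58489 2012.9 0.012988 11.922 2012.9
1.77828 1581.9 0.015616 11.702 1581.9
1.99526 1235.5 0.018635 11.448 1235.5
2.23872 961.56 0.022054 11.158 961.56
2.48276 765.14 0.025466 10.868 765.14
2.48524 10207 0.025501 10.865 10207
2.51189 6231.5 0.02587 10.834 6231.5
2.58431 2336.3 0.026872 10.748 2336.3
2.58689 8326.9 0.026908 10.745 8326.9
2.81838 2271.2 0.03007 10.475 2271.2
3.06487 1828.3 0.033359 10.192 1828.3
3.06793 2143.3 0.0334 10.188 2143.3
3.16228 1974.7 0.034635 10.082 1974.7
3.54813 1478.4 0.039544 9.6561 1478.4
3.55242 1474 0.039598 9.6515 1474
3.55598 1572.5 0.039642 9.6477 1572.5
3.98107 1239.7 0.044773 9.1989 1239.7
4.46684 938.13 0.050284 8.712 938.13
5.01187 707.43 0.056021 8.1995 707.43
5.62341 531.35 0.0619 7.6674 531.35
6.30957 398.09 0.067818 7.1237 398.09
7.07946 297.52 0.073669 6.5769 297.52
7.94328 221.84 0.079361 6.0346 221.84
8.91251 165.09 0.084828 5.5019 165.1
10 122.5 0.090022 4.9825 122.5
11.2202 90.803 0.094907 4.4791 90.805
12.5893 67.216 0.09944 3.9952 67.219
13.0287 61.443 0.10072 3.8553 61.446
13.0417 157.61 0.10075 3.8513 157.61
14.1254 127.06 0.10357 3.5351 127.06
15.1924 104.13 0.10596 3.2587 104.14
15.2076 145.7 0.106 3.255 145.71
15.8489 130.33 0.10727 3.1039 130.34
15.8529 130.24 0.10727 3.103 130.25
15.8687 150.25 0.1073 3.0994 150.25
17.7828 112.32 0.11048 2.7061 112.33
19.9526 83.435 0.1132 2.3454 83.439
22.3872 61.829 0.11544 2.024 61.834
25.1189 45.714 0.1172 1.743 45.72
28.1838 33.699 0.11846 1.5113 33.706
31.6228 24.777 0.11929 1.3221 24.784
35.4813 18.173 0.11974 1.1648 18.18
39.8107 13.314 0.11985 1.0335 13.323
44.6684 9.7442 0.11962 0.92425 9.7534
50.1187 7.1233 0.11906 0.83359 7.1334
56.2341 5.2013 0.11819 0.75865 5.2122
63.0957 3.7922 0.11699 0.69681 3.804
70.7946 2.7617 0.1155 0.64575 2.7744
79.4328 2.0095 0.11372 0.60339 2.0231
87.961 1.5158 0.11192 0.57169 1.5302
88.049 7.2193 0.1119 0.57141 2.3976
89.1251 6.9994 0.11167 0.56794 2.3818
100 5.2102 0.10939 0.53783 2.1525
112.202 3.8613 0.1069 0.51169 1.8478
125.893 2.8549 0.10423 0.48834 1.5345
141.254 2.1032 0.10142 0.46674 1.243
158.489 1.5489 0.098488 0.44599 0.99123
177.828 1.1403 0.095461 0.42532 0.78156
199.526 0.83912 0.092363 0.40407 0.61126
223.872 0.61728 0.089214 0.38173 0.47547
251.189 0.45392 0.086035 0.35796 0.36871
281.838 0.33365 0.082841 0.33261 0.2857
316.228 0.24516 0.079648 0.30576 0.22172
354.813 0.18006 0.076468 0.27774 0.17276
398.107 0.13219 0.073311 0.24909 0.1355
446.684 0.097004 0.070187 0.22049 0.10727
501.187 0.071154 0.0671 0.19273 0.085954
562.341 0.052171 0.064057 0.16653 0.069886
630.957 0.038235 0.061062 0.14245 0.057778
707.946 0.02801 0.058119 0.12089 0.048641
794.328 0.02051 0.055234 0.10194 0.041719
891.251 0.015012 0.052409 0.085589 0.03644
1000 0.010983 0.049649 0.071627 0.032373
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 81.9488
0.01 81.8995
0.0130782 81.8646
0.0171039 81.8051
0.0223689 81.7038
0.0292545 81.532
0.0382596 81.2423
0.0500366 80.7585
0.0654389 79.964
0.0855824 78.6938
0.111926 76.7467
0.14638 73.9388
0.191438 70.1838
0.250367 65.4808
0.327435 59.7619
0.428225 53.0573
0.560042 45.8993
0.732434 38.7306
0.957892 31.409
1.25275 24.2496
1.63837 18.3061
2.1427 15.3697
2.80226 15.3284
3.66485 15.258
4.79297 15.1388
6.26834 14.9382
8.19787 14.6041
10.7213 14.0582
14.0216 13.1928
18.3377 11.8875
23.9824 10.064
31.3647 7.78982
41.0194 5.35937
53.646 3.21212
70.1593 1.67151
91.7557 0.766659
120 0.318273
# incoherent scattering function S(x), same x grid
@sf 37
0 0.102365
0.01 0.200772
0.0130782 0.270467
0.0171039 0.389213
0.0223689 0.59116
0.0292545 0.932983
0.0382596 1.50753
0.0500366 2.46162
0.0654389 4.01447
0.0855824 6.46084
0.111926 10.1242
0.14638 15.2222
0.191438 21.6989
0.250367 29.2619
0.327435 37.6385
0.428225 46.3192
0.560042 54.2446
0.732434 60.8255
0.957892 66.1977
1.25275 70.2305
1.63837 72.8799
2.1427 74.5062
2.80226 75.6885
3.66485 76.8582
4.79297 77.7433
6.26834 78.2517
8.19787 78.5605
10.7213 78.906
14.0216 79.3887
18.3377 79.9803
23.9824 80.6051
31.3647 81.1787
41.0194 81.6123
53.646 81.8603
70.1593 81.962
91.7557 81.992
120 81.9986
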