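# element photon data: Si (Z=14)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 14
# A: 28.08550
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 1467.6 0.017998 2.5271 1467.6
1.12202 1082.6 0.021541 2.47 1082.6
1.25893 797.14 0.025535 2.4036 797.14
1.41254 585.84 0.029948 2.328 585.84
1.58489 429.74 0.034725 2.2432 429.74
1.77828 314.61 0.039793 2.1501 314.61
1.83798 287.59 0.041289 2.1221 287.59
1.83982 3345.8 0.041335 2.1212 3345.8
1.99526 2807.9 0.045077 2.0502 2807.9
2.23872 2082.9 0.050521 1.9452 2082.9
2.51189 1545.3 0.056105 1.8371 1545.3
2.81838 1144.2 0.061846 1.7279 1144.2
3.16228 843.08 0.06779 1.6194 843.08
3.54813 618.56 0.073993 1.5126 618.56
3.98107 451.49 0.080487 1.4083 451.49
4.46684 328.32 0.087263 1.3064 328.32
5.01187 238.04 0.094264 1.2062 238.04
5.62341 172.08 0.10139 1.1068 172.08
6.30957 124.03 0.1085 1.0076 124.03
7.07946 89.127 0.11545 0.90836 89.128
7.94328 63.856 0.1221 0.81 63.858
8.91251 45.611 0.1283 0.71402 45.614
10 32.408 0.13392 0.62239 32.411
11.2202 22.989 0.13888 0.5371 22.992
12.5893 16.28 0.14316 0.45967 16.284
14.1254 11.51 0.1468 0.39094 11.514
15.8489 8.124 0.14987 0.33098 8.1288
17.7828 5.7245 0.15244 0.27927 5.7298
19.9526 4.0269 0.15456 0.23501 4.0328
22.3872 2.8279 0.15629 0.19734 2.8346
25.1189 1.9825 0.15766 0.16547 1.99
28.1838 1.3871 0.15868 0.13891 1.3953
31.6228 0.96856 0.15934 0.11677 0.97768
35.4813 0.67528 0.15963 0.098241 0.68535
39.8107 0.47008 0.15952 0.082686 0.48116
44.6684 0.32673 0.15899 0.069598 0.33887
50.1187 0.22674 0.15804 0.058553 0.23998
56.2341 0.15711 0.15666 0.049199 0.17149
63.0957 0.10869 0.15488 0.041252 0.12424
70.7946 0.07508 0.15273 0.034489 0.091806
79.4328 0.051783 0.15022 0.028733 0.069699
89.1251 0.035661 0.14738 0.023849 0.054764
100 0.02452 0.14425 0.019727 0.044797
112.202 0.016835 0.14085 0.01627 0.038258
125.893 0.011541 0.13722 0.013393 0.034072
141.254 0.0079 0.13338 0.011016 0.031489
158.489 0.0053998 0.12938 0.0090618 0.029984
177.828 0.0036855 0.12523 0.0074641 0.029193
199.526 0.0025119 0.12099 0.0061625 0.028863
223.872 0.0017096 0.11667 0.0051053 0.028816
251.189 0.0011619 0.1123 0.0042491 0.028931
281.838 0.00078862 0.10792 0.0035582 0.029123
316.228 0.00053456 0.10355 0.0030036 0.029333
354.813 0.00036188 0.099201 0.0025616 0.029523
398.107 0.00024468 0.094897 0.0022127 0.029665
446.684 0.00016524 0.090652 0.0019402 0.029741
501.187 0.00011146 0.086476 0.0017299 0.029741
562.341 7.5108e-05 0.082379 0.0015692 0.029656
630.957 5.0559e-05 0.078369 0.0014473 0.029483
707.946 3.4001e-05 0.074451 0.0013551 0.029221
794.328 2.2846e-05 0.07063 0.0012847 0.02887
891.251 1.5339e-05 0.066909 0.0012311 0.028432
1000 1.0292e-05 0.063291 0.0011894 0.02791
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 13.9976
0.01 13.9736
0.0130782 13.9566
0.0171039 13.9277
0.0223689 13.8788
0.0292545 13.7964
0.0382596 13.6592
0.0500366 13.4349
0.0654389 13.0791
0.0855824 12.5424
0.111926 11.7933
0.14638 10.8581
0.191438 9.8398
0.250367 8.85578
0.327435 7.92929
0.428225 6.92812
0.560042 5.67669
0.732434 4.22354
0.957892 2.87941
1.25275 1.9635
1.63837 1.47161
2.1427 1.25221
2.80226 1.14672
3.66485 0.994829
4.79297 0.796909
6.26834 0.572749
8.19787 0.36055
10.7213 0.196857
14.0216 0.0940754
18.3377 0.0402925
23.9824 0.0159172
31.3647 0.00595158
41.0194 0.0021481
53.646 0.000758528
70.1593 0.000264324
91.7557 9.13835e-05
120 3.14461e-05
# incoherent scattering function S(x), same x grid
@sf 37
0 0.00479745
0.01 0.0526719
0.0130782 0.0863831
0.0171039 0.143479
0.0223689 0.239501
0.0292545 0.399105
0.0382596 0.65917
0.0500366 1.06912
0.0654389 1.68132
0.0855824 2.52128
0.111926 3.54173
0.14638 4.61888
0.191438 5.67305
0.250367 6.79424
0.327435 8.101
0.428225 9.50337
0.560042 10.7654
0.732434 11.689
0.957892 12.2229
1.25275 12.5598
1.63837 12.8815
2.1427 13.2312
2.80226 13.5548
3.66485 13.7734
4.79297 13.8882
6.26834 13.9456
8.19787 13.9773
10.7213 13.9928
14.0216 13.9983
18.3377 13.9997
23.9824 13.9999
31.3647 14
41.0194 14
53.646 14
70.1593 14
91.7557 14
120 14
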