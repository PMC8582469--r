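# element photon data: Fe (Z=26)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 26
# A: 55.84500
# kedge_keV: 7.1120
# kjump: 8.4160
# kyield: 0.3400
# klines_keV: 6.400 7.058
# klines_w: 0.8800 0.1200
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 8832 0.011773 4.5378 8832
1.12202 6714.6 0.014291 4.4699 6714.6
1.25893 5072.9 0.017234 4.3898 5072.9
1.41254 3809.1 0.020627 4.2968 3809.1
1.58489 2847.8 0.024477 4.1902 2847.8
1.77828 2121.8 0.028778 4.0697 2121.8
1.99526 1575.8 0.033508 3.9354 1575.8
2.23872 1166.6 0.038637 3.7878 1166.6
2.51189 861.03 0.044132 3.6271 861.04
2.81838 633.63 0.049961 3.4535 633.63
3.16228 464.6 0.056092 3.2672 464.6
3.54813 339.63 0.062481 3.0685 339.63
3.98107 247.8 0.06906 2.8586 247.8
4.46684 180.56 0.075729 2.6398 180.56
5.01187 131.38 0.082367 2.4156 131.38
5.62341 95.469 0.088853 2.1903 95.47
6.30957 69.277 0.095084 1.9687 69.278
7.07946 50.199 0.101 1.7554 50.201
7.10844 49.627 0.1012 1.748 49.629
7.11556 418.05 0.10125 1.7462 304.01
7.94328 309.6 0.10657 1.5545 233.95
8.91251 229.41 0.11181 1.3692 179.45
10 168.88 0.11676 1.2014 136.1
11.2202 123.94 0.12144 1.0518 102.5
12.5893 90.653 0.12583 0.91929 76.678
14.1254 66.082 0.1299 0.80193 57.005
15.8489 47.938 0.13359 0.69731 42.071
17.7828 34.675 0.13685 0.60335 30.895
19.9526 25.014 0.13963 0.51857 22.586
22.3872 17.997 0.1419 0.44221 16.443
25.1189 12.913 0.14367 0.37401 11.922
28.1838 9.2359 0.14492 0.31782 8.6074
31.6228 6.5839 0.14566 0.27247 6.1882
35.4813 4.6757 0.14595 0.23497 4.4292
39.8107 3.3164 0.14582 0.2036 3.1649
44.6684 2.3493 0.1453 0.17723 2.2583
50.1187 1.662 0.14443 0.15497 1.6098
56.2341 1.1743 0.14322 0.13608 1.1469
63.0957 0.8286 0.1417 0.11991 0.81734
70.7946 0.58391 0.13985 0.10591 0.58323
79.4328 0.41093 0.13771 0.093613 0.41734
89.1251 0.28881 0.13528 0.082651 0.3001
100 0.20271 0.13258 0.072744 0.21747
112.202 0.14209 0.12962 0.063704 0.15942
125.893 0.099464 0.12644 0.055422 0.11877
141.254 0.069531 0.12306 0.047851 0.090428
158.489 0.048541 0.11952 0.040985 0.070752
177.828 0.033841 0.11582 0.034839 0.057164
199.526 0.023561 0.11202 0.029419 0.047833
223.872 0.016381 0.10813 0.024715 0.041466
251.189 0.011374 0.10418 0.020692 0.037149
281.838 0.0078867 0.10021 0.017292 0.034238
316.228 0.0054611 0.096217 0.014449 0.032279
354.813 0.0037764 0.092239 0.012088 0.030955
398.107 0.0026078 0.08829 0.010139 0.030044
446.684 0.0017984 0.084385 0.0085388 0.029392
501.187 0.0012385 0.080536 0.0072292 0.02889
562.341 0.0008518 0.076753 0.0061613 0.028464
630.957 0.00058502 0.073043 0.005292 0.028063
707.946 0.00040126 0.069413 0.0045899 0.027653
794.328 0.00027484 0.065867 0.0040162 0.027211
891.251 0.000188 0.062411 0.0035621 0.026724
1000 0.00012842 0.059049 0.0031922 0.026183
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 25.9904
0.01 25.9615
0.0130782 25.9411
0.0171039 25.9063
0.0223689 25.8473
0.0292545 25.7479
0.0382596 25.5818
0.0500366 25.309
0.0654389 24.8726
0.0855824 24.2037
0.111926 23.2395
0.14638 21.9525
0.191438 20.3411
0.250367 18.3505
0.327435 15.8998
0.428225 13.1178
0.560042 10.3907
0.732434 8.19247
0.957892 6.73613
1.25275 5.58655
1.63837 4.26243
2.1427 3.1745
2.80226 3.09116
3.66485 2.95604
4.79297 2.74462
6.26834 2.43214
8.19787 2.00891
10.7213 1.50349
14.0216 0.992623
18.3377 0.569135
23.9824 0.284143
31.3647 0.125972
41.0194 0.0510059
53.646 0.0193863
70.1593 0.00706991
91.7557 0.0025124
120 0.000878843
# incoherent scattering function S(x), same x grid
@sf 37
0 0.0191936
0.01 0.0768756
0.0130782 0.117611
0.0171039 0.18683
0.0223689 0.303916
0.0292545 0.500422
0.0382596 0.825924
0.0500366 1.35349
0.0654389 2.17881
0.0855824 3.40046
0.111926 5.06942
0.14638 7.13234
0.191438 9.46011
0.250367 11.9647
0.327435 14.5225
0.428225 16.8154
0.560042 18.6401
0.732434 20.1689
0.957892 21.6294
1.25275 22.9031
1.63837 23.8059
2.1427 24.3545
2.80226 24.6822
3.66485 24.9827
4.79297 25.2921
6.26834 25.5604
8.19787 25.7509
10.7213 25.8726
14.0216 25.9454
18.3377 25.9819
23.9824 25.9954
31.3647 25.9991
41.0194 25.9998
53.646 26
70.1593 26
91.7557 26
120 26
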