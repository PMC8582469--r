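# element photon data: I (Z=53)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 53
# A: 126.90447
# kedge_keV: 33.1694
# kjump: 6.1662
# kyield: 0.8840
# klines_keV: 28.612 28.317 32.295 33.042
# klines_w: 0.5200 0.2800 0.1700 0.0300
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 69
1 8823.8 0.0084146 8.4174 8823.8
1.12202 7200.2 0.010334 8.3138 7200.2
1.25893 5591.9 0.012623 8.1899 5591.9
1.41254 4321.7 0.015321 8.0433 4321.7
1.58489 3320.1 0.018459 7.8719 3320.1
1.77828 2535.8 0.022054 7.6746 2535.8
1.99526 1928.8 0.026108 7.4507 1928.8
2.23872 1461.1 0.030598 7.201 1461.1
2.51189 1102.5 0.035485 6.927 1102.5
2.81838 828.8 0.040712 6.6312 828.8
3.16228 620.63 0.046212 6.3167 620.63
3.54813 463.19 0.051917 5.9868 463.19
3.98107 344.66 0.057762 5.6442 344.66
4.46684 255.96 0.063691 5.2917 255.96
4.55482 243.34 0.0647 5.2311 243.34
4.55938 794.29 0.064752 5.228 794.29
4.84967 656.75 0.067949 5.0348 656.75
4.85453 912.44 0.068001 5.0316 912.44
5.01187 832.66 0.069654 4.931 832.66
5.18551 758.66 0.071418 4.8231 758.66
5.19069 873.3 0.071469 4.8199 873.3
5.62341 713.41 0.075602 4.5645 713.41
6.30957 531.41 0.081468 4.195 531.42
7.07946 394.17 0.087168 3.8273 394.17
7.94328 291.44 0.092599 3.4676 291.44
8.91251 214.85 0.097666 3.1226 214.85
10 157.79 0.1023 2.7981 157.79
11.2202 115.59 0.10648 2.4974 115.59
12.5893 84.526 0.11021 2.2212 84.529
14.1254 61.715 0.11354 1.9676 61.718
15.8489 44.99 0.11651 1.7336 44.994
17.7828 32.745 0.11917 1.5167 32.749
19.9526 23.794 0.12151 1.3158 23.799
22.3872 17.261 0.12354 1.1312 17.266
25.1189 12.504 0.12524 0.96426 12.51
28.1838 9.035 0.12655 0.82679 9.0416
31.6228 6.5134 0.12748 0.71619 6.5207
33.1528 5.6943 0.12775 0.67661 5.702
33.186 35.138 0.12776 0.67581 12.178
35.4813 29.475 0.12803 0.62473 11.463
39.8107 21.754 0.12819 0.54837 9.9094
44.6684 16.002 0.12796 0.48452 8.2408
50.1187 11.731 0.12735 0.43124 6.6646
56.2341 8.575 0.12636 0.38682 5.2789
63.0957 6.249 0.12503 0.34978 4.1132
70.7946 4.5387 0.12338 0.31876 3.1615
79.4328 3.2882 0.12144 0.29255 2.4047
89.1251 2.3681 0.11925 0.2701 1.8072
100 1.7047 0.11683 0.25047 1.3513
112.202 1.2269 0.11421 0.23287 1.0071
125.893 0.88292 0.11141 0.21662 0.74914
141.254 0.63527 0.10845 0.20117 0.55696
158.489 0.457 0.10537 0.1861 0.41456
177.828 0.3287 0.10217 0.17112 0.30952
199.526 0.23638 0.098881 0.15609 0.23233
223.872 0.16996 0.095526 0.14099 0.17582
251.189 0.12219 0.092124 0.12597 0.13455
281.838 0.087826 0.088694 0.11124 0.1045
316.228 0.063119 0.085252 0.097115 0.082656
354.813 0.045357 0.081814 0.083877 0.066794
398.107 0.03259 0.078393 0.071772 0.055277
446.684 0.023415 0.075 0.060952 0.046903
501.187 0.016821 0.071646 0.051472 0.040791
562.341 0.012084 0.068341 0.043297 0.0363
630.957 0.0086805 0.06509 0.03633 0.03296
707.946 0.0062357 0.061901 0.030454 0.030433
794.328 0.0044796 0.05878 0.025511 0.028475
891.251 0.0032182 0.05573 0.021412 0.026907
1000 0.0023122 0.052757 0.017997 0.025605
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 53.0006
0.01 52.9551
0.0130782 52.9229
0.0171039 52.868
0.0223689 52.7747
0.0292545 52.6167
0.0382596 52.3509
0.0500366 51.9093
0.0654389 51.1895
0.0855824 50.0531
0.111926 48.3449
0.14638 45.9539
0.191438 42.8946
0.250367 39.3117
0.327435 35.3314
0.428225 30.9078
0.560042 26.0791
0.732434 21.5078
0.957892 17.8305
1.25275 14.5328
1.63837 10.895
2.1427 8.19281
2.80226 8.14012
3.66485 8.05118
4.79297 7.9024
6.26834 7.65732
8.19787 7.26378
10.7213 6.65763
14.0216 5.78343
18.3377 4.6416
23.9824 3.34418
31.3647 2.11116
41.0194 1.15595
53.646 0.55379
70.1593 0.237645
91.7557 0.094007
120 0.0351815
# incoherent scattering function S(x), same x grid
@sf 37
0 1e-12
0.01 0.0896904
0.0130782 0.153992
0.0171039 0.263513
0.0223689 0.449395
0.0292545 0.763256
0.0382596 1.28841
0.0500366 2.15391
0.0654389 3.54513
0.0855824 5.69307
0.111926 8.80942
0.14638 12.9459
0.191438 17.8563
0.250367 23.066
0.327435 28.1795
0.428225 33.0492
0.560042 37.4245
0.732434 40.7582
0.957892 43.0664
1.25275 45.0217
1.63837 46.9475
2.1427 48.5846
2.80226 49.7364
3.66485 50.4536
4.79297 50.8291
6.26834 51.1079
8.19787 51.4378
10.7213 51.8193
14.0216 52.1919
18.3377 52.5103
23.9824 52.7514
31.3647 52.901
41.0194 52.9702
53.646 52.9931
70.1593 52.9987
91.7557 52.9998
120 53
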