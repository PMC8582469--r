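# element photon data: Mo (Z=42)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 42
# A: 95.95000
# kedge_keV: 19.9995
# kjump: 6.8643
# kyield: 0.7640
# klines_keV: 17.443 19.646
# klines_w: 0.8400 0.1600
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 69
1 4741.5 0.0098287 6.9478 4741.5
1.12202 3637.3 0.011954 6.8565 3637.3
1.25893 2782 0.014474 6.7478 2782
1.41254 2121.4 0.017423 6.62 2121.4
1.58489 1612.6 0.020827 6.4716 1612.6
1.77828 1220.3 0.024696 6.3018 1220.3
1.99526 920.82 0.029022 6.1105 920.82
2.23872 692.93 0.03378 5.8982 692.93
2.51189 520.07 0.038931 5.6661 520.07
2.51894 516.43 0.039061 5.6602 516.43
2.52146 1967.5 0.039107 5.6581 1967.5
2.62379 1755.6 0.040974 5.5733 1755.6
2.62641 2440.4 0.041022 5.5712 2440.4
2.81838 2023.9 0.044428 5.4155 2023.9
2.86407 1941.4 0.045221 5.3791 1941.4
2.86693 2226.1 0.04527 5.3769 2226.1
3.16228 1740.3 0.05022 5.1481 1740.3
3.54813 1300.3 0.056248 4.8657 1300.3
3.98107 968.29 0.06244 4.5708 968.29
4.46684 718.56 0.068702 4.2672 718.56
5.01187 531.57 0.074921 3.9597 531.57
5.62341 391.73 0.080978 3.654 391.73
6.30957 287.84 0.086778 3.3552 287.84
7.07946 211.03 0.092262 3.0669 211.04
7.94328 154.39 0.097419 2.7901 154.39
8.91251 112.71 0.10227 2.5242 112.71
10 82.052 0.10684 2.2679 82.054
11.2202 59.647 0.11114 2.0206 59.65
12.5893 43.263 0.11515 1.7833 43.266
14.1254 31.329 0.11886 1.5587 31.332
15.8489 22.67 0.12221 1.3503 22.674
17.7828 16.391 0.1252 1.161 16.395
19.9526 11.84 0.12782 0.99272 11.845
19.9895 11.779 0.12786 0.99019 11.784
20.0095 80.921 0.12788 0.98883 33.953
22.3872 59.711 0.13007 0.84586 28.737
25.1189 44.082 0.13195 0.71943 23.705
28.1838 32.389 0.13343 0.61496 19.048
31.6228 23.703 0.13448 0.52908 15.005
35.4813 17.297 0.13508 0.45758 11.644
39.8107 12.586 0.13523 0.39788 8.9235
44.6684 9.1177 0.13494 0.34809 6.7572
50.1187 6.5891 0.13424 0.30663 5.0734
56.2341 4.7504 0.13316 0.27211 3.7815
63.0957 3.4165 0.13174 0.24328 2.8009
70.7946 2.4513 0.13 0.21904 2.0634
79.4328 1.7544 0.12798 0.19841 1.5132
89.1251 1.2529 0.1257 0.18056 1.1059
100 0.89408 0.12319 0.16478 0.80759
112.202 0.63764 0.12046 0.15048 0.59001
125.893 0.45445 0.11753 0.13722 0.4319
141.254 0.32369 0.11443 0.12463 0.31739
158.489 0.2304 0.11118 0.11252 0.23474
177.828 0.16389 0.1078 0.10077 0.17525
199.526 0.1165 0.10432 0.089397 0.13257
223.872 0.082762 0.10077 0.078501 0.10202
251.189 0.058756 0.097155 0.068224 0.080204
281.838 0.041686 0.093509 0.05872 0.064663
316.228 0.029557 0.089849 0.050115 0.053605
354.813 0.020944 0.086192 0.04248 0.045738
398.107 0.014832 0.082555 0.035826 0.04013
446.684 0.010498 0.07895 0.030112 0.036112
501.187 0.0074254 0.07539 0.025262 0.033205
562.341 0.0052493 0.071885 0.021183 0.031064
630.957 0.003709 0.068441 0.01778 0.029445
707.946 0.0026192 0.065066 0.014962 0.028174
794.328 0.0018487 0.061766 0.012635 0.027128
891.251 0.0013042 0.058545 0.010735 0.026221
1000 0.00091967 0.055407 0.0091781 0.025393
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 41.9561
0.01 41.9169
0.0130782 41.8892
0.0171039 41.8419
0.0223689 41.7617
0.0292545 41.6259
0.0382596 41.398
0.0500366 41.0207
0.0654389 40.4093
0.0855824 39.4527
0.111926 38.0346
0.14638 36.083
0.191438 33.6109
0.250367 30.6617
0.327435 27.2727
0.428225 23.7178
0.560042 20.4128
0.732434 17.1883
0.957892 13.5651
1.25275 9.87106
1.63837 7.05671
2.1427 5.81349
2.80226 5.75411
3.66485 5.65464
4.79297 5.49039
6.26834 5.22558
8.19787 4.81506
10.7213 4.21703
14.0216 3.42425
18.3377 2.50517
23.9824 1.60991
31.3647 0.89757
41.0194 0.436924
53.646 0.189848
70.1593 0.0757656
91.7557 0.0285207
120 0.0103377
# incoherent scattering function S(x), same x grid
@sf 37
0 0.0877388
0.01 0.165923
0.0130782 0.221222
0.0171039 0.315334
0.0223689 0.474909
0.0292545 0.743903
0.0382596 1.19273
0.0500366 1.92896
0.0654389 3.10325
0.0855824 4.8941
0.111926 7.44549
0.14638 10.7554
0.191438 14.6163
0.250367 18.7446
0.327435 22.8636
0.428225 26.5058
0.560042 29.3583
0.732434 31.7539
0.957892 34.0146
1.25275 35.9738
1.63837 37.5734
2.1427 38.8762
2.80226 39.7123
3.66485 40.1493
4.79297 40.4373
6.26834 40.743
8.19787 41.0797
10.7213 41.3909
14.0216 41.6376
18.3377 41.8144
23.9824 41.9239
31.3647 41.9762
41.0194 41.9943
53.646 41.9989
70.1593 41.9998
91.7557 42
120 42
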