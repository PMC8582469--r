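# element photon data: Ti (Z=22)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 22
# A: 47.86700
# kedge_keV: 4.9664
# kjump: 9.0146
# kyield: 0.2140
# klines_keV: 4.511 4.932
# klines_w: 0.8800 0.1200
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 5635.8 0.015803 3.693 5635.8
1.12202 4220.9 0.018927 3.62 4220.9
1.25893 3151.3 0.022468 3.5362 3151.3
1.41254 2345.5 0.026414 3.4416 2345.5
1.58489 1740.5 0.030738 3.3364 1740.5
1.77828 1287.8 0.035403 3.2211 1287.8
1.99526 949.59 0.040366 3.0961 949.59
2.23872 698.45 0.045593 2.962 698.45
2.51189 512.45 0.051052 2.8189 512.45
2.81838 375.27 0.056715 2.667 375.27
3.16228 274.02 0.062543 2.5068 274.02
3.54813 199.55 0.068483 2.339 199.55
3.98107 145.13 0.074465 2.1653 145.13
4.46684 105.41 0.08041 1.9882 105.42
4.96392 78.546 0.085764 1.8254 78.547
4.96888 708.66 0.085815 1.8239 584.88
5.01187 691.2 0.086246 1.8106 571.51
5.62341 508.72 0.091915 1.6364 430.21
6.30957 377.13 0.097394 1.4692 325.26
7.07946 278.24 0.10269 1.3125 244.13
7.94328 204.45 0.10783 1.1686 182.12
8.91251 149.64 0.11283 1.0382 135.07
10 109.06 0.11766 0.92086 99.599
11.2202 79.108 0.12227 0.8148 72.992
12.5893 57.227 0.12658 0.71806 53.285
14.1254 41.291 0.13052 0.62903 38.758
15.8489 29.715 0.13402 0.54678 28.092
17.7828 21.327 0.13704 0.47106 20.291
19.9526 15.267 0.13955 0.40211 14.608
22.3872 10.897 0.14154 0.34031 10.481
25.1189 7.7587 0.14304 0.28602 7.4974
28.1838 5.5056 0.14409 0.24145 5.3436
31.6228 3.895 0.14471 0.20522 3.7964
35.4813 2.7517 0.14493 0.17507 2.6936
39.8107 1.9413 0.14478 0.14975 1.909
44.6684 1.3676 0.14429 0.1284 1.3521
50.1187 0.96207 0.14345 0.11037 0.95744
56.2341 0.67582 0.14228 0.095088 0.67846
63.0957 0.47406 0.14078 0.082061 0.48168
70.7946 0.33205 0.13896 0.070871 0.34321
79.4328 0.23224 0.13682 0.061173 0.24605
89.1251 0.16219 0.13438 0.052694 0.17807
100 0.11311 0.13166 0.04523 0.13068
112.202 0.078763 0.12868 0.038638 0.097784
125.893 0.054765 0.12548 0.032824 0.075055
141.254 0.038023 0.12208 0.027725 0.059447
158.489 0.02636 0.11851 0.023294 0.048806
177.828 0.018248 0.1148 0.019487 0.041613
199.526 0.012613 0.11099 0.016255 0.036802
223.872 0.0087053 0.1071 0.01354 0.033623
251.189 0.0059994 0.10315 0.011281 0.031549
281.838 0.0041284 0.099176 0.0094151 0.030214
316.228 0.0028367 0.095199 0.0078841 0.029361
354.813 0.0019462 0.091239 0.0066338 0.028812
398.107 0.0013333 0.087311 0.0056163 0.028444
446.684 0.00091207 0.083431 0.0047899 0.02817
501.187 0.00062298 0.07961 0.0041201 0.027933
562.341 0.00042489 0.075856 0.0035786 0.027693
630.957 0.00028935 0.072178 0.0031417 0.027422
707.946 0.00019676 0.068581 0.0027935 0.027104
794.328 0.0001336 0.065071 0.0025129 0.026729
891.251 9.0576e-05 0.06165 0.002296 0.026289
1000 6.1318e-05 0.058323 0.0021222 0.025784
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 21.9972
0.01 21.9612
0.0130782 21.9358
0.0171039 21.8926
0.0223689 21.8197
0.0292545 21.6977
0.0382596 21.4967
0.0500366 21.1732
0.0654389 20.6732
0.0855824 19.9452
0.111926 18.9674
0.14638 17.7564
0.191438 16.3096
0.250367 14.5592
0.327435 12.4959
0.428225 10.3076
0.560042 8.40069
0.732434 7.05057
0.957892 5.93723
1.25275 4.6369
1.63837 3.20268
2.1427 2.26084
2.80226 2.17886
3.66485 2.04861
4.79297 1.85141
6.26834 1.57442
8.19787 1.22621
10.7213 0.850192
14.0216 0.513933
18.3377 0.26964
23.9824 0.124527
31.3647 0.0519634
41.0194 0.0201588
53.646 0.00744895
70.1593 0.00266873
91.7557 0.000938138
120 0.000326032
# incoherent scattering function S(x), same x grid
@sf 37
0 0.00559932
0.01 0.077532
0.0130782 0.12817
0.0171039 0.213894
0.0223689 0.357991
0.0292545 0.597265
0.0382596 0.98664
0.0500366 1.5996
0.0654389 2.5151
0.0855824 3.77924
0.111926 5.35256
0.14638 7.11282
0.191438 8.96426
0.250367 10.8723
0.327435 12.72
0.428225 14.3548
0.560042 15.8155
0.732434 17.2675
0.957892 18.6005
1.25275 19.5968
1.63837 20.224
2.1427 20.6215
2.80226 20.9551
3.66485 21.2795
4.79297 21.566
6.26834 21.7672
8.19787 21.8842
10.7213 21.9482
14.0216 21.9811
18.3377 21.9947
23.9824 21.9989
31.3647 21.9998
41.0194 22
53.646 22
70.1593 22
91.7557 22
120 22
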