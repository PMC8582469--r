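# element photon data: N (Z=7)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 7
# A: 14.00670
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 61
1 3169.3 0.015559 1.2908 3169.3
1.12202 2312.2 0.019079 1.2654 2312.2
1.25893 1681.7 0.02329 1.2347 1681.7
1.41254 1219.3 0.028266 1.198 1219.3
1.58489 881.38 0.034061 1.1549 881.38
1.77828 634.39 0.040692 1.1049 634.39
1.99526 455.39 0.048123 1.0479 455.39
2.23872 326.08 0.05625 0.98435 326.08
2.51189 232.9 0.064899 0.91502 232.9
2.81838 165.93 0.073827 0.84136 165.93
3.16228 117.84 0.082753 0.76523 117.84
3.54813 83.43 0.091395 0.68872 83.43
3.98107 58.943 0.099514 0.61392 58.944
4.46684 41.555 0.10695 0.54261 41.556
5.01187 29.235 0.11363 0.47615 29.236
5.62341 20.524 0.11958 0.41546 20.525
6.30957 14.378 0.12486 0.361 14.38
7.07946 10.051 0.12961 0.31288 10.053
7.94328 7.0109 0.13394 0.2709 7.0131
8.91251 4.8808 0.13797 0.23453 4.8833
10 3.3831 0.14177 0.20306 3.386
11.2202 2.3429 0.14541 0.17571 2.3462
12.5893 1.621 0.14888 0.15177 1.6248
14.1254 1.1205 0.15219 0.13065 1.1248
15.8489 0.77386 0.15529 0.11194 0.77871
17.7828 0.53396 0.15811 0.095357 0.53944
19.9526 0.36809 0.16058 0.080691 0.37426
22.3872 0.25352 0.16263 0.067802 0.26044
25.1189 0.17445 0.1642 0.056573 0.18218
28.1838 0.11973 0.16524 0.047185 0.12831
31.6228 0.081987 0.16575 0.039369 0.091481
35.4813 0.056137 0.16572 0.032759 0.066584
39.8107 0.038433 0.16519 0.027147 0.049878
44.6684 0.026309 0.16419 0.022394 0.038793
50.1187 0.018008 0.16275 0.01839 0.031568
56.2341 0.012324 0.16089 0.015042 0.026995
63.0957 0.0084334 0.15866 0.012262 0.024241
70.7946 0.0057703 0.15607 0.0099699 0.022734
79.4328 0.0039477 0.15317 0.0080907 0.022077
89.1251 0.0027004 0.14997 0.006558 0.021994
100 0.001847 0.1465 0.0053138 0.022294
112.202 0.0012631 0.14281 0.0043085 0.022838
125.893 0.00086372 0.13891 0.0035002 0.023531
141.254 0.00059054 0.13484 0.0028541 0.024302
158.489 0.00040371 0.13064 0.0023408 0.0251
177.828 0.00027596 0.12632 0.0019356 0.025887
199.526 0.0001886 0.12193 0.0016178 0.026637
223.872 0.00012889 0.11748 0.0013698 0.027328
251.189 8.8068e-05 0.11301 0.001177 0.027946
281.838 6.0169e-05 0.10854 0.0010277 0.02848
316.228 4.1103e-05 0.10409 0.00091228 0.028924
354.813 2.8075e-05 0.099676 0.00082305 0.029272
398.107 1.9174e-05 0.095318 0.00075395 0.02952
446.684 1.3093e-05 0.091027 0.00070012 0.029669
501.187 8.9398e-06 0.086813 0.000658 0.029717
562.341 6.1033e-06 0.082684 0.00062498 0.029665
630.957 4.1662e-06 0.078645 0.00059912 0.029514
707.946 2.8436e-06 0.074703 0.00057933 0.029266
794.328 1.9406e-06 0.07086 0.00056371 0.028924
891.251 1.3242e-06 0.067119 0.00055258 0.028491
1000 9.0352e-07 0.063485 0.00054387 0.027973
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 6.9946
0.01 6.9856
0.0130782 6.97922
0.0171039 6.96833
0.0223689 6.94977
0.0292545 6.91822
0.0382596 6.86483
0.0500366 6.77517
0.0654389 6.62646
0.0855824 6.3851
0.111926 6.00713
0.14638 5.449
0.191438 4.6977
0.250367 3.81526
0.327435 2.94609
0.428225 2.23928
0.560042 1.77421
0.732434 1.51508
0.957892 1.30361
1.25275 1.04228
1.63837 0.742304
2.1427 0.492545
2.80226 0.368227
3.66485 0.242791
4.79297 0.139017
6.26834 0.0693176
8.19787 0.0307004
10.7213 0.0124214
14.0216 0.00471882
18.3377 0.00172035
23.9824 0.000611234
31.3647 0.000213787
41.0194 7.40743e-05
53.646 2.5523e-05
70.1593 8.7653e-06
91.7557 3.00443e-06
120 1.02864e-06
# incoherent scattering function S(x), same x grid
@sf 37
0 0.0107955
0.01 0.0287601
0.0130782 0.0414752
0.0171039 0.063146
0.0223689 0.0999689
0.0292545 0.162248
0.0382596 0.266753
0.0500366 0.439774
0.0654389 0.719789
0.0855824 1.15592
0.111926 1.79335
0.14638 2.63357
0.191438 3.57639
0.250367 4.4153
0.327435 4.97847
0.428225 5.29055
0.560042 5.51431
0.732434 5.7825
0.957892 6.11465
1.25275 6.4588
1.63837 6.73722
2.1427 6.90242
2.80226 6.96931
3.66485 6.99055
4.79297 6.99722
6.26834 6.99931
8.19787 6.99986
10.7213 6.99998
14.0216 7
18.3377 7
23.9824 7
31.3647 7
41.0194 7
53.646 7
70.1593 7
91.7557 7
120 7
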