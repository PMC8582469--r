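# element photon data: C (Z=6)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 6
# A: 12.01070
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 61
1 2072.6 0.019855 1.0789 2072.6
1.12202 1501.9 0.024209 1.0515 1501.9
1.25893 1082.9 0.029312 1.0189 1082.9
1.41254 778.63 0.035199 0.98089 778.63
1.58489 558.46 0.041862 0.93709 558.46
1.77828 399.54 0.049236 0.88759 399.54
1.99526 285.13 0.057192 0.83283 285.13
2.23872 202.97 0.065538 0.77366 202.98
2.51189 144.13 0.074029 0.71132 144.13
2.81838 102.08 0.0824 0.64738 102.08
3.16228 72.091 0.090404 0.58353 72.091
3.54813 50.77 0.097847 0.52144 50.77
3.98107 35.679 0.10462 0.46257 35.68
4.46684 25.021 0.1107 0.40802 25.023
5.01187 17.51 0.11616 0.3585 17.512
5.62341 12.222 0.12111 0.31431 12.223
6.30957 8.5106 0.12568 0.27534 8.5123
7.07946 5.9175 0.12999 0.2412 5.9194
7.94328 4.1082 0.13416 0.21135 4.1104
8.91251 2.8477 0.13822 0.18516 2.8502
10 1.9651 0.14221 0.16202 1.968
11.2202 1.355 0.14613 0.14138 1.3583
12.5893 0.93366 0.14994 0.12282 0.93746
14.1254 0.64286 0.15356 0.10603 0.64718
15.8489 0.4423 0.15691 0.090834 0.44722
17.7828 0.30409 0.1599 0.077164 0.30965
19.9526 0.20891 0.16243 0.065009 0.21517
22.3872 0.14342 0.16445 0.054371 0.15043
25.1189 0.098386 0.16591 0.045224 0.1062
28.1838 0.067307 0.16679 0.03759 0.075971
31.6228 0.04594 0.16712 0.031203 0.0555
35.4813 0.031363 0.16692 0.025806 0.041864
39.8107 0.021415 0.16622 0.021248 0.032904
44.6684 0.014626 0.16507 0.017417 0.027144
50.1187 0.0099909 0.16349 0.01422 0.023578
56.2341 0.0068263 0.16152 0.011571 0.021516
63.0957 0.004665 0.15918 0.0093904 0.020486
70.7946 0.0031886 0.1565 0.0076062 0.020161
79.4328 0.0021799 0.15351 0.0061536 0.020314
89.1251 0.0014906 0.15024 0.0049765 0.020786
100 0.0010195 0.14672 0.004027 0.021465
112.202 0.00069741 0.14297 0.0032649 0.022269
125.893 0.00047718 0.13904 0.0026562 0.023139
141.254 0.00032656 0.13493 0.0021729 0.024031
158.489 0.00022352 0.1307 0.0017912 0.024912
177.828 0.00015303 0.12636 0.0014914 0.025756
199.526 0.00010479 0.12195 0.001257 0.026543
223.872 7.1769e-05 0.11749 0.0010744 0.027261
251.189 4.9164e-05 0.11301 0.00093244 0.027896
281.838 3.3686e-05 0.10853 0.00082211 0.028443
316.228 2.3085e-05 0.10408 0.00073622 0.028894
354.813 1.5824e-05 0.09966 0.00066919 0.029247
398.107 1.0848e-05 0.0953 0.00061677 0.0295
446.684 7.439e-06 0.091007 0.0005757 0.029651
501.187 5.1021e-06 0.086791 0.00054357 0.029701
562.341 3.5001e-06 0.082661 0.00051854 0.02965
630.957 2.4015e-06 0.078622 0.0004992 0.0295
707.946 1.6481e-06 0.074679 0.00048464 0.029253
794.328 1.1313e-06 0.070835 0.00047363 0.028911
891.251 7.7672e-07 0.067095 0.00046596 0.028479
1000 5.3338e-07 0.063461 0.00046041 0.027961
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 5.9992
0.01 5.9888
0.0130782 5.98144
0.0171039 5.96888
0.0223689 5.94752
0.0292545 5.91131
0.0382596 5.85035
0.0500366 5.74882
0.0654389 5.58281
0.0855824 5.3196
0.111926 4.92252
0.14638 4.36849
0.191438 3.67951
0.250367 2.94587
0.327435 2.30229
0.428225 1.8544
0.560042 1.58953
0.732434 1.3908
0.957892 1.15843
1.25275 0.866333
1.63837 0.56078
2.1427 0.352025
2.80226 0.244657
3.66485 0.148283
4.79297 0.0779964
6.26834 0.0360982
8.19787 0.0150875
10.7213 0.00585961
14.0216 0.00216676
18.3377 0.00077663
23.9824 0.000273083
31.3647 9.49201e-05
41.0194 3.2767e-05
53.646 1.12655e-05
70.1593 3.86392e-06
91.7557 1.32341e-06
120 4.52904e-07
# incoherent scattering function S(x), same x grid
@sf 37
0 0.00160011
0.01 0.0223636
0.0130782 0.0370416
0.0171039 0.0620046
0.0223689 0.104298
0.0292545 0.175465
0.0382596 0.293856
0.0500366 0.487015
0.0654389 0.792047
0.0855824 1.24837
0.111926 1.87364
0.14638 2.62047
0.191438 3.34983
0.250367 3.89743
0.327435 4.21852
0.428225 4.42836
0.560042 4.66686
0.732434 4.97724
0.957892 5.32544
1.25275 5.63875
1.63837 5.85072
2.1427 5.95303
2.80226 5.98668
3.66485 5.99617
4.79297 5.99899
6.26834 5.99978
8.19787 5.99996
10.7213 5.99999
14.0216 6
18.3377 6
23.9824 6
31.3647 6
41.0194 6
53.646 6
70.1593 6
91.7557 6
120 6
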