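# element photon data: Ca (Z=20)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 20
# A: 40.07800
# kedge_keV: 4.0381
# kjump: 9.4560
# kyield: 0.1630
# klines_keV: 3.691 4.013
# klines_w: 0.8800 0.1200
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 4662.5 0.020047 3.5819 4662.5
1.12202 3476.2 0.023717 3.5022 3476.2
1.25893 2584.1 0.02778 3.4128 2584.1
1.41254 1915.2 0.032202 3.3139 1915.2
1.58489 1414.4 0.036941 3.206 1414.4
1.77828 1042.1 0.041953 3.0899 1042.1
1.99526 765.87 0.047205 2.9657 765.87
2.23872 561.78 0.052674 2.8338 561.78
2.51189 411.32 0.058344 2.6939 411.32
2.81838 300.61 0.064203 2.5459 300.61
3.16228 219.1 0.070224 2.3898 219.1
3.54813 159.28 0.07636 2.2265 159.28
3.98107 115.64 0.082542 2.0577 115.64
4.03608 111.3 0.083279 2.0373 111.3
4.04012 1053.4 0.083332 2.0358 911.62
4.46684 804.27 0.088694 1.8865 706.39
5.01187 596.91 0.094753 1.7168 532.17
5.62341 441.14 0.10069 1.5528 398.5
6.30957 324.7 0.10653 1.3981 296.73
7.07946 238.06 0.11229 1.2551 219.78
7.94328 173.85 0.11797 1.1243 161.95
8.91251 126.45 0.12354 1.0052 118.74
10 91.525 0.12891 0.89581 86.552
11.2202 66.078 0.134 0.79438 62.88
12.5893 47.586 0.1387 0.69952 45.535
14.1254 34.181 0.14293 0.61066 32.87
15.8489 24.49 0.14664 0.52797 23.654
17.7828 17.498 0.14978 0.45207 16.968
19.9526 12.461 0.15235 0.3837 12.128
22.3872 8.8576 0.15438 0.32339 8.6491
25.1189 6.2839 0.15589 0.27129 6.1553
28.1838 4.4404 0.15695 0.22844 4.3629
31.6228 3.1267 0.15758 0.1933 3.082
35.4813 2.1994 0.15782 0.16397 2.1757
39.8107 1.5456 0.15767 0.13931 1.5354
44.6684 1.085 0.15715 0.11854 1.0838
50.1187 0.76091 0.15626 0.10102 0.76575
56.2341 0.53308 0.155 0.086198 0.54216
63.0957 0.37307 0.15337 0.073614 0.38527
70.7946 0.26083 0.15137 0.062862 0.27542
79.4328 0.18216 0.14902 0.053614 0.19872
89.1251 0.12709 0.14634 0.045615 0.14532
100 0.088572 0.14335 0.038669 0.10829
112.202 0.061664 0.14008 0.032636 0.082725
125.893 0.042885 0.13656 0.027415 0.065182
141.254 0.029794 0.13283 0.022926 0.053231
158.489 0.020677 0.12892 0.019102 0.045165
177.828 0.014335 0.12487 0.015875 0.039784
199.526 0.009927 0.1207 0.013179 0.036246
223.872 0.0068674 0.11644 0.010947 0.03396
251.189 0.0047457 0.11213 0.0091127 0.032514
281.838 0.003276 0.1078 0.0076136 0.031618
316.228 0.0022591 0.10346 0.0063939 0.031072
354.813 0.0015561 0.099144 0.0054047 0.030737
398.107 0.0010708 0.094866 0.004604 0.030514
446.684 0.00073603 0.090642 0.0039565 0.030338
501.187 0.00050538 0.086483 0.0034343 0.030162
562.341 0.00034664 0.082399 0.0030148 0.029956
630.957 0.00023751 0.078399 0.0026798 0.0297
707.946 0.00016256 0.074488 0.0024159 0.02938
794.328 0.00011114 0.070671 0.0022067 0.028988
891.251 7.5907e-05 0.066953 0.0020474 0.028522
1000 5.1787e-05 0.063338 0.0019222 0.027981
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 20
0.01 19.9589
0.0130782 19.9299
0.0171039 19.8809
0.0223689 19.7986
0.0292545 19.662
0.0382596 19.4397
0.0500366 19.0901
0.0654389 18.5678
0.0855824 17.843
0.111926 16.9227
0.14638 15.8313
0.191438 14.5396
0.250367 12.9535
0.327435 11.074
0.428225 9.19169
0.560042 7.70745
0.732434 6.59185
0.957892 5.40771
1.25275 3.99759
1.63837 2.63171
2.1427 1.887
2.80226 1.8049
3.66485 1.67638
4.79297 1.48631
6.26834 1.22863
8.19787 0.920483
10.7213 0.60848
14.0216 0.349344
18.3377 0.174623
23.9824 0.0774934
31.3647 0.0313992
41.0194 0.0119399
53.646 0.00435562
70.1593 0.00154812
91.7557 0.000541599
120 0.000187683
# incoherent scattering function S(x), same x grid
@sf 37
0 1e-12
0.01 0.0820886
0.0130782 0.139672
0.0171039 0.23678
0.0223689 0.398934
0.0292545 0.665263
0.0382596 1.09092
0.0500366 1.74195
0.0654389 2.67272
0.0855824 3.88292
0.111926 5.28986
0.14638 6.78573
0.191438 8.34192
0.250367 9.97112
0.327435 11.5739
0.428225 13.0314
0.560042 14.4545
0.732434 15.8781
0.957892 17.0755
1.25275 17.9006
1.63837 18.3958
2.1427 18.7518
2.80226 19.0957
3.66485 19.421
4.79297 19.6799
6.26834 19.841
8.19787 19.9258
10.7213 19.9692
14.0216 19.9898
18.3377 19.9974
23.9824 19.9995
31.3647 19.9999
41.0194 20
53.646 20
70.1593 20
91.7557 20
120 20
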