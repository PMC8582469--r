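# element photon data: Na (Z=11)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 11
# A: 22.98977
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 596.96 0.01522 1.9208 596.96
1.07156 495.31 0.016778 1.8998 495.31
1.07264 5584.5 0.016801 1.8995 5584.5
1.12202 6723.8 0.017876 1.8849 6723.8
1.25893 5024.3 0.020852 1.8445 5024.3
1.41254 3711.1 0.024179 1.7998 3711.1
1.58489 2762.6 0.027903 1.751 2762.6
1.77828 2047.3 0.032085 1.6984 2047.3
1.99526 1510.4 0.036787 1.642 1510.4
2.23872 1108.7 0.042058 1.5813 1108.7
2.51189 810.1 0.047924 1.5158 810.1
2.81838 589.83 0.054377 1.4444 589.83
3.16228 427.64 0.061381 1.3664 427.64
3.54813 308.89 0.068863 1.2813 308.89
3.98107 222.5 0.076714 1.1895 222.5
4.46684 159.84 0.084787 1.092 159.84
5.01187 114.4 0.092905 0.99059 114.4
5.62341 81.651 0.10086 0.88786 81.652
6.30957 58.151 0.10844 0.78653 58.152
7.07946 41.324 0.11543 0.68931 41.325
7.94328 29.301 0.12169 0.59841 29.303
8.91251 20.73 0.12715 0.51537 20.733
10 14.602 0.13188 0.44101 14.605
11.2202 10.269 0.13597 0.37551 10.272
12.5893 7.2099 0.13952 0.3186 7.2135
14.1254 5.0541 0.14262 0.26965 5.0582
15.8489 3.5372 0.14531 0.22783 3.5417
17.7828 2.4716 0.14767 0.19218 2.4767
19.9526 1.7242 0.14971 0.1618 1.7299
22.3872 1.2009 0.15144 0.13591 1.2073
25.1189 0.83496 0.15286 0.11387 0.84213
28.1838 0.57981 0.15393 0.095499 0.58779
31.6228 0.40212 0.15458 0.080239 0.41097
35.4813 0.27852 0.15477 0.067447 0.28828
39.8107 0.19266 0.15447 0.056662 0.20338
44.6684 0.13309 0.15373 0.047528 0.14481
50.1187 0.091821 0.15256 0.039768 0.10457
56.2341 0.063265 0.15102 0.033168 0.077083
63.0957 0.043533 0.14915 0.027558 0.05845
70.7946 0.029915 0.14695 0.022806 0.045957
79.4328 0.020531 0.14446 0.018801 0.037709
89.1251 0.014071 0.14168 0.015447 0.03239
100 0.0096314 0.13863 0.012658 0.029078
112.202 0.0065838 0.13533 0.010354 0.027134
125.893 0.0044945 0.13182 0.0084589 0.026111
141.254 0.0030642 0.12811 0.0069087 0.025698
158.489 0.0020863 0.12424 0.0056457 0.025677
177.828 0.0014187 0.12025 0.0046215 0.025898
199.526 0.00096337 0.11616 0.0037952 0.026253
223.872 0.00065334 0.11201 0.0031331 0.026669
251.189 0.0004425 0.10781 0.0026066 0.027095
281.838 0.0002993 0.1036 0.0021917 0.027495
316.228 0.00020218 0.099399 0.0018678 0.027844
354.813 0.0001364 0.095223 0.0016171 0.028126
398.107 9.1895e-05 0.09109 0.0014245 0.028331
446.684 6.1833e-05 0.087014 0.001277 0.02845
501.187 4.155e-05 0.083005 0.0011645 0.028481
562.341 2.7885e-05 0.079072 0.0010785 0.028421
630.957 1.8689e-05 0.075223 0.0010125 0.02827
707.946 1.251e-05 0.071463 0.00096197 0.028028
794.328 8.3628e-06 0.067795 0.00092225 0.027698
891.251 5.5832e-06 0.064223 0.00089187 0.027281
1000 3.7227e-06 0.060751 0.00086753 0.026783
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 10.9924
0.01 10.9737
0.0130782 10.9605
0.0171039 10.9382
0.0223689 10.9006
0.0292545 10.8381
0.0382596 10.7361
0.0500366 10.5749
0.0654389 10.3328
0.0855824 9.9957
0.111926 9.56976
0.14638 9.06917
0.191438 8.45619
0.250367 7.61858
0.327435 6.4801
0.428225 5.10723
0.560042 3.7226
0.732434 2.59231
0.957892 1.86122
1.25275 1.47824
1.63837 1.22288
2.1427 1.01105
2.80226 0.88164
3.66485 0.711445
4.79297 0.516243
6.26834 0.328596
8.19787 0.181424
10.7213 0.0875542
14.0216 0.0377862
18.3377 0.0150076
23.9824 0.00563139
31.3647 0.00203707
41.0194 0.000720303
53.646 0.000251209
70.1593 8.68915e-05
91.7557 2.99089e-05
120 1.02654e-05
# incoherent scattering function S(x), same x grid
@sf 37
0 0.0151438
0.01 0.0522205
0.0130782 0.0781425
0.0171039 0.121688
0.0223689 0.193931
0.0292545 0.311349
0.0382596 0.495936
0.0500366 0.77165
0.0654389 1.15559
0.0855824 1.65277
0.111926 2.27966
0.14638 3.1008
0.191438 4.17384
0.250367 5.45635
0.327435 6.80809
0.428225 8.01388
0.560042 8.84711
0.732434 9.26994
0.957892 9.5556
1.25275 9.8591
1.63837 10.2039
2.1427 10.5383
2.80226 10.7396
3.66485 10.8197
4.79297 10.8776
6.26834 10.938
8.19787 10.9782
10.7213 10.9945
14.0216 10.9989
18.3377 10.9998
23.9824 11
31.3647 11
41.0194 11
53.646 11
70.1593 11
91.7557 11
120 11
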