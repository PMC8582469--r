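# element photon data: Ag (Z=47)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 47
# A: 107.86820
# kedge_keV: 25.5140
# kjump: 6.5089
# kyield: 0.8310
# klines_keV: 22.163 21.990 24.932 25.456
# klines_w: 0.5300 0.2800 0.1600 0.0300
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 69
1 6784.2 0.0078117 7.8335 6784.2
1.12202 5242.9 0.0095935 7.7482 5242.9
1.25893 4033.3 0.011724 7.6459 4033.3
1.41254 3089.2 0.014247 7.5243 3089.2
1.58489 2354.1 0.017206 7.381 2354.1
1.77828 1787 0.020637 7.214 1787
1.99526 1352.4 0.02457 7.0213 1352.4
2.23872 1020.2 0.029025 6.8013 1020.2
2.51189 766.88 0.034006 6.5533 766.88
2.81838 574.76 0.039496 6.2771 574.76
3.16228 429.05 0.045452 5.9739 429.05
3.34942 370.17 0.048578 5.8133 370.17
3.35278 1223 0.048633 5.8104 1223
3.52194 1121 0.051378 5.6683 1121
3.52546 1523.8 0.051434 5.6654 1523.8
3.54813 1501.8 0.051796 5.6466 1501.8
3.8039 1266.8 0.055776 5.4387 1266.8
3.8077 1454.2 0.055834 5.4357 1454.2
3.98107 1300.2 0.058421 5.2994 1300.2
4.46684 972.51 0.065195 4.9382 972.51
5.01187 723.98 0.071973 4.5698 723.99
5.62341 536.88 0.078613 4.2012 536.88
6.30957 396.91 0.084985 3.8396 396.92
7.07946 292.51 0.090984 3.4914 292.52
7.94328 214.93 0.096543 3.1614 214.93
8.91251 157.55 0.10164 2.8521 157.55
10 115.11 0.1063 2.5634 115.11
11.2202 83.967 0.11056 2.2929 83.969
12.5893 61.151 0.11447 2.0382 61.154
14.1254 44.474 0.11806 1.7976 44.477
15.8489 32.285 0.12133 1.5712 32.289
17.7828 23.394 0.12427 1.3606 23.398
19.9526 16.934 0.12685 1.1684 16.939
22.3872 12.248 0.12906 0.99646 12.253
25.1189 8.8499 0.1309 0.84607 8.8562
25.5012 8.4799 0.13111 0.82822 8.4862
25.5268 55.248 0.13113 0.82705 20.766
28.1838 42.36 0.13235 0.72257 18.417
31.6228 31.246 0.13339 0.622 15.509
35.4813 22.956 0.13401 0.53845 12.655
39.8107 16.808 0.1342 0.46863 10.089
44.6684 12.271 0.13396 0.4103 7.9035
50.1187 8.9321 0.13331 0.36168 6.1034
56.2341 6.4753 0.13227 0.32119 4.6526
63.0957 4.683 0.13088 0.28746 3.5135
70.7946 3.3796 0.12916 0.2592 2.6331
79.4328 2.4337 0.12715 0.23533 1.9607
89.1251 1.7459 0.12488 0.21487 1.45
100 1.2518 0.12237 0.19697 1.0696
112.202 0.8972 0.11964 0.18095 0.78803
125.893 0.64276 0.11673 0.16621 0.58064
141.254 0.46029 0.11364 0.15231 0.42854
158.489 0.32947 0.11042 0.13892 0.31742
177.828 0.23572 0.10706 0.12585 0.23652
199.526 0.16858 0.10361 0.11304 0.17781
223.872 0.12051 0.10009 0.10052 0.13532
251.189 0.086102 0.096507 0.088447 0.10465
281.838 0.061493 0.092895 0.076995 0.082553
316.228 0.043897 0.08927 0.066362 0.066664
354.813 0.031323 0.085648 0.056706 0.055244
398.107 0.022341 0.082045 0.048122 0.047029
446.684 0.015928 0.078473 0.040627 0.041103
501.187 0.011351 0.074944 0.034182 0.036801
562.341 0.0080859 0.071469 0.028703 0.033643
630.957 0.0057578 0.068053 0.024086 0.031284
707.946 0.0040985 0.064705 0.02023 0.029474
794.328 0.0029163 0.06143 0.017018 0.028038
891.251 0.0020744 0.058232 0.014377 0.026849
1000 0.001475 0.055115 0.012199 0.025817
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 46.9991
0.01 46.9632
0.0130782 46.9377
0.0171039 46.8944
0.0223689 46.8207
0.0292545 46.6961
0.0382596 46.4868
0.0500366 46.1397
0.0654389 45.575
0.0855824 44.6829
0.111926 43.3291
0.14638 41.3704
0.191438 38.6732
0.250367 35.1693
0.327435 31.0038
0.428225 26.6018
0.560042 22.5341
0.732434 19.1261
0.957892 15.8689
1.25275 12.1902
1.63837 8.59624
2.1427 6.63243
2.80226 6.57826
3.66485 6.48712
4.79297 6.33558
6.26834 6.08841
8.19787 5.69795
10.7213 5.11204
14.0216 4.30014
18.3377 3.29901
23.9824 2.24483
31.3647 1.32934
41.0194 0.683893
53.646 0.310711
70.1593 0.128082
91.7557 0.0492748
120 0.0181097
# incoherent scattering function S(x), same x grid
@sf 37
0 0.00180052
0.01 0.0736331
0.0130782 0.124454
0.0171039 0.210951
0.0223689 0.357728
0.0292545 0.605374
0.0382596 1.01936
0.0500366 1.70086
0.0654389 2.7957
0.0855824 4.49056
0.111926 6.98141
0.14638 10.4126
0.191438 14.8048
0.250367 19.9392
0.327435 25.2154
0.428225 29.8469
0.560042 33.3412
0.732434 35.8309
0.957892 37.9603
1.25275 40.0338
1.63837 41.8478
2.1427 43.3063
2.80226 44.3254
3.66485 44.8952
4.79297 45.2147
6.26834 45.5066
8.19787 45.8451
10.7213 46.1907
14.0216 46.4883
18.3377 46.7164
23.9824 46.871
31.3647 46.9547
41.0194 46.9879
53.646 46.9975
70.1593 46.9996
91.7557 46.9999
120 47
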