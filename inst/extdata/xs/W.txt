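# element photon data: W (Z=74)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 74
# A: 183.84000
# kedge_keV: 69.5250
# kjump: 5.1275
# kyield: 0.9580
# klines_keV: 59.318 57.982 67.150 69.090
# klines_w: 0.4600 0.2700 0.2100 0.0600
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 77
1 3514.5 0.00647 11.451 3514.5
1.12202 2793.7 0.0079055 11.343 2793.7
1.25893 2214.7 0.0096213 11.214 2214.7
1.41254 1751.5 0.01165 11.061 1751.5
1.58489 1381.1 0.014021 10.882 1381.1
1.77828 1085.2 0.016753 10.675 1085.2
1.8083 1047.4 0.017182 10.642 1047.4
1.8101 20297 0.017207 10.64 20297
1.87066 4696.8 0.018073 10.574 4696.8
1.87254 16975 0.0181 10.572 16975
1.99526 3871.4 0.019859 10.438 3871.4
2.23872 2919.2 0.02334 10.172 2919.2
2.27986 2789.5 0.023924 10.127 2789.5
2.28214 3267.6 0.023957 10.124 3267.6
2.51189 2564.9 0.02719 9.8755 2564.9
2.57361 2418.6 0.028048 9.8092 2418.6
2.57619 2581.4 0.028084 9.8064 2581.4
2.81838 2071.1 0.031402 9.5495 2071.1
3.16228 1647.4 0.035968 9.1936 1647.4
3.54813 1248.9 0.040885 8.8074 1248.9
3.98107 942.33 0.046142 8.3907 942.33
4.46684 708.81 0.051709 7.9447 708.81
5.01187 531.5 0.057532 7.4725 531.5
5.62341 397.4 0.063525 6.9797 397.4
6.30957 296.44 0.069583 6.4734 296.44
7.07946 220.7 0.075602 5.9612 220.71
7.94328 164.01 0.081488 5.4496 164.01
8.91251 121.65 0.087164 4.9443 121.65
10 89.936 0.092562 4.4502 89.938
10.2017 85.326 0.093465 4.366 85.329
10.2119 234.96 0.09351 4.3618 234.96
11.2202 177.73 0.097613 3.9727 177.73
11.5382 164.68 0.098779 3.86 164.68
11.5498 228.52 0.09882 3.856 228.53
12.0938 201.66 0.10068 3.6737 201.66
12.1059 232.64 0.10072 3.6698 232.65
12.5893 210.69 0.10225 3.5183 210.69
14.1254 156.69 0.10639 3.0937 156.69
15.8489 116.18 0.11002 2.7045 116.19
17.7828 85.915 0.11312 2.354 85.919
19.9526 63.389 0.1157 2.0421 63.394
22.3872 46.659 0.11782 1.7668 46.664
25.1189 34.269 0.11951 1.5249 34.274
28.1838 25.104 0.12076 1.3243 25.111
31.6228 18.352 0.12158 1.1605 18.359
35.4813 13.4 0.12204 1.0247 13.408
39.8107 9.7733 0.12214 0.91172 9.7818
44.6684 7.1188 0.12191 0.81783 7.1282
50.1187 5.1764 0.12133 0.74002 5.1867
56.2341 3.7564 0.12042 0.6757 3.7675
63.0957 2.7235 0.11918 0.62253 2.7355
69.4902 2.0791 0.11791 0.58504 2.0918
69.5598 10.667 0.11789 0.58469 3.4438
70.7946 10.209 0.11764 0.57846 3.4174
79.4328 7.5677 0.1158 0.54168 3.086
89.1251 5.5941 0.11369 0.5106 2.6472
100 4.1161 0.11136 0.48384 2.1895
112.202 3.0238 0.10882 0.4602 1.7687
125.893 2.2186 0.1061 0.43863 1.4045
141.254 1.6241 0.10325 0.41822 1.0998
158.489 1.1808 0.10027 0.39819 0.84837
177.828 0.85949 0.097203 0.37788 0.6513
199.526 0.6263 0.094061 0.35675 0.49876
223.872 0.45689 0.090868 0.33446 0.38181
251.189 0.33368 0.087641 0.31081 0.29279
281.838 0.24397 0.084398 0.28585 0.22542
316.228 0.17859 0.081154 0.25983 0.17466
354.813 0.13088 0.077919 0.23321 0.13655
398.107 0.096029 0.074706 0.20663 0.10799
446.684 0.070546 0.071522 0.18078 0.086616
501.187 0.051889 0.068375 0.15633 0.070623
562.341 0.038216 0.06527 0.13383 0.058638
630.957 0.028183 0.062214 0.11362 0.049628
707.946 0.020812 0.05921 0.095861 0.042818
794.328 0.015391 0.056264 0.080489 0.037627
891.251 0.011398 0.05338 0.067385 0.033625
1000 0.0084536 0.050564 0.05628 0.030491
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 73.9518
0.01 73.903
0.0130782 73.8684
0.0171039 73.8095
0.0223689 73.7093
0.0292545 73.5397
0.0382596 73.2547
0.0500366 72.7814
0.0654389 72.011
0.0855824 70.7967
0.111926 68.9749
0.14638 66.4204
0.191438 63.0919
0.250367 58.9381
0.327435 53.7641
0.428225 47.5493
0.560042 40.7441
0.732434 33.6983
0.957892 26.6337
1.25275 20.5537
1.63837 16.2605
2.1427 13.8946
2.80226 13.8487
3.66485 13.7707
4.79297 13.6389
6.26834 13.4177
8.19787 13.0517
10.7213 12.4595
14.0216 11.5361
18.3377 10.1785
23.9824 8.35428
31.3647 6.19971
41.0194 4.05183
53.646 2.29865
70.1593 1.13657
91.7557 0.500005
120 0.201322
# incoherent scattering function S(x), same x grid
@sf 37
0 0.096323
0.01 0.193869
0.0130782 0.262898
0.0171039 0.380446
0.0223689 0.580057
0.0292545 0.91726
0.0382596 1.48197
0.0500366 2.41412
0.0654389 3.91641
0.0855824 6.24664
0.111926 9.65678
0.14638 14.2645
0.191438 19.9643
0.250367 26.5962
0.327435 34.1126
0.428225 42.0563
0.560042 49.4152
0.732434 55.5982
0.957892 60.4018
1.25275 63.5816
1.63837 65.6137
2.1427 67.1793
2.80226 68.4063
3.66485 69.5026
4.79297 70.2351
6.26834 70.6271
8.19787 70.9135
10.7213 71.2879
14.0216 71.7895
18.3377 72.3625
23.9824 72.9315
31.3647 73.4181
41.0194 73.7513
53.646 73.9196
70.1593 73.9803
91.7557 73.9962
120 73.9994
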