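# element photon data: Cr (Z=24)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 24
# A: 51.99610
# kedge_keV: 5.9892
# kjump: 8.6774
# kyield: 0.2750
# klines_keV: 5.412 5.947
# klines_w: 0.8800 0.1200
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 7183.8 0.012108 4.1415 7183.8
1.12202 5409.1 0.014669 4.0774 5409.1
1.25893 4056.1 0.01765 4.0021 4056.1
1.41254 3030.2 0.021073 3.9149 3030.2
1.58489 2256.5 0.024951 3.815 2256.5
1.77828 1675 0.029281 3.702 1675
1.99526 1239.6 0.034055 3.5756 1239.6
2.23872 914.7 0.039255 3.4356 914.7
2.51189 672.81 0.044857 3.2819 672.81
2.81838 493.67 0.050826 3.1146 493.67
3.16228 361.06 0.057107 2.9341 361.06
3.54813 263.33 0.063618 2.742 263.33
3.98107 191.8 0.070245 2.5406 191.8
4.46684 139.52 0.076861 2.3333 139.52
5.01187 101.36 0.083345 2.1244 101.36
5.62341 73.535 0.089599 1.9181 73.537
5.98621 61.739 0.092877 1.8088 61.741
5.99219 536.2 0.092929 1.807 416.97
6.30957 462.71 0.095567 1.7188 365
7.07946 343.98 0.10123 1.5303 279.24
7.94328 254.41 0.10662 1.3557 211.73
8.91251 187.24 0.11175 1.1969 159.25
10 137.2 0.11666 1.0545 118.92
11.2202 100.2 0.12132 0.92749 88.307
12.5893 72.882 0.12571 0.81412 65.171
14.1254 52.798 0.12975 0.71214 47.821
15.8489 38.146 0.13338 0.61962 34.944
17.7828 27.488 0.13655 0.53533 25.433
19.9526 19.755 0.13921 0.4587 18.441
22.3872 14.16 0.14137 0.38966 13.323
25.1189 10.122 0.14301 0.32837 9.5916
28.1838 7.2042 0.14416 0.27801 6.8712
31.6228 5.1101 0.14484 0.2373 4.9032
35.4813 3.6201 0.1451 0.20355 3.4934
39.8107 2.5612 0.14496 0.17527 2.4856
44.6684 1.8097 0.14445 0.15145 1.7668
50.1187 1.2771 0.1436 0.13133 1.2551
56.2341 0.89997 0.14242 0.11425 0.89172
63.0957 0.63339 0.14091 0.099662 0.63416
70.7946 0.44517 0.13909 0.087069 0.45205
79.4328 0.31247 0.13696 0.076076 0.32359
89.1251 0.21903 0.13453 0.066363 0.23323
100 0.15332 0.13183 0.057693 0.16986
112.202 0.10718 0.12887 0.049905 0.12557
125.893 0.074822 0.12569 0.0429 0.094741
141.254 0.052162 0.12231 0.036626 0.07338
158.489 0.036315 0.11876 0.031058 0.058661
177.828 0.025248 0.11507 0.026177 0.048583
199.526 0.01753 0.11127 0.021958 0.041734
223.872 0.012154 0.10739 0.018359 0.037118
251.189 0.0084154 0.10345 0.015326 0.034033
281.838 0.0058189 0.099478 0.012794 0.031987
316.228 0.0040179 0.095504 0.010696 0.030636
354.813 0.0027706 0.091543 0.0089687 0.029737
398.107 0.0019079 0.087613 0.0075529 0.029124
446.684 0.001312 0.083728 0.0063964 0.028679
501.187 0.00090102 0.0799 0.0054545 0.028323
562.341 0.00061793 0.07614 0.0046895 0.027998
630.957 0.0004232 0.072453 0.0040688 0.027669
707.946 0.00028945 0.068847 0.0035701 0.02731
794.328 0.0001977 0.065327 0.0031645 0.026905
891.251 0.00013485 0.061896 0.0028469 0.026444
1000 9.1852e-05 0.058558 0.0025896 0.025923
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 23.9937
0.01 23.9655
0.0130782 23.9456
0.0171039 23.9117
0.0223689 23.8543
0.0292545 23.7577
0.0382596 23.5969
0.0500366 23.3339
0.0654389 22.9161
0.0855824 22.2807
0.111926 21.3701
0.14638 20.1447
0.191438 18.5616
0.250367 16.5526
0.327435 14.1433
0.428225 11.582
0.560042 9.2606
0.732434 7.54493
0.957892 6.35466
1.25275 5.15886
1.63837 3.7508
2.1427 2.70073
2.80226 2.61792
3.66485 2.48485
4.79297 2.27965
6.26834 1.98317
8.19787 1.59492
10.7213 1.1522
14.0216 0.729638
18.3377 0.40076
23.9824 0.192522
31.3647 0.0827924
41.0194 0.0328
53.646 0.0122873
70.1593 0.0044401
91.7557 0.00156901
120 0.000546988
# incoherent scattering function S(x), same x grid
@sf 37
0 0.0125971
0.01 0.0688578
0.0130782 0.108567
0.0171039 0.175991
0.0223689 0.289867
0.0292545 0.480547
0.0382596 0.795226
0.0500366 1.30224
0.0654389 2.08858
0.0855824 3.23983
0.111926 4.79807
0.14638 6.72886
0.191438 8.95292
0.250367 11.3609
0.327435 13.6943
0.428225 15.6517
0.560042 17.2328
0.732434 18.6966
0.957892 20.1129
1.25275 21.2618
1.63837 22.0273
2.1427 22.492
2.80226 22.8176
3.66485 23.132
4.79297 23.4348
6.26834 23.6725
8.19787 23.8257
10.7213 23.9163
14.0216 23.9668
18.3377 23.9898
23.9824 23.9976
31.3647 23.9996
41.0194 23.9999
53.646 24
70.1593 24
91.7557 24
120 24
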