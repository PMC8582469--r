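# element photon data: Mn (Z=25)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 25
# A: 54.93805
# kedge_keV: 6.5390
# kjump: 8.5445
# kyield: 0.3080
# klines_keV: 5.895 6.492
# klines_w: 0.8800 0.1200
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 7837.8 0.012388 4.2417 7837.8
1.12202 5933.5 0.015 4.1736 5933.5
1.25893 4462 0.018035 4.0939 4462
1.41254 3341.7 0.021508 4.0017 3341.7
1.58489 2493.7 0.02542 3.8968 2493.7
1.77828 1854.9 0.029757 3.779 1854.9
1.99526 1375.3 0.03449 3.6487 1375.3
2.23872 1016.6 0.039585 3.5062 1016.6
2.51189 749.26 0.045008 3.3518 749.26
2.81838 550.55 0.050729 3.1859 550.55
3.16228 403.19 0.056714 3.0084 403.19
3.54813 294.35 0.062915 2.8201 294.35
3.98107 214.6 0.06926 2.6221 214.6
4.46684 156.25 0.075649 2.417 156.25
5.01187 113.61 0.081972 2.2081 113.61
5.62341 82.496 0.088124 1.9996 82.497
6.30957 59.82 0.094025 1.7957 59.821
6.53573 54.203 0.095772 1.7349 54.204
6.54227 463.55 0.095821 1.7332 348.58
7.07946 372.04 0.099631 1.6006 286.77
7.94328 276.26 0.10494 1.418 219.83
8.91251 203.91 0.10997 1.2505 166.79
10 149.8 0.11476 1.0996 125.5
11.2202 109.69 0.1193 0.96509 93.832
12.5893 80.054 0.12358 0.84564 69.739
14.1254 58.154 0.12753 0.73911 51.477
15.8489 42.098 0.13111 0.64331 37.792
17.7828 30.394 0.13425 0.55658 27.625
19.9526 21.885 0.13691 0.47791 20.111
22.3872 15.716 0.13908 0.40691 14.583
25.1189 11.256 0.14074 0.3436 10.535
28.1838 8.0367 0.14191 0.2915 7.5814
31.6228 5.7071 0.14261 0.24944 5.4225
35.4813 4.0473 0.14287 0.21461 3.8713
39.8107 2.8668 0.14273 0.18545 2.7599
44.6684 2.0282 0.14222 0.1609 1.9654
50.1187 1.4331 0.14137 0.14017 1.3986
56.2341 1.0114 0.1402 0.12256 0.99508
63.0957 0.71288 0.13871 0.1075 0.70848
70.7946 0.50185 0.13691 0.094469 0.50536
79.4328 0.35285 0.13481 0.083054 0.36174
89.1251 0.24777 0.13243 0.072916 0.26046
100 0.17376 0.12977 0.063806 0.18924
112.202 0.12171 0.12687 0.055552 0.13931
125.893 0.085137 0.12375 0.048055 0.10443
141.254 0.059479 0.12043 0.041268 0.080177
158.489 0.041501 0.11695 0.035176 0.063387
177.828 0.028919 0.11333 0.029777 0.05183
199.526 0.020126 0.10959 0.025062 0.043926
223.872 0.013988 0.10578 0.021004 0.038557
251.189 0.0097095 0.10191 0.017557 0.034936
281.838 0.0067309 0.098009 0.014662 0.03251
316.228 0.00466 0.0941 0.012252 0.030888
354.813 0.0032221 0.090203 0.010259 0.029798
398.107 0.002225 0.086336 0.0086198 0.02905
446.684 0.0015344 0.082513 0.0072771 0.02851
501.187 0.0010568 0.078745 0.0061813 0.028088
562.341 0.0007269 0.075042 0.0052895 0.027718
630.957 0.00049933 0.071412 0.0045648 0.027359
707.946 0.00034256 0.06786 0.0039808 0.02698
794.328 0.00023471 0.064392 0.0035045 0.026564
891.251 0.0001606 0.061012 0.0031293 0.026098
1000 0.00010975 0.057723 0.0028244 0.025576
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 24.9922
0.01 24.9618
0.0130782 24.9403
0.0171039 24.9038
0.0223689 24.8419
0.0292545 24.7375
0.0382596 24.5638
0.0500366 24.2794
0.0654389 23.8276
0.0855824 23.1416
0.111926 22.1668
0.14638 20.8868
0.191438 19.3041
0.250367 17.3593
0.327435 14.9895
0.428225 12.3489
0.560042 9.82005
0.732434 7.85268
0.957892 6.54335
1.25275 5.38559
1.63837 4.018
2.1427 2.93844
2.80226 2.85519
3.66485 2.72077
4.79297 2.51191
6.26834 2.20652
8.19787 1.79947
10.7213 1.32403
14.0216 0.856602
18.3377 0.480887
23.9824 0.235538
31.3647 0.102843
41.0194 0.041186
53.646 0.0155396
70.1593 0.00564073
91.7557 0.00199879
120 0.000697978
# incoherent scattering function S(x), same x grid
@sf 37
0 0.0155942
0.01 0.0762725
0.0130782 0.119103
0.0171039 0.191828
0.0223689 0.314696
0.0292545 0.520505
0.0382596 0.860304
0.0500366 1.40806
0.0654389 2.25749
0.0855824 3.49803
0.111926 5.16099
0.14638 7.17119
0.191438 9.3976
0.250367 11.7645
0.327435 14.1418
0.428225 16.2409
0.560042 17.9363
0.732434 19.4275
0.957892 20.8698
1.25275 22.0847
1.63837 22.9193
2.1427 23.4244
2.80226 23.7493
3.66485 24.0568
4.79297 24.3639
6.26834 24.6178
8.19787 24.7898
10.7213 24.8957
14.0216 24.9569
18.3377 24.9863
23.9824 24.9967
31.3647 24.9994
41.0194 24.9999
53.646 25
70.1593 25
91.7557 25
120 25
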