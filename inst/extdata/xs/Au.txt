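# element photon data: Au (Z=79)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 79
# A: 196.96700
# kedge_keV: 80.7249
# kjump: 4.8943
# kyield: 0.9640
# klines_keV: 68.804 66.990 77.980 80.180
# klines_w: 0.4600 0.2700 0.2100 0.0600
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 77
1 4444.4 0.0053576 12.268 4444.4
1.12202 3563.5 0.0065967 12.168 3563.5
1.25893 2844.4 0.0081029 12.048 2844.4
1.41254 2256.4 0.0099194 11.902 2256.4
1.58489 1775.7 0.01209 11.727 1775.7
1.77828 1390.5 0.014654 11.52 1390.5
1.99526 1085.6 0.017647 11.277 1085.6
2.2046 873.7 0.020605 11.036 873.7
2.2068 11896 0.020636 11.033 11896
2.23872 6429.2 0.02109 10.996 6429.2
2.28995 2975.1 0.021821 10.937 2975.1
2.29225 10033 0.021854 10.934 10033
2.51189 2698.7 0.024992 10.677 2698.7
2.74163 2168.2 0.02826 10.408 2168.2
2.74437 2511 0.028299 10.405 2511
2.81838 2355.2 0.029343 10.318 2355.3
3.14623 1798.6 0.033898 9.9407 1798.6
3.14937 1912.2 0.033941 9.9371 1912.2
3.16228 1892.8 0.034118 9.9224 1892.8
3.54813 1492.3 0.039276 9.4913 1492.3
3.98107 1131.3 0.044767 9.0284 1131.3
4.46684 854.39 0.050531 8.5375 854.39
5.01187 642.47 0.056493 8.0237 642.48
5.62341 481.85 0.062566 7.4934 481.86
6.30957 360.43 0.06865 6.954 360.43
7.07946 268.9 0.074646 6.4131 268.9
7.94328 200.23 0.08047 5.8772 200.23
8.91251 148.83 0.086062 5.3509 148.83
10 110.3 0.091379 4.8369 110.31
11.2202 81.631 0.096382 4.3382 81.633
11.9127 69.773 0.098844 4.0861 69.775
11.9247 182.6 0.098885 4.082 182.6
12.5893 157.31 0.10102 3.8589 157.31
13.7267 124.28 0.10423 3.5149 124.28
13.7405 173.41 0.10427 3.511 173.41
14.1254 160.9 0.10524 3.4046 160.9
14.3456 154.29 0.10577 3.3458 154.3
14.36 178.02 0.1058 3.342 178.03
15.8489 138.37 0.10897 2.9817 138.38
17.7828 102.77 0.1122 2.5954 102.78
19.9526 76.142 0.1149 2.2487 76.147
22.3872 56.283 0.11712 1.9418 56.288
25.1189 41.507 0.11887 1.6736 41.513
28.1838 30.525 0.12014 1.4517 30.531
31.6228 22.384 0.12097 1.2704 22.391
35.4813 16.395 0.12143 1.1198 16.402
39.8107 11.993 0.12154 0.99431 12.002
44.6684 8.7629 0.12131 0.88988 8.7722
50.1187 6.3944 0.12075 0.8033 6.4046
56.2341 4.6587 0.11986 0.73176 4.6697
63.0957 3.3891 0.11864 0.6727 3.401
70.7946 2.462 0.11712 0.62388 2.4748
79.4328 1.7877 0.1153 0.58332 1.8015
80.6845 1.7117 0.11503 0.57835 1.7256
80.7653 8.383 0.11502 0.57803 2.7504
89.1251 6.5144 0.11322 0.54926 2.5528
100 4.8283 0.1109 0.52021 2.2173
112.202 3.5684 0.10838 0.49484 1.8548
125.893 2.6262 0.10568 0.47202 1.5088
141.254 1.9308 0.10283 0.45074 1.2054
158.489 1.4186 0.099857 0.43016 0.95073
177.828 1.0417 0.096792 0.40951 0.74281
199.526 0.76444 0.093655 0.3882 0.57649
223.872 0.56061 0.090467 0.36576 0.4455
251.189 0.41086 0.087247 0.34191 0.34357
281.838 0.30092 0.084012 0.31655 0.26502
316.228 0.22025 0.080777 0.28983 0.20497
354.813 0.16109 0.077554 0.26215 0.15935
398.107 0.11774 0.074353 0.23407 0.12488
446.684 0.086 0.071184 0.2063 0.098932
501.187 0.06277 0.068053 0.1796 0.079461
562.341 0.045783 0.064965 0.15463 0.064871
630.957 0.03337 0.061926 0.13189 0.053937
707.946 0.024304 0.05894 0.11167 0.045725
794.328 0.017689 0.056011 0.094004 0.039528
891.251 0.012866 0.053144 0.07884 0.034814
1000 0.0093506 0.050343 0.065929 0.031185
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 78.9572
0.01 78.9153
0.0130782 78.8856
0.0171039 78.8349
0.0223689 78.7486
0.0292545 78.6017
0.0382596 78.3532
0.0500366 77.9357
0.0654389 77.2426
0.0855824 76.1153
0.111926 74.3406
0.14638 71.6828
0.191438 67.9698
0.250367 63.1847
0.327435 57.4307
0.428225 50.8859
0.560042 43.9727
0.732434 36.9679
0.957892 29.688
1.25275 22.748
1.63837 17.4401
2.1427 14.7953
2.80226 14.7524
3.66485 14.6795
4.79297 14.556
6.26834 14.3484
8.19787 14.0035
10.7213 13.4417
14.0216 12.5562
18.3377 11.2322
23.9824 9.40749
31.3647 7.17461
41.0194 4.84644
53.646 2.84734
70.1593 1.454
91.7557 0.656554
120 0.269424
# incoherent scattering function S(x), same x grid
@sf 37
0 0.0855753
0.01 0.169238
0.0130782 0.228555
0.0171039 0.329715
0.0223689 0.501939
0.0292545 0.794215
0.0382596 1.2875
0.0500366 2.11231
0.0654389 3.4702
0.0855824 5.6491
0.111926 9.00495
0.14638 13.8607
0.191438 20.303
0.250367 28.0202
0.327435 36.4299
0.428225 44.8478
0.560042 52.4307
0.732434 58.7767
0.957892 63.9989
1.25275 67.7893
1.63837 70.1729
2.1427 71.7535
2.80226 72.957
3.66485 74.1062
4.79297 74.9382
6.26834 75.4012
8.19787 75.6984
10.7213 76.0535
14.0216 76.5439
18.3377 77.1294
23.9824 77.7337
31.3647 78.2746
41.0194 78.6695
53.646 78.8855
70.1593 78.97
91.7557 78.9939
120 78.999
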