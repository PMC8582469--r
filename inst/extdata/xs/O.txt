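# element photon data: O (Z=8)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 8
# A: 15.99940
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 61
1 4419 0.012479 1.5015 4419
1.12202 3253.5 0.015414 1.4774 3253.5
1.25893 2387.2 0.01896 1.4481 2387.2
1.41254 1745.5 0.0232 1.413 1745.5
1.58489 1272 0.028211 1.371 1272
1.77828 923.68 0.034048 1.3217 923.68
1.99526 668.46 0.040734 1.2646 668.46
2.23872 481.86 0.04824 1.1995 481.86
2.51189 346.15 0.056477 1.1269 346.15
2.81838 248.02 0.065284 1.0476 248.02
3.16228 177.11 0.074436 0.96312 177.11
3.54813 126.06 0.083664 0.87545 126.06
3.98107 89.529 0.09268 0.78689 89.53
4.46684 63.445 0.10122 0.69984 63.446
5.01187 44.862 0.10909 0.61651 44.863
5.62341 31.652 0.11617 0.53871 31.653
6.30957 22.283 0.12244 0.46768 22.284
7.07946 15.652 0.12795 0.40405 15.654
7.94328 10.971 0.13282 0.3479 10.973
8.91251 7.6722 0.13716 0.29891 7.6748
10 5.3534 0.1411 0.25649 5.3564
11.2202 3.7216 0.14472 0.21994 3.725
12.5893 2.5844 0.14808 0.18848 2.5882
14.1254 1.7928 0.15122 0.16132 1.7971
15.8489 1.2424 0.15414 0.13775 1.2472
17.7828 0.86007 0.1568 0.11721 0.8655
19.9526 0.59477 0.15917 0.099239 0.60087
22.3872 0.41087 0.16118 0.083539 0.41772
25.1189 0.28354 0.16278 0.069897 0.29119
28.1838 0.19512 0.16391 0.0585 0.20363
31.6228 0.13394 0.16454 0.049019 0.14337
35.4813 0.091931 0.16465 0.041003 0.10232
39.8107 0.063081 0.16426 0.034181 0.074478
44.6684 0.043275 0.16339 0.028374 0.055721
50.1187 0.029681 0.16206 0.023447 0.043212
56.2341 0.020353 0.16031 0.01929 0.035001
63.0957 0.013953 0.15818 0.015807 0.029745
70.7946 0.0095638 0.15568 0.01291 0.026517
79.4328 0.0065536 0.15285 0.010516 0.024677
89.1251 0.0044899 0.14971 0.0085506 0.023782
100 0.0030753 0.1463 0.0069446 0.023523
112.202 0.0021059 0.14266 0.0056388 0.023685
125.893 0.0014418 0.1388 0.0045819 0.024115
141.254 0.00098686 0.13476 0.0037309 0.024706
158.489 0.00067532 0.13058 0.0030496 0.025381
177.828 0.00046203 0.12629 0.0025078 0.026085
199.526 0.00031603 0.12191 0.0020801 0.026776
223.872 0.00021611 0.11748 0.0017447 0.027428
251.189 0.00014775 0.11302 0.0014836 0.028019
281.838 0.00010099 0.10855 0.0012815 0.028535
316.228 6.9017e-05 0.10411 0.0011255 0.028966
354.813 4.7154e-05 0.099701 0.0010052 0.029305
398.107 3.2209e-05 0.095346 0.00091237 0.029548
446.684 2.1996e-05 0.091057 0.00084055 0.029693
501.187 1.5018e-05 0.086844 0.00078485 0.029739
562.341 1.0251e-05 0.082715 0.00074151 0.029685
630.957 6.9961e-06 0.078677 0.0007076 0.029532
707.946 4.7735e-06 0.074734 0.00068137 0.029283
794.328 3.2562e-06 0.070891 0.00066037 0.02894
891.251 2.2208e-06 0.06715 0.00064487 0.028507
1000 1.5142e-06 0.063514 0.00063241 0.027988
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 7.9994
0.01 7.99115
0.0130782 7.9853
0.0171039 7.97532
0.0223689 7.95829
0.0292545 7.92932
0.0382596 7.88021
0.0500366 7.7975
0.0654389 7.65965
0.0855824 7.43402
0.111926 7.07546
0.14638 6.53227
0.191438 5.768
0.250367 4.80217
0.327435 3.74508
0.428225 2.78101
0.560042 2.07765
0.732434 1.66032
0.957892 1.41179
1.25275 1.1812
1.63837 0.898993
2.1427 0.643821
2.80226 0.508488
3.66485 0.35886
4.79297 0.221265
6.26834 0.118346
8.19787 0.0555571
10.7213 0.0234717
14.0216 0.00918397
18.3377 0.00341252
23.9824 0.00122685
31.3647 0.000432185
41.0194 0.000150387
53.646 5.19484e-05
70.1593 1.78671e-05
91.7557 6.12955e-06
120 2.09968e-06
# incoherent scattering function S(x), same x grid
@sf 37
0 0.00119966
0.01 0.0176816
0.0130782 0.0293559
0.0171039 0.0492643
0.0223689 0.083134
0.0292545 0.140543
0.0382596 0.237227
0.0500366 0.398298
0.0654389 0.661747
0.0855824 1.07958
0.111926 1.70942
0.14638 2.58403
0.191438 3.65333
0.250367 4.73887
0.327435 5.59853
0.428225 6.11332
0.560042 6.39244
0.732434 6.6341
0.957892 6.93665
1.25275 7.28362
1.63837 7.60545
2.1427 7.83081
2.80226 7.94041
3.66485 7.98034
4.79297 7.9937
6.26834 7.99825
8.19787 7.99961
10.7213 7.99993
14.0216 7.99999
18.3377 8
23.9824 8
31.3647 8
41.0194 8
53.646 8
70.1593 8
91.7557 8
120 8
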