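# element photon data: Ar (Z=18)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 18
# A: 39.94800
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 3056 0.011247 3.0413 3056
1.12202 2265.5 0.01381 2.9925 2265.5
1.25893 1675.7 0.016862 2.9335 1675.7
1.41254 1236.1 0.02045 2.8631 1236.1
1.58489 909.86 0.024603 2.78 909.86
1.77828 668.47 0.029326 2.6833 668.47
1.99526 490.2 0.034586 2.5726 490.2
2.23872 358.81 0.040309 2.4484 358.81
2.51189 262.16 0.046383 2.3119 262.16
2.81838 191.18 0.052667 2.1654 191.19
3.16228 139.05 0.059016 2.0121 139.05
3.2013 134.39 0.059691 1.9955 134.39
3.2045 1339.5 0.059746 1.9941 1339.5
3.54813 1033.9 0.065307 1.8557 1033.9
3.98107 767.03 0.071465 1.7001 767.03
4.46684 567.18 0.077471 1.5492 567.18
5.01187 417.87 0.083358 1.4059 417.87
5.62341 306.68 0.089174 1.2721 306.68
6.30957 224.2 0.094952 1.1488 224.2
7.07946 163.16 0.10068 1.0355 163.16
7.94328 118.35 0.10631 0.93079 118.35
8.91251 85.584 0.11175 0.83307 85.586
10 61.623 0.11692 0.74088 61.626
11.2202 44.264 0.12171 0.65347 44.266
12.5893 31.717 0.12605 0.57085 31.72
14.1254 22.665 0.12988 0.49359 22.668
15.8489 16.137 0.13317 0.42262 16.142
17.7828 11.469 0.1359 0.35879 11.474
19.9526 8.1362 0.13811 0.30266 8.1416
22.3872 5.7613 0.13985 0.25428 5.7673
25.1189 4.072 0.14117 0.21324 4.0787
28.1838 2.8726 0.1421 0.17934 2.88
31.6228 2.0227 0.14268 0.15127 2.0309
35.4813 1.4216 0.14291 0.12776 1.4306
39.8107 0.99723 0.14281 0.10802 1.0072
44.6684 0.69823 0.14236 0.091411 0.7091
50.1187 0.48796 0.14157 0.077425 0.49982
56.2341 0.34036 0.14043 0.065614 0.35326
63.0957 0.23696 0.13894 0.0556 0.25092
70.7946 0.16466 0.13711 0.047065 0.17969
79.4328 0.1142 0.13495 0.039758 0.13032
89.1251 0.079049 0.13249 0.033481 0.096254
100 0.054615 0.12975 0.028087 0.072889
112.202 0.037661 0.12677 0.023465 0.05698
125.893 0.02592 0.12356 0.019527 0.046247
141.254 0.017805 0.12016 0.016199 0.039095
158.489 0.012208 0.1166 0.013411 0.034403
177.828 0.0083535 0.11291 0.011097 0.031389
199.526 0.0057053 0.10912 0.0091892 0.029507
223.872 0.0038891 0.10525 0.0076272 0.028378
251.189 0.0026459 0.10135 0.0063538 0.027736
281.838 0.0017967 0.097415 0.0053192 0.0274
316.228 0.0012177 0.093486 0.0044806 0.027243
354.813 0.00082365 0.089577 0.003802 0.027178
398.107 0.00055606 0.085705 0.0032539 0.027146
446.684 0.00037468 0.081882 0.0028126 0.027106
501.187 0.00025197 0.078119 0.0024594 0.027032
562.341 0.00016913 0.074426 0.0021789 0.026906
630.957 0.0001133 0.070809 0.0019581 0.026717
707.946 7.5756e-05 0.067273 0.001787 0.026458
794.328 5.0554e-05 0.063824 0.0016546 0.026125
891.251 3.3671e-05 0.060464 0.0015548 0.025719
1000 2.2383e-05 0.057198 0.0014779 0.025241
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 17.9994
0.01 17.9803
0.0130782 17.9668
0.0171039 17.9437
0.0223689 17.9044
0.0292545 17.8377
0.0382596 17.7248
0.0500366 17.5355
0.0654389 17.2222
0.0855824 16.7158
0.111926 15.9272
0.14638 14.7717
0.191438 13.2299
0.250367 11.431
0.327435 9.66654
0.428225 8.23123
0.560042 7.14003
0.732434 6.04733
0.957892 4.70027
1.25275 3.24685
1.63837 2.10002
2.1427 1.62677
2.80226 1.5404
3.66485 1.40783
4.79297 1.21766
6.26834 0.97122
8.19787 0.694149
10.7213 0.434188
14.0216 0.235553
18.3377 0.111943
23.9824 0.0477395
31.3647 0.0188022
41.0194 0.00701641
53.646 0.00252928
70.1593 0.000892452
91.7557 0.000310851
120 0.00010744
# incoherent scattering function S(x), same x grid
@sf 37
0 0.00120158
0.01 0.0392956
0.0130782 0.0662538
0.0171039 0.112168
0.0223689 0.190124
0.0292545 0.321814
0.0382596 0.542313
0.0500366 0.906055
0.0654389 1.49124
0.0855824 2.39411
0.111926 3.69532
0.14638 5.38027
0.191438 7.24879
0.250367 8.97234
0.327435 10.4037
0.428225 11.7481
0.560042 13.1731
0.732434 14.5052
0.957892 15.5222
1.25275 16.1631
1.63837 16.5526
2.1427 16.8924
2.80226 17.2416
3.66485 17.5515
4.79297 17.7702
6.26834 17.8912
8.19787 17.9512
10.7213 17.9812
14.0216 17.9943
18.3377 17.9987
23.9824 17.9998
31.3647 18
41.0194 18
53.646 18
70.1593 18
91.7557 18
120 18
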