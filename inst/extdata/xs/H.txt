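# element photon data: H (Z=1)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 1
# A: 1.00794
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 61
1 1e-12 0.0919 0.35867 0.00024365
1.12202 1e-12 0.10958 0.34973 0.0003236
1.25893 1e-12 0.12927 0.33902 0.00042461
1.41254 1e-12 0.15068 0.32635 0.00054961
1.58489 1e-12 0.17334 0.31158 0.00070088
1.77828 1e-12 0.19664 0.29464 0.0008797
1.99526 1e-12 0.21986 0.27559 0.0010862
2.23872 1e-12 0.24229 0.25464 0.0013195
2.51189 1e-12 0.26329 0.23217 0.0015782
2.81838 1e-12 0.28239 0.20873 0.0018609
3.16228 1e-12 0.29933 0.18499 0.002167
3.54813 1e-12 0.31402 0.16169 0.0024971
3.98107 1e-12 0.32654 0.13949 0.0028532
4.46684 1e-12 0.33703 0.11896 0.0032386
5.01187 1e-12 0.3457 0.10046 0.0036573
5.62341 1e-12 0.35276 0.084148 0.0041143
6.30957 1e-12 0.35839 0.07003 0.0046148
7.07946 1e-12 0.36278 0.057972 0.0051644
7.94328 1e-12 0.36609 0.047773 0.0057688
8.91251 1e-12 0.36844 0.039204 0.0064338
10 1e-12 0.36996 0.032043 0.0071654
11.2202 1e-12 0.37074 0.026089 0.0079695
12.5893 1e-12 0.37087 0.021166 0.0088521
14.1254 1e-12 0.37041 0.017116 0.0098192
15.8489 1e-12 0.36941 0.013801 0.010876
17.7828 1e-12 0.36791 0.0111 0.012029
19.9526 1e-12 0.36595 0.0089082 0.013282
22.3872 1e-12 0.36354 0.0071361 0.014639
25.1189 1e-12 0.3607 0.0057079 0.016103
28.1838 1e-12 0.35743 0.0045597 0.017677
31.6228 1e-12 0.35375 0.0036388 0.01936
35.4813 1e-12 0.34964 0.0029018 0.021151
39.8107 1e-12 0.34512 0.0023131 0.023046
44.6684 1e-12 0.34018 0.0018435 0.025038
50.1187 1e-12 0.33481 0.0014694 0.02712
56.2341 1e-12 0.32903 0.001172 0.029278
63.0957 1e-12 0.32283 0.0009359 0.0315
70.7946 1e-12 0.31624 0.00074894 0.033766
79.4328 1e-12 0.30925 0.00060139 0.036058
89.1251 1e-12 0.3019 0.00048548 0.038353
100 1e-12 0.29421 0.00039507 0.040629
112.202 1e-12 0.2862 0.00032526 0.042859
125.893 1e-12 0.27792 0.00027213 0.04502
141.254 1e-12 0.26941 0.00023247 0.047087
158.489 1e-12 0.2607 0.00020364 0.049038
177.828 1e-12 0.25185 0.00018337 0.050852
199.526 1e-12 0.2429 0.00016969 0.052511
223.872 1e-12 0.23389 0.00016087 0.054
251.189 1e-12 0.22487 0.00015549 0.055307
281.838 1e-12 0.21588 0.00015238 0.056422
316.228 1e-12 0.20695 0.00015069 0.057339
354.813 1e-12 0.19812 0.00014983 0.058055
398.107 1e-12 0.18941 0.00014941 0.058567
446.684 1e-12 0.18085 0.0001492 0.058874
501.187 1e-12 0.17245 0.00014911 0.058977
562.341 1e-12 0.16422 0.00014907 0.058879
630.957 1e-12 0.15618 0.00014905 0.058583
707.946 1e-12 0.14834 0.00014904 0.058094
794.328 1e-12 0.1407 0.00014904 0.057416
891.251 1e-12 0.13326 0.00014904 0.056558
1000 1e-12 0.12604 0.00014904 0.055529
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 0.999953
0.01 0.998313
0.0130782 0.997151
0.0171039 0.995168
0.0223689 0.99179
0.0292545 0.986052
0.0382596 0.976356
0.0500366 0.960106
0.0654389 0.933254
0.0855824 0.88991
0.111926 0.822558
0.14638 0.724001
0.191438 0.592233
0.250367 0.43714
0.327435 0.28258
0.428225 0.15625
0.560042 0.0736924
0.732434 0.0307703
0.957892 0.0109136
1.25275 0.00404954
1.63837 0.00306844
2.1427 0.00233182
2.80226 0.000822281
3.66485 0.000286306
4.79297 9.89351e-05
6.26834 3.4035e-05
8.19787 1.16777e-05
10.7213 4.00049e-06
14.0216 1.36923e-06
18.3377 4.68392e-07
23.9824 1.6018e-07
31.3647 5.4768e-08
41.0194 1.8724e-08
53.646 6.40097e-09
70.1593 2.18814e-09
91.7557 7.47991e-10
120 2.55689e-10
# incoherent scattering function S(x), same x grid
@sf 37
0 1e-12
0.01 0.00897388
0.0130782 0.0152878
0.0171039 0.0259709
0.0223689 0.0439096
0.0292545 0.0736453
0.0382596 0.121875
0.0500366 0.197316
0.0654389 0.308511
0.0855824 0.45759
0.111926 0.630526
0.14638 0.79349
0.191438 0.910217
0.250367 0.970563
0.327435 0.992681
0.428225 0.998564
0.560042 0.999765
0.732434 0.999966
0.957892 0.999995
1.25275 0.999999
1.63837 1
2.1427 1
2.80226 1
3.66485 1
4.79297 1
6.26834 1
8.19787 1
10.7213 1
14.0216 1
18.3377 1
23.9824 1
31.3647 1
41.0194 1
53.646 1
70.1593 1
91.7557 1
120 1
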