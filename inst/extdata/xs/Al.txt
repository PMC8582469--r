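# element photon data: Al (Z=13)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 13
# A: 26.98154
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 1100.3 0.017926 2.2566 1100.3
1.12202 810.29 0.02127 2.2048 810.29
1.25893 595.66 0.024986 2.1452 595.66
1.41254 436.92 0.029035 2.0782 436.92
1.55882 334.39 0.03273 2.0153 334.39
1.56038 4068.5 0.032768 2.0146 4068.5
1.58489 3992.1 0.03337 2.0042 3992.1
1.77828 3072.2 0.037944 1.9242 3072.2
1.99526 2275.9 0.042729 1.8397 2275.9
2.23872 1690 0.04773 1.752 1690
2.51189 1250.3 0.052985 1.6625 1250.3
2.81838 920.84 0.05855 1.5722 920.84
3.16228 674.9 0.064478 1.4816 674.9
3.54813 491.85 0.070796 1.3908 491.85
3.98107 357.41 0.077486 1.2993 357.41
4.46684 258.95 0.084481 1.207 258.96
5.01187 187.07 0.091672 1.1132 187.07
5.62341 134.75 0.098919 1.0179 134.75
6.30957 96.771 0.10607 0.92128 96.772
7.07946 69.272 0.11297 0.82441 69.274
7.94328 49.444 0.11946 0.72901 49.446
8.91251 35.21 0.12539 0.63727 35.213
10 24.949 0.13067 0.55137 24.952
11.2202 17.649 0.13525 0.47306 17.652
12.5893 12.464 0.13919 0.40329 12.468
14.1254 8.7884 0.14254 0.34224 8.7924
15.8489 6.1862 0.14539 0.28944 6.1907
17.7828 4.3472 0.1478 0.2441 4.3523
19.9526 3.0498 0.14982 0.20535 3.0555
22.3872 2.136 0.15149 0.17241 2.1424
25.1189 1.4935 0.15283 0.14462 1.5006
28.1838 1.0423 0.15384 0.12146 1.0503
31.6228 0.72624 0.1545 0.10215 0.73508
35.4813 0.50526 0.15478 0.085976 0.51503
39.8107 0.35101 0.15464 0.072381 0.36174
44.6684 0.24348 0.15409 0.060917 0.25525
50.1187 0.16865 0.15312 0.051217 0.18147
56.2341 0.11664 0.15173 0.042981 0.13056
63.0957 0.080555 0.14997 0.035971 0.095595
70.7946 0.05555 0.14784 0.030001 0.071729
79.4328 0.03825 0.14538 0.024927 0.055576
89.1251 0.026299 0.14261 0.020633 0.044771
100 0.018055 0.13956 0.017023 0.03766
112.202 0.012378 0.13626 0.014009 0.033089
125.893 0.0084726 0.13273 0.01151 0.030254
141.254 0.0057911 0.129 0.0094507 0.028594
158.489 0.0039524 0.12512 0.0077624 0.027717
177.828 0.0026935 0.1211 0.0063838 0.02735
199.526 0.0018329 0.11699 0.0052622 0.027304
223.872 0.0012454 0.1128 0.0043531 0.027447
251.189 0.00084498 0.10858 0.0036192 0.027687
281.838 0.00057246 0.10434 0.0030297 0.02796
316.228 0.00038726 0.10011 0.0025596 0.028224
354.813 0.00026159 0.095899 0.0021879 0.028448
398.107 0.00017644 0.091736 0.0018973 0.028613
446.684 0.00011883 0.08763 0.0016726 0.028706
501.187 7.9917e-05 0.083592 0.0015006 0.028718
562.341 5.3666e-05 0.07963 0.0013699 0.028645
630.957 3.5986e-05 0.075753 0.0012707 0.028485
707.946 2.4095e-05 0.071965 0.0011952 0.028235
794.328 1.6109e-05 0.068271 0.0011371 0.027899
891.251 1.0755e-05 0.064674 0.0010924 0.027477
1000 7.1694e-06 0.061177 0.0010575 0.026974
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 12.9937
0.01 12.9699
0.0130782 12.9532
0.0171039 12.9246
0.0223689 12.8764
0.0292545 12.7954
0.0382596 12.6612
0.0500366 12.4435
0.0654389 12.1034
0.0855824 11.6022
0.111926 10.9281
0.14638 10.1287
0.191438 9.29626
0.250367 8.46565
0.327435 7.55934
0.428225 6.45574
0.560042 5.09588
0.732434 3.64864
0.957892 2.4715
1.25275 1.76207
1.63837 1.37583
2.1427 1.18991
2.80226 1.07557
3.66485 0.914911
4.79297 0.712836
6.26834 0.494485
8.19787 0.299073
10.7213 0.156993
14.0216 0.0725353
18.3377 0.0302778
23.9824 0.0117487
31.3647 0.00434194
41.0194 0.00155573
53.646 0.000546914
70.1593 0.000190076
91.7557 6.56104e-05
120 2.25563e-05
# incoherent scattering function S(x), same x grid
@sf 37
0 0.0125867
0.01 0.0598778
0.0130782 0.0931191
0.0171039 0.149303
0.0223689 0.243468
0.0292545 0.399064
0.0382596 0.650116
0.0500366 1.03951
0.0654389 1.60637
0.0855824 2.35597
0.111926 3.22994
0.14638 4.1453
0.191438 5.12197
0.250367 6.28384
0.327435 7.64284
0.428225 9.01213
0.560042 10.1599
0.732434 10.9268
0.957892 11.3432
1.25275 11.6522
1.63837 11.979
2.1427 12.33
2.80226 12.6284
3.66485 12.8087
4.79297 12.8989
6.26834 12.9491
8.19787 12.9796
10.7213 12.9939
14.0216 12.9986
18.3377 12.9998
23.9824 13
31.3647 13
41.0194 13
53.646 13
70.1593 13
91.7557 13
120 13
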