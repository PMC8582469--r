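# element photon data: P (Z=15)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 15
# A: 30.97376
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 1806 0.016115 2.6562 1806
1.12202 1333.5 0.019464 2.6001 1333.5
1.25893 982.68 0.02331 2.5341 982.68
1.41254 722.83 0.027645 2.4577 722.83
1.58489 530.7 0.03243 2.3706 530.7
1.77828 388.9 0.037598 2.2732 388.9
1.99526 284.45 0.043058 2.1666 284.45
2.14443 233.61 0.046581 2.0959 233.61
2.14657 2603.2 0.046631 2.0949 2603.2
2.23872 2382.1 0.048712 2.0525 2382.1
2.51189 1770.7 0.054477 1.9331 1770.7
2.81838 1313 0.060305 1.811 1313
3.16228 971.79 0.066193 1.6888 971.79
3.54813 716.25 0.072177 1.5687 716.25
3.98107 525.87 0.078306 1.4525 525.87
4.46684 384.35 0.084619 1.3412 384.35
5.01187 279.6 0.091114 1.2347 279.6
5.62341 202.8 0.097737 1.1322 202.8
6.30957 146.65 0.1044 1.0326 146.65
7.07946 105.72 0.11097 0.93493 105.73
7.94328 75.991 0.11733 0.83877 75.993
8.91251 54.454 0.12334 0.74463 54.457
10 38.846 0.12888 0.65375 38.848
11.2202 27.637 0.13385 0.56775 27.64
12.5893 19.627 0.1382 0.48826 19.631
14.1254 13.914 0.14191 0.41656 13.918
15.8489 9.8452 0.14502 0.35325 9.8498
17.7828 6.9537 0.14761 0.29828 6.9589
19.9526 4.9024 0.14973 0.2511 4.9081
22.3872 3.4498 0.15144 0.21088 3.4563
25.1189 2.4231 0.15277 0.17677 2.4303
28.1838 1.6974 0.15374 0.14834 1.7054
31.6228 1.1863 0.15438 0.12468 1.1951
35.4813 0.82798 0.15465 0.10488 0.83774
39.8107 0.57716 0.15455 0.088269 0.58789
44.6684 0.4018 0.15406 0.074309 0.41356
50.1187 0.27936 0.15317 0.06255 0.2922
56.2341 0.19398 0.15188 0.052615 0.20793
63.0957 0.13453 0.15019 0.044189 0.1496
70.7946 0.093172 0.14813 0.037024 0.1094
79.4328 0.064449 0.14573 0.030924 0.08184
89.1251 0.044524 0.143 0.025736 0.063071
100 0.03072 0.13999 0.021341 0.050409
112.202 0.021169 0.13671 0.017642 0.041974
125.893 0.01457 0.1332 0.014549 0.036453
141.254 0.010016 0.12949 0.011984 0.032927
158.489 0.0068767 0.12561 0.0098703 0.030756
177.828 0.0047159 0.1216 0.0081387 0.029494
199.526 0.0032303 0.11749 0.0067264 0.028828
223.872 0.0022102 0.1133 0.0055782 0.028543
251.189 0.0015106 0.10907 0.0046472 0.028487
281.838 0.0010313 0.10482 0.003894 0.028557
316.228 0.00070337 0.10058 0.0032868 0.028681
354.813 0.00047923 0.096356 0.0027999 0.028809
398.107 0.00032621 0.092179 0.0024123 0.028908
446.684 0.00022185 0.088058 0.0021066 0.028955
501.187 0.00015075 0.084003 0.0018682 0.028936
562.341 0.00010236 0.080025 0.0016846 0.02884
630.957 6.9454e-05 0.076131 0.0015445 0.028664
707.946 4.7098e-05 0.072326 0.0014387 0.028403
794.328 3.1921e-05 0.068614 0.0013581 0.028057
891.251 2.1625e-05 0.065 0.0012976 0.027628
1000 1.4646e-05 0.061486 0.0012506 0.027119
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 14.9993
0.01 14.9765
0.0130782 14.9604
0.0171039 14.9329
0.0223689 14.8863
0.0292545 14.8075
0.0382596 14.6756
0.0500366 14.4577
0.0654389 14.1068
0.0855824 13.5635
0.111926 12.7745
0.14638 11.7333
0.191438 10.5284
0.250367 9.3293
0.327435 8.27046
0.428225 7.29589
0.560042 6.16331
0.732434 4.77087
0.957892 3.33214
1.25275 2.21739
1.63837 1.58717
2.1427 1.31614
2.80226 1.21824
3.66485 1.07441
4.79297 0.881288
6.26834 0.653446
8.19787 0.426628
10.7213 0.241776
14.0216 0.119433
18.3377 0.052501
23.9824 0.0211274
31.3647 0.00799718
41.0194 0.00290885
53.646 0.00103204
70.1593 0.000360662
91.7557 0.000124901
120 4.3023e-05
# incoherent scattering function S(x), same x grid
@sf 37
0 0.0013999
0.01 0.0468733
0.0130782 0.0789567
0.0171039 0.133407
0.0223689 0.225312
0.0292545 0.37901
0.0382596 0.632022
0.0500366 1.03767
0.0654389 1.66023
0.0855824 2.55082
0.111926 3.69529
0.14638 4.96743
0.191438 6.19473
0.250367 7.35711
0.327435 8.61589
0.428225 10.0165
0.560042 11.3598
0.732434 12.4175
0.957892 13.0836
1.25275 13.4686
1.63837 13.7922
2.1427 14.1379
2.80226 14.4771
3.66485 14.7281
4.79297 14.8698
6.26834 14.9386
8.19787 14.9738
10.7213 14.9912
14.0216 14.9977
18.3377 14.9996
23.9824 14.9999
31.3647 15
41.0194 15
53.646 15
70.1593 15
91.7557 15
120 15
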