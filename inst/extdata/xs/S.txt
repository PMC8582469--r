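# element photon data: S (Z=16)
# provenance: Cromer-Liberman photoabsorption (gemmi), Klein-Nishina x S(x,Z), IT92 form factors; see tools/make_physics_tables.py
# Z: 16
# A: 32.06500
# columns: E_keV mu_photo mu_incoh mu_coh mu_en  (cm2/g)
@xs 63
1 2300.8 0.015132 2.9466 2300.8
1.12202 1700.9 0.018406 2.8895 1700.9
1.25893 1254.9 0.022221 2.8216 1254.9
1.41254 924.15 0.026594 2.742 924.15
1.58489 679.29 0.031512 2.6499 679.29
1.77828 498.38 0.036926 2.5454 498.38
1.99526 364.97 0.042749 2.429 364.97
2.23872 266.76 0.04887 2.3022 266.76
2.47076 203.62 0.054254 2.1869 203.62
2.47324 2179 0.054309 2.1857 2179
2.51189 2103.9 0.055163 2.1671 2103.9
2.81838 1573.4 0.06152 2.0267 1573.4
3.16228 1167.9 0.067874 1.8843 1167.9
3.54813 864.26 0.074206 1.743 864.27
3.98107 637.15 0.080545 1.6058 637.15
4.46684 467.92 0.086945 1.4747 467.92
5.01187 342.23 0.093445 1.3509 342.23
5.62341 249.03 0.10004 1.2344 249.04
6.30957 180.67 0.10669 1.1242 180.67
7.07946 130.68 0.11329 1.0188 130.68
7.94328 94.231 0.11973 0.91703 94.233
8.91251 67.741 0.12587 0.81825 67.743
10 48.523 0.13161 0.72276 48.526
11.2202 34.651 0.13683 0.63156 34.654
12.5893 24.667 0.14146 0.54609 24.671
14.1254 17.528 0.14545 0.46777 17.532
15.8489 12.431 0.1488 0.39766 12.435
17.7828 8.7992 0.15158 0.33618 8.8045
19.9526 6.2167 0.15385 0.28313 6.2227
22.3872 4.3838 0.15565 0.23781 4.3904
25.1189 3.0853 0.15703 0.1993 3.0927
28.1838 2.1655 0.15803 0.16724 2.1737
31.6228 1.5162 0.15867 0.14061 1.5253
35.4813 1.0603 0.15895 0.11833 1.0703
39.8107 0.74048 0.15885 0.09963 0.75152
44.6684 0.51646 0.15835 0.083925 0.52855
50.1187 0.35974 0.15746 0.070709 0.37293
56.2341 0.25024 0.15616 0.059558 0.26458
63.0957 0.17384 0.15446 0.050114 0.18935
70.7946 0.12061 0.15237 0.042088 0.13731
79.4328 0.083561 0.14993 0.035249 0.10146
89.1251 0.057817 0.14715 0.029422 0.076913
100 0.039951 0.14407 0.024469 0.060225
112.202 0.027569 0.14072 0.020279 0.048994
125.893 0.018998 0.13712 0.01676 0.041536
141.254 0.013075 0.13332 0.013828 0.036674
158.489 0.0089858 0.12934 0.011403 0.033584
177.828 0.0061673 0.12522 0.0094103 0.031692
199.526 0.0042272 0.12099 0.0077822 0.030598
223.872 0.0028935 0.11669 0.0064572 0.030023
251.189 0.0019779 0.11234 0.005382 0.029771
281.838 0.0013502 0.10797 0.0045114 0.02971
316.228 0.00092049 0.1036 0.0038078 0.029746
354.813 0.00062669 0.099259 0.0032411 0.029815
398.107 0.00042609 0.094959 0.0027871 0.029875
446.684 0.00028931 0.090716 0.002426 0.029894
501.187 0.00019618 0.086542 0.0021416 0.029855
562.341 0.00013285 0.082446 0.0019202 0.029743
630.957 8.9841e-05 0.078435 0.0017498 0.029552
707.946 6.0677e-05 0.074516 0.0016206 0.029277
794.328 4.0925e-05 0.070693 0.001522 0.028917
891.251 2.7567e-05 0.06697 0.0014485 0.028473
1000 1.8544e-05 0.06335 0.0013917 0.027946
# Rayleigh form factor F(x), x = sin(theta/2)/lambda [1/A]
@ff 37
0 15.9998
0.01 15.9783
0.0130782 15.9631
0.0171039 15.9372
0.0223689 15.8931
0.0292545 15.8184
0.0382596 15.6927
0.0500366 15.4839
0.0654389 15.1436
0.0855824 14.6069
0.111926 13.8039
0.14638 12.6972
0.191438 11.3428
0.250367 9.92008
0.327435 8.65056
0.428225 7.60374
0.560042 6.55721
0.732434 5.26381
0.957892 3.80201
1.25275 2.52245
1.63837 1.7291
2.1427 1.39008
2.80226 1.29821
3.66485 1.1609
4.79297 0.971783
6.26834 0.740587
8.19787 0.499817
10.7213 0.293365
14.0216 0.149671
18.3377 0.0675341
23.9824 0.0276982
31.3647 0.0106192
41.0194 0.0038942
53.646 0.0013886
70.1593 0.000486741
91.7557 0.000168869
120 5.82301e-05
# incoherent scattering function S(x), same x grid
@sf 37
0 0.000400537
0.01 0.0433006
0.0130782 0.0736077
0.0171039 0.12512
0.0223689 0.212298
0.0292545 0.358727
0.0382596 0.601557
0.0500366 0.995717
0.0654389 1.613
0.0855824 2.52475
0.111926 3.75267
0.14638 5.19779
0.191438 6.64095
0.250367 7.93233
0.327435 9.18291
0.428225 10.5593
0.560042 11.9547
0.732434 13.1239
0.957892 13.9183
1.25275 14.3745
1.63837 14.709
2.1427 15.0505
2.80226 15.3981
3.66485 15.6753
4.79297 15.8443
6.26834 15.928
8.19787 15.9689
10.7213 15.989
14.0216 15.997
18.3377 15.9994
23.9824 15.9999
31.3647 16
41.0194 16
53.646 16
70.1593 16
91.7557 16
120 16
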