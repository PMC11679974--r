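n_nmol,pi_mN_per_m
16.6053900099649,16.3626667205949
17.2138923117938,16.8114618010004
17.8223946136227,17.9158433468562
18.4308969154515,18.7144483131045
19.0393992172804,19.3214281647593
19.6479015191093,19.8471438809983
20.2564038209382,21.0449295626136
20.8649061227671,21.3287824621101
21.4734084245959,22.7934073543189
22.0819107264248,23.0709756137074
22.6904130282537,24.4566471242406
23.2989153300826,25.7995869177896
23.9074176319115,25.8159913643896
24.5159199337403,27.3351059580238
25.1244222355692,28.6274749145225
25.7329245373981, 30.164766716943
 26.341426839227,31.2479317545312
26.9499291410559,31.9431072860131
27.5584314428847,33.4573256148326
28.1669337447136,36.0726453655031
28.7754360465425, 37.104845155919
29.3839383483714,38.2113561867176
29.9924406502003,40.2676486956575
30.6009429520292,42.2778186739971
 31.209445253858, 44.093315103402
31.8179475556869,45.0208085603829
32.4264498575158,46.7087775938429
33.0349521593447,47.9010516173211
33.6434544611736,50.1380292064494
34.2519567630024, 49.808001537212
34.8604590648313,50.1366350369724
35.4689613666602,50.2114512011686
36.0774636684891, 50.310531056591
 36.685965970318,49.8173220873778
37.2944682721468,50.1514865369894
37.9029705739757, 49.484897396278
38.5114728758046,49.7646622974862
39.1199751776335, 49.744727721747
39.7284774794624, 49.275737705016
40.3369797812912,50.0108367820677
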