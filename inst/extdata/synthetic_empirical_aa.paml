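# Synthetic empirical-style amino-acid exchangeability matrix.
# Generated pseudo-randomly (lognormal exchangeabilities, Dirichlet-like
# frequencies); a stand-in with the statistical shape of an empirical
# model, NOT fitted to any alignment database.
# PAML order: A R N D C Q E G H I L K M F P S T W Y V
6.998544
0.141972 0.595305
1.224446 1.749299 1.233186
0.354959 1.573435 4.678669 1.204464
1.047239 1.728526 0.306438 0.919072 1.896991
12.695213 0.279487 2.114143 0.067847 0.152404 0.407394
0.810199 0.75216 3.244679 2.622658 3.373181 3.871879 1.912525
0.651478 1.403716 5.834352 0.699574 4.713195 0.871351 11.037 0.392204
5.86047 1.112696 0.255692 0.073509 0.517497 0.571386 0.232067 0.471362 0.401684
4.262744 0.389914 0.101931 0.357814 6.541231 0.543509 2.305526 4.799507 5.394675 1.971023
0.561936 0.208405 0.619274 1.403067 1.471553 1.440234 0.298025 0.311454 0.376446 0.324131 0.461977
1.074107 2.641252 2.284332 5.729673 0.499977 0.428047 0.36991 1.947677 2.446156 0.511109 1.034411 0.573632
1.060305 1.80929 0.076988 2.109174 0.616738 0.744151 0.396923 0.309714 1.044292 0.05487 0.491415 3.478707 0.694841
0.799485 2.751986 0.528348 2.233543 6.312842 8.828166 2.308927 0.308118 0.1482 0.825738 1.69482 2.125082 1.237507 0.285584
1.616833 0.367297 0.814105 0.879546 0.614721 0.640858 13.250844 0.190362 0.517368 1.613307 2.602375 3.101498 0.444529 2.633329 0.42753
0.462272 7.852754 0.258704 3.318002 5.747226 0.13811 1.838225 3.520264 0.885877 0.853033 0.145788 4.239319 1.000289 1.60142 1.706569 2.028213
2.335203 2.299549 0.367761 1.774672 1.475936 0.444847 1.418267 0.527566 0.346092 0.272157 0.115515 1.47962 1.01022 1.824023 0.355145 0.943798 4.025853
0.335687 0.969127 2.285973 1.008318 2.214102 4.710865 0.24956 0.197593 4.593256 0.246886 1.673364 0.631142 6.619731 1.651703 0.311922 1.095263 0.856885 1.409851
1.714466 3.5307 3.362022 3.45972 1.283941 0.525564 0.659551 0.766707 0.703998 1.056979 3.391251 0.418451 4.530779 1.108723 2.107355 0.922403 0.208044 0.753494 24.00957

0.0611280000000001 0.056815 0.061812 0.073364 0.052257 0.057202 0.077637 0.094489 0.026883 0.045569 0.039564 0.041756 0.037592 0.055809 0.059398 0.023816 0.014434 0.032116 0.026026 0.062333
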