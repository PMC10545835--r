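sample_id,day,mu_a,mu_s_prime
1,0,0.008,0.573
1,7,0.004,0.458
1,14,0.008,0.549
1,21,0.005,0.335
1,28,0.011,0.44
1,35,0.003,0.331
1,42,0.005,0.324
1,49,0.003,0.294
2,0,0.006,0.523
2,7,0.01,0.557
2,14,0.011,0.735
2,21,0.007,0.419
2,28,0.006,0.501
2,35,0.006,0.409
2,42,0.01,0.448
2,49,0.011,0.374
3,0,0.01,0.505
3,7,0.041,1.8
3,14,0.013,0.742
3,21,0.01,0.612
3,28,0.012,0.784
3,35,0.018,1
3,42,0.008,0.654
3,49,0.008,0.594
4,0,0.018,1
4,7,0.014,0.704
4,14,0.017,0.706
4,21,0.01,0.497
4,28,0.014,0.56
4,35,0.009,0.358
4,42,0.01,0.341
4,49,0.008,0.333
5,0,0.009,0.553
5,7,0.014,1.154
5,14,0.013,1.058
5,21,0.011,0.738
5,28,0.012,0.974
5,35,0.02,1.145
5,42,0.011,0.86
5,49,0.007,0.676
6,0,0.009,0.532
6,7,0.016,0.653
6,14,0.007,0.471
6,21,0.006,0.408
6,28,0.009,0.48
6,35,0.008,0.387
6,42,0.008,0.475
6,49,0.01,0.41
7,0,0.008,0.659
7,7,0.022,0.739
7,14,0.013,0.479
7,21,0.013,0.608
7,28,0.009,0.431
7,35,0.008,0.411
7,42,0.009,0.454
7,49,0.006,0.444
8,0,0.023,1.146
8,7,0.007,0.372
8,14,0.01,0.537
8,21,0.004,0.297
8,28,0.006,0.307
8,35,0.006,0.26
8,42,0.006,0.297
8,49,0.006,0.257
9,0,0.007,0.481
9,7,0.006,0.38
9,14,0.007,0.473
9,21,0.004,0.378
9,28,0.006,0.333
9,35,0.005,0.368
9,42,0.004,0.286
9,49,0.004,0.255
10,0,0.013,0.809
10,7,0.007,0.46
10,14,0.011,0.74
10,21,0.008,0.5
10,28,0.007,0.52
10,35,0.004,0.46
10,42,0.011,0.69
10,49,0.006,0.42
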