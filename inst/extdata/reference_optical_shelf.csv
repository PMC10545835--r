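sample_id,day,mu_a,mu_s_prime
1,0,0.015,1.011
1,1,0.021,0.965
1,3,0.011,0.796
1,5,0.011,0.512
1,7,0.01,0.471
1,9,0.012,0.709
1,11,0.018,0.713
1,13,0.007,0.426
2,0,0.008,0.73
2,1,0.007,0.34
2,3,0.006,0.333
2,5,0.004,0.243
2,7,0.005,0.289
2,9,0.005,0.358
2,11,0.006,0.292
2,13,0.006,0.25
3,0,0.008,0.664
3,1,0.009,0.668
3,3,0.011,0.534
3,5,0.008,0.456
3,7,0.007,0.43
3,9,0.01,0.503
3,11,0.008,0.435
3,13,0.008,0.456
4,0,0.009,0.753
4,1,0.011,0.959
4,3,0.01,0.584
4,5,0.006,0.426
4,7,0.011,0.712
4,9,0.011,0.552
4,11,0.01,0.553
4,13,0.011,0.547
5,0,0.011,0.89
5,1,0.007,0.506
5,3,0.008,0.475
5,5,0.007,0.436
5,7,0.005,0.532
5,9,0.008,0.391
5,11,0.008,0.349
5,13,0.005,0.386
6,0,0.008,0.638
6,1,0.014,0.704
6,3,0.015,0.662
6,5,0.011,0.529
6,7,0.008,0.484
6,9,0.007,0.411
6,11,0.007,0.45
6,13,0.008,0.583
7,0,0.013,0.831
7,1,0.011,0.567
7,3,0.008,0.457
7,5,0.007,0.483
7,7,0.009,0.482
7,9,0.008,0.437
7,11,0.007,0.374
7,13,0.008,0.395
8,0,0.011,0.757
8,1,0.01,0.629
8,3,0.005,0.575
8,5,0.008,0.681
8,7,0.005,0.421
8,9,0.013,0.583
8,11,0.011,0.689
8,13,0.012,0.62
9,0,0.011,0.707
9,1,0.007,0.471
9,3,0.01,0.532
9,5,0.007,0.394
9,7,0.01,0.441
9,9,0.007,0.38
9,11,0.006,0.437
9,13,0.008,0.336
10,0,0.011,0.76
10,1,0.012,0.621
10,3,0.01,0.661
10,5,0.009,0.51
10,7,0.011,0.596
10,9,0.009,0.497
10,11,0.008,0.454
10,13,0.009,0.508
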