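"experiment_id","dataset","run","accuracy"
1,"training",1,0.9777
1,"training",2,0.9796
1,"training",3,0.9792
1,"preliminary_test",1,0.8045
1,"preliminary_test",2,0.8066
1,"preliminary_test",3,0.7927
2,"training",1,0.985
2,"training",2,0.9864
2,"training",3,0.9872
2,"preliminary_test",1,0.7916
2,"preliminary_test",2,0.7943
2,"preliminary_test",3,0.805
3,"training",1,0.9211
3,"training",2,0.9218
3,"training",3,0.9216
3,"preliminary_test",1,0.7477
3,"preliminary_test",2,0.7483
3,"preliminary_test",3,0.7483
4,"training",1,0.7892
4,"training",2,0.7888
4,"training",3,0.7893
4,"preliminary_test",1,0.6508
4,"preliminary_test",2,0.6508
4,"preliminary_test",3,0.6508
5,"training",1,0.9533
5,"training",2,0.9538
5,"training",3,0.9535
5,"preliminary_test",1,0.7783
5,"preliminary_test",2,0.7809
5,"preliminary_test",3,0.7788
6,"training",1,0.864
6,"training",2,0.8639
6,"training",3,0.8647
6,"preliminary_test",1,0.6909
6,"preliminary_test",2,0.6904
6,"preliminary_test",3,0.6888
7,"training",1,0.985
7,"training",2,0.9877
7,"training",3,0.985
7,"preliminary_test",1,0.8056
7,"preliminary_test",2,0.8013
7,"preliminary_test",3,0.7965
8,"training",1,0.9056
8,"training",2,0.9057
8,"training",3,0.9064
8,"preliminary_test",1,0.7268
8,"preliminary_test",2,0.7327
8,"preliminary_test",3,0.7338
9,"training",1,0.9796
9,"training",2,0.9831
9,"training",3,0.9831
9,"preliminary_test",1,0.7954
9,"preliminary_test",2,0.7868
9,"preliminary_test",3,0.7563
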