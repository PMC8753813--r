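"model","accuracy_train","accuracy_test"
"model-8249(#1)",0.9881,0.8249
"model-8184(#2)",0.9856,0.8184
"model-8452(#3)",0.9872,0.8452
"model-8125(#4)",0.9893,0.8125
"model-8061(#5)",0.9841,0.8061
"model-8281(#6)",0.9848,0.8281
"model-8307(#7)",0.9811,0.8307
"model-8002(#8)",0.9877,0.8002
"model-8216(#9)",0.9859,0.8216
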