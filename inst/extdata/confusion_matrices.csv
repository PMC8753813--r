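"model","kind","ensemble_size","tp","fp","fn","tn"
"model-8249(#1)","individual",NA,1095,203,124,445
"model-8184(#2)","individual",NA,1047,167,172,481
"model-8452(#3)","individual",NA,1114,184,105,464
"model-8125(#4)","individual",NA,1078,209,141,439
"model-8061(#5)","individual",NA,1030,173,189,475
"model-8281(#6)","individual",NA,1114,216,105,432
"model-8307(#7)","individual",NA,1090,187,129,461
"model-8002(#8)","individual",NA,1032,186,187,462
"model-8216(#9)","individual",NA,1099,213,120,435
"ensemble-3","ensemble",3,1104,182,115,466
"ensemble-5","ensemble",5,1100,173,119,475
"ensemble-7","ensemble",7,1116,176,103,472
"ensemble-9","ensemble",9,1118,177,101,471
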