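Optimizer: [adam, sgdm, adam]
MiniBatchSize: [60, 65, 70]
MaxEpochs: [8, 10, 12]
InitialLearnRate: [1.0e-4, 1.0e-5, 1.0e-6]
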