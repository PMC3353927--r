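# fig10_pectin_sine simulation scenario
preset: fig10_pectin_sine
duration: 3000
record_stride: 5
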