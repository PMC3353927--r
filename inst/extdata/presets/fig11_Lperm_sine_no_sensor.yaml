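# fig11_Lperm_sine_no_sensor simulation scenario
preset: fig11_Lperm_sine_no_sensor
duration: 3000
record_stride: 5
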