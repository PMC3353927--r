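# custom scenario: simultaneous medium dilution and halved hardening
duration: 2500
record_stride: 5
scenario:
  A_mem_mode: osmotic_zone
  perturbations:
    - parameter: C_o
      shape: step
      onset: 600
      value: 0.25
    - parameter: alpha
      shape: step
      onset: 600
      value: 3.0
sensor: true
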