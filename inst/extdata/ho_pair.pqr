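ATOM      1  OE1 GLU A   1     0.0000  0.0000  0.0000  -0.8200  1.5000
TER
ATOM      2  HH11 ARG B   2     1.5700  0.0000  0.0000   0.4500  1.2000
TER
END
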