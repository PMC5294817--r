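>DR3_half_site_RGKTSA
A [     0.425      0.05     0.075      0.05     0.075      0.85 ]
C [     0.075      0.05     0.075      0.05     0.425      0.05 ]
G [     0.425      0.85     0.425      0.05     0.425      0.05 ]
T [     0.075      0.05     0.425      0.85     0.075      0.05 ]
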