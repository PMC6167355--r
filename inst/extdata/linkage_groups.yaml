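LG1: [DXS10148, DXS10135, DXS8378]
LG2: [DXS10159, DXS10162, DXS10164]
LG3: [DXS7132, DXS10079, DXS10074, DXS10075]
LG4: [DXS6809, DXS6789]
LG5: [DXS7424, DXS101]
LG6: [DXS10103, HPRTB, DXS10101]
LG7: [DXS10134, DXS7423]
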