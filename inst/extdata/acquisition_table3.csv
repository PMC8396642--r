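compound,precursor_mz,scan_range,nce_pct
bemethyl,179.0638,50-200,35
M1,151.0325,50-170,55
M2,195.0587,50-215,35
M3,227.0485,50-250,35
M4,275.0155,50-300,35
M5,280.0689,50-305,35
M6,371.0908,50-395,35
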