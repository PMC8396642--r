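role,compound,rt_min,mz,printed_formula,rel_intensity_pct,parent_compound,scan_range,nce_pct
precursor,bemethyl,10.70,179.0638,C9H10N2S+H,100,,50-200,35
product,bemethyl,10.70,151.0324,C7H6N2S,,bemethyl,50-200,35
product,bemethyl,10.70,93.0581,C6H7N,,bemethyl,50-200,35
product,bemethyl,10.70,118.0531,C7H6N2,,bemethyl,50-200,35
precursor,M1a,9.40,151.0325,C7H6N2S+H,100,,50-170,55
product,M1a,9.40,92.04948,C6H6N,4,M1a,50-170,55
product,M1a,9.40,93.0581,C6H7N,29,M1a,50-170,55
product,M1a,9.40,118.0531,C7H6N2,14,M1a,50-170,55
product,M1a,9.40,119.0604,C7H7N2,5,M1a,50-170,55
precursor,M1b,11.01,151.0325,C7H6N2S+H,100,,50-170,55
product,M1b,11.01,92.04948,C6H6N,4,M1b,50-170,55
product,M1b,11.01,93.0581,C6H7N,29,M1b,50-170,55
product,M1b,11.01,118.0531,C7H6N2,14,M1b,50-170,55
product,M1b,11.01,119.0604,C7H7N2,5,M1b,50-170,55
precursor,M2a,9.13,195.0587,C9H10N2OS+H,100,,50-215,35
product,M2a,9.13,134.0483,C7H6N2O,5,M2a,50-215,35
product,M2a,9.13,166.0195,C7H6N2OS,12,M2a,50-215,35
product,M2a,9.13,167.0278,C7H7N2OS,94,M2a,50-215,35
precursor,M2b,11.42,195.0587,C9H10N2OS+H,100,,50-215,35
product,M2b,11.42,149.0168,C7H5N2S,42,M2b,50-215,35
product,M2b,11.42,167.0279,C7H7N2OS,100,M2b,50-215,35
precursor,M3a,9.26,227.0485,C9H10N2O3S+H,100,,50-250,35
product,M3a,9.26,199.0170,C7H7N2O3S,18,M3a,50-250,35
product,M3a,9.26,181.0066,C7H5N2O2S,100,M3a,50-250,35
product,M3a,9.26,153.0117,C6H5N2OS,7,M3a,50-250,35
product,M3a,9.26,135.0553,C7H7N2O,13,M3a,50-250,35
precursor,M3b,10.51,227.0485,C9H10N2O3S+H,100,,50-250,35
product,M3b,10.51,199.0170,C7H7N2O3S,18,M3b,50-250,35
product,M3b,10.51,181.0066,C7H5N2O2S,100,M3b,50-250,35
product,M3b,10.51,153.0117,C6H5N2OS,7,M3b,50-250,35
product,M3b,10.51,135.0553,C7H7N2O,13,M3b,50-250,35
precursor,M4,9.14,275.0155,C9H10N2O4S2+H,100,,50-300,35
product,M4,9.14,195.0587,C9H11N2OS,,M4,50-300,35
product,M4,9.14,167.0274,C7H7N2OS,,M4,50-300,35
precursor,M5,9.37,280.0689,C12H13N3O3S+H,100,,50-305,35
product,M5,9.37,151.0325,C7H7N2S,,M5,50-305,35
product,M5,9.37,130.0499,C5H8NO3,,M5,50-305,35
product,M5,9.37,88.0393,C3H6NO2,,M5,50-305,35
product,M5,9.37,84.0443,C4H6NO,,M5,50-305,35
precursor,M6,8.21,371.0908,C15H18N2O7S+H,0.2,,50-395,35
product,M6,8.21,195.0587,C9H11N2OS,100,M6,50-395,35
product,M6,8.21,167.0274,C7H7N2OS,10,M6,50-395,35
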