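from,from_formula,to,to_formula,rule,enzymes,score
bemethyl,C9H10N2S,M2a,C9H10N2OS,S-oxidation,"CYP1A2, CYP2A6, CYP2B6, CYP2C9, CYP3A4",4.20
bemethyl,C9H10N2S,M2b,C9H10N2OS,aromatic hydroxylation,"CYP1A2, CYP2A6, CYP2B6, CYP2C9, CYP2C19, CYP3A4",2.49
bemethyl,C9H10N2S,T1,C9H10N2OS,alpha-carbon hydroxylation,,2.11
bemethyl,C9H10N2S,vinyl,C9H8N2S,vinyl desaturation,,0.42
M2a,C9H10N2OS,T2,C9H10N2O2S,sulfoxide oxidation,"CYP2C9, CYP3A4",4.14
T2,C9H10N2O2S,M3b,C9H10N2O3S,aromatic hydroxylation,"CYP1A2, CYP2C9, CYP2C19, CYP3A4",2.52
M2a,C9H10N2OS,HOSO-a,C9H10N2O2S,aromatic hydroxylation,,2.54
HOSO-a,C9H10N2O2S,M3b,C9H10N2O3S,sulfoxide oxidation,,2.52
M2b,C9H10N2OS,HOSO-b,C9H10N2O2S,S-oxidation,,3.87
HOSO-b,C9H10N2O2S,M3b,C9H10N2O3S,sulfoxide oxidation,,3.87
M2b,C9H10N2OS,C16,C9H10N2O2S,aromatic hydroxylation,,2.15
C16,C9H10N2O2S,M3a,C9H10N2O3S,aromatic hydroxylation,,1.81
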