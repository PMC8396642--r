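name,formula
bemethyl,C9H10N2S
triclabendazole,C14H9Cl3N2OS
afobazole,C15H21N3O2S
pantoprazole,C16H15F2N3O4S
omeprazole,C17H19N3O3S
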