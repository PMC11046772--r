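MODULE water
    TIMESCALE 1
    SCOPE s (0, 0)
        MARKING(H2_molecule, 4)
        MARKING(O2_molecule, 2)
        PROCESS reaction
            TIMESCALE 1
            CUSTOM_PROCESS(2*H2_molecule + O2_molecule -> 2*H2O_molecule)
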