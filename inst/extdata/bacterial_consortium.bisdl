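MODULE bacterialConsortium
    TIMESCALE 1
    SCOPE producer (0, 0)
        MARKING(LuxI_gene, 1)
        MARKING(SAM_molecule, 5)
        MARKING(ACP_molecule, 5)
        PROCESS AHL_production
            TIMESCALE 2
            TRANSCRIPTION(LuxI_gene, LuxI_mRNA) INHIBITORS(LacI_protein)
            TRANSLATION(LuxI_mRNA, LuxI_protein)
            DEGRADATION(LuxI_mRNA)
            DEGRADATION(LuxI_protein)
            ENZYMATIC_REACTION(LuxI_protein, SAM_molecule + ACP_molecule -> 3*AHL_molecule)
        PROCESS substrate_supply
            TIMESCALE 1
            CUSTOM_PROCESS( -> SAM_molecule + ACP_molecule)
            DEGRADATION(LacI_protein)
        PARACRINE_SIGNAL(AHL_molecule, emit)
    SCOPE sensor (0, 1)
        MARKING(GFP_gene, 1)
        PROCESS GFP_production
            TIMESCALE 3
            TRANSCRIPTION(GFP_gene, GFP_mRNA) INDUCERS(AHL_molecule)
            TRANSLATION(GFP_mRNA, GFP_reporter_protein)
            DEGRADATION(GFP_mRNA)
            DEGRADATION(AHL_molecule)
        PARACRINE_SIGNAL(AHL_molecule, receive)
    DIFFUSION(AHL_molecule, producer, sensor, bidirectional)
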