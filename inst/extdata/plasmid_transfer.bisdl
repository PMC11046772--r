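MODULE plasmidTransfer
    TIMESCALE 1
    SCOPE donor (0, 0)
        MARKING(R_plasmid_gene, 1)
        PROCESS pilus_expression
            TIMESCALE 1
            TRANSCRIPTION(R_plasmid_gene, Pilus_mRNA)
            TRANSLATION(Pilus_mRNA, Pilus_protein)
            DEGRADATION(Pilus_mRNA)
        PROCESS R_expression
            TIMESCALE 1
            TRANSCRIPTION(R_plasmid_gene, R_mRNA)
            TRANSLATION(R_mRNA, R_protein)
        PROCESS strand_replication
            TIMESCALE 2
            CUSTOM_PROCESS(R_plasmid_gene -> R_plasmid_gene + R_plasmid_ss_gene) ACTIVATORS(Pilus_protein)
        PROCESS strand_circularization
            TIMESCALE 2
            CUSTOM_PROCESS(R_plasmid_ss_gene -> R_plasmid_gene)
        JUXTACRINE_SIGNAL(R_plasmid_ss_gene, emit, pilus)
    SCOPE pilus (0, 1)
        JUXTACRINE_SIGNAL(R_plasmid_ss_gene, receive, donor)
        JUXTACRINE_SIGNAL(R_plasmid_ss_gene, emit, transconjugant)
    SCOPE transconjugant (0, 2)
        PROCESS strand_circularization
        PROCESS R_expression
        JUXTACRINE_SIGNAL(R_plasmid_ss_gene, receive, pilus)
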