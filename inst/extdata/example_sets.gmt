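mito_membrane	synthetic example set	GENE01	GENE02	GENE03	GENE04	GENE05
antigen_presentation	synthetic example set	GENE06	GENE07	GENE08	GENE09	GENE10	GENE11	GENE12
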