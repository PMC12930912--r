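sample_id	group
biopsy_01	IBM
biopsy_02	IBM
biopsy_03	IBM
biopsy_04	NDC
biopsy_05	NDC
biopsy_06	NDC
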