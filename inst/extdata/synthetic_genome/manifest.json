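{"seed":20,"genome_id":"sim","n_proteins":25}
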