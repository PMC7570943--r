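organism,ligand,dg_bind
Homo sapiens,Rofecoxib,-48.15
Homo sapiens,Z814,-45.51
Homo sapiens,Z627,-42.76
Mus musculus,Celecoxib,-47.78
Mus musculus,Z627,-41.63
Mus musculus,Z964,-44.27
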