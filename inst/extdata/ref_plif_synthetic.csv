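residue_id,bit
LEU70,1
VAL75,1
LEU78,1
LEU129,1
ASP156,1
LEU157,1
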