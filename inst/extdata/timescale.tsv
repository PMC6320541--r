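period	older_ma	younger_ma
Cambrian	541	485.4
Ordovician	485.4	443.8
Silurian	443.8	419.2
Devonian	419.2	358.9
Carboniferous	358.9	298.9
Permian	298.9	251.9
Triassic	251.9	201.3
Jurassic	201.3	145
Cretaceous	145	66
Paleogene	66	23.03
Neogene	23.03	0
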