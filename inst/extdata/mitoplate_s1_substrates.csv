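substrate,category
L-Malate,TCA cycle
D-Malate,TCA cycle
Succinate,TCA cycle
Fumarate,TCA cycle
Citrate,TCA cycle
Isocitrate,TCA cycle
cis-Aconitate,TCA cycle
a-Keto-Glutarate,TCA cycle
Pyruvate,glycolysis end product
L-Lactate,glycolysis end product
D-Lactate,glycolysis end product
L-Glutamate,amino acid
L-Glutamine,amino acid
L-Alanine,amino acid
L-Serine,amino acid
a-Glycerol-Phosphate,glycerol shuttle
Acetyl-L-Carnitine,fatty acid shuttle
Octanoyl-L-Carnitine,fatty acid shuttle
Palmitoyl-L-Carnitine,fatty acid shuttle
b-Hydroxy-Butyrate,ketone body
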