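substrate,category
D-Glucose,hexose
D-Glucose-6-Phosphate,phosphorylated sugar
D-Fructose,hexose
D-Fructose-6-Phosphate,phosphorylated sugar
D-Galactose,hexose
D-Mannose,hexose
D-Ribose,pentose
D-Xylose,pentose
Maltose,disaccharide
Sucrose,disaccharide
D-Trehalose,disaccharide
Dextrin,glucan
Glycogen,glucan
Pyruvate,carboxylic acid
L-Lactate,carboxylic acid
Acetate,carboxylic acid
L-Glutamine,amino acid
L-Glutamate,amino acid
Inosine,nucleoside
Adenosine,nucleoside
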