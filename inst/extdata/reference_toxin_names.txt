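δ-Paraponeritoxin-Pc1e_1
δ-Paraponeritoxin-Pc1e_2
δ-Paraponeritoxin-Pc1e_3
δ-Paraponeritoxin-Pc1e_4
δ-Paraponeritoxin-Pc1e_5
δ-Paraponeritoxin-Pc1e_6
Phospholipase-A2-1a_1-P-clavata
Phospholipase-A2-1a_2-P-clavata
Translationally-controlled-tumor-protein-1a-P-clavata
Icarapin-1a-P-clavata
Serine-protease-1a-P-clavata
Serine-protease-1b-P-clavata
Serine-protease-2a-P-clavata
Serine-protease-3a-P-clavata
Serine-protease-4a-P-clavata
Serine-protease-5a-P-clavata
Serine-protease-6a-P-clavata
Serine-protease-7a-P-clavata
Serine-protease-8a-P-clavata
Arginine-kinase-1a_1-P-clavata
Arginine-kinase-1a_2-P-clavata
U_1_-Paraponeritoxin-Pc1a
Venom-allergen3-1a-P-clavata
Venom-allergen3-1b-P-clavata
Cysteine-rich protein-1a-P-clavata
Disintegrin-and-metalloproteinase-domain-containing-protein-1a-P-clavata
Disintegrin-and-metalloproteinase-domain-containing-protein-2a-P-clavata
Lysosomal-aspartic-protease-1a-P-clavata
Defensin-2-like-1a-P-clavata
Serine-protease-inhibitor-1a-P-clavata
Cathepsin-L-1a-P-clavata
Hyalyronidase-1a_1-P-clavata
Hyalyronidase-1a_2-P-clavata
Hyalyronidase-1a_3-P-clavata
Hyalyronidase-1a_4-P-clavata
Hyalyronidase-1a_5-P-clavata
Hyalyronidase-1a_6-P-clavata
Hyalyronidase-1a_7-P-clavata
Hyalyronidase-1a_8-P-clavata
Venom-dipeptidyl-peptidase-1a_1-P-clavata
Venom-dipeptidyl-peptidase-1a_2-P-clavata
Carboxypeptidase-Q-1a_1-P-clavata
Carboxypeptidase-Q-1a_2-P-clavata
Pancreatic-lipase-1a-P-clavata
Pancreatic-lipase-1b-P-clavata
Matrix-metalloproteinase-14-like-1a-P-clavata
Matrix-metalloproteinase-14-like-2a-P-clavata
Alaserpin-X5-like-1a-P-clavata
Pancreatic-triacylglycerol-lipase-X1-like-1a-P-clavata
Pancreatic-triacylglycerol-lipase-X1-like-2a-P-clavata
Pancreatic-triacylglycerol-lipase-X1-like-3a-P-clavata
Venom-acid-phosphatase-1a-P-clavata
Iron-zinc-purple-acid phosphatase-like-1a_1-P-clavata
Iron-zinc-purple-acid phosphatase-like-1a_2-P-clavata
Alkaline-phosphatase-1a_1-P-clavata
Alkaline-phosphatase-1a_2-P-clavata
Neprilysin-11-isoform-X2-1a_1-P-clavata
Neprilysin-11--isoform-X2-1a_2-P-clavata
Protein-5NUC-1a-P-clavata
Cytosolic-dipeptidase-1a-P-clavata
Phenoloxidase-2-like-1a-P-clavata
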