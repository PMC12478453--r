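"wavenumber_cm1","metabolite","vibrational_mode"
621,"Phenylalanine","C-C twisting mode"
643,"Proline","C-C twisting mode, skeletal stretching vibration"
671,"DNA bases","C-S stretching mode"
701,"Cholesterol","Choline group, CH2 rocking, cholesterol ring deformation"
719,"Phosphatidylcholine (PC)/sphingomyelin","Symmetric stretch vibration of choline group"
744,"Thymine (DNA base)","Backbone vibrations, deformation of the ring"
757,"Tryptophan","Symmetric breathing of tryptophan, sigma(ring)"
805,"DNA/RNA","C'-O-P-O-C'3 phosphodiester stretching"
828,"Tyrosine","Out-of-plane ring breathing"
852,"Sugars (glucose, glycerol)","C-O-C skeletal stretching"
878,"Glutamic acid","COOH deformation"
898,"Glycine","C-C stretching"
938,"Citric acid, Succinic acid","v(OH...O) out of plane wagging vibration of hydrogen bonds"
957,"Fatty acid","C-H bending"
992,"Arginine","C-N stretching, C-C stretching"
1002,"Phenylalanine","Symmetric in-plane ring breathing"
1011,"Carbohydrates","C-O-C ring, C-O-H bending"
1031,"Phenylalanine","C-H in-plane bending, ring in-plane bending"
1051,"Glucose/glycerol","C-O stretching"
1063,"Lipids","Chain C-C stretching"
1082,"Lipids","Chain C-C stretching"
1103,"Mannose","sigma(CH2) twisting vibrations"
1126,"Glucose","C-C stretching, C-O stretching, C-O-H in-plane bending"
1155,"Carotenoids","C-C stretching, C-H stretching"
1172,"Saturated long-chain fatty acids","C-C stretching"
1207,"Amino acids","NH3 asymmetric rocking"
1249,"Amide III","Asymmetric O-P-O stretching"
1257,"Unsaturated lipids, fatty acids","CH3/CH2 twisting and wagging"
1268,"Unsaturated lipids, fatty acids","CH3/CH2 twisting and wagging"
1314,"Histidine","NH3+ asymmetric rocking, C-C-H stretching"
1338,"Threonine","C-H deformation"
1448,"Lipids and proteins","CH2 and CH2CH3 bending, scissoring, and deformation"
1518,"Carotenoids","C-C stretching and C=C stretching"
1552,"Tryptophan","Indole ring stretching, C=C stretching"
1575,"DNA & NADH","Ring breathing modes"
1585,"Phenylalanine","C-C bending"
1605,"Phenylalanine","C=O stretching, C=C in-plane bending"
1615,"Tyrosine","C=C stretching"
1657,"Unsaturated lipids, PC, phosphatidylethanolamine","C=C stretching"
1682,"Amide I","C=O stretching"
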