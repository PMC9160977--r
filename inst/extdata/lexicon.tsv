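term	role	maps_to
aspartate	aa_synonym	D
glutamate	aa_synonym	E
amber	stop_name	*
ochre	stop_name	*
opal	stop_name	*
substitution	sub_noun	
replacement	sub_noun	
change	sub_noun	
mutation	sub_noun	
exchange	sub_noun	
substituted	sub_verb	
replaced	sub_verb	
changed	sub_verb	
exchanged	sub_verb	
mutated	sub_verb	
codon	pos_word	
residue	pos_word	
position	pos_word	
amino acid	pos_word	
deletion	indel_del	
insertion	indel_ins	
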