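lemma	pos	frequency
sein	verb	70
sein	verb	50
sein	pronoun	80
haus	noun	12
gehen	verb	45
schnell	adverb	18
baum	noun	7
reden	verb	21
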