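>pep1 worked-example 15-mer binding peptide
FSNYAIHWVRQAPGQ
>pep2 single-substitution variant (S2T) sharing all three TCEMs
FTNYAIHWVRQAPGQ
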