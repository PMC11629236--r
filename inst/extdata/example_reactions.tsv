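id	stoichiometry	reversibility
rxn00148	-1:cpd00020:c;-1:cpd00003:c;1:cpd00022:c;1:cpd00004:c;1:cpd00011:c	>
rxn00248	-1:cpd00032:c;-1:cpd00004:c;1:cpd00130:c;1:cpd00003:c	=
rxn05145	-1:cpd00027:e;1:cpd00027:c	>
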