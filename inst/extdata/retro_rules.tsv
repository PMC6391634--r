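# Retrosynthetic (RECAP-style) bond environment rules for RMMP generation.
# One rule per line: rule_id<TAB>pattern. A pattern 'SIDE-SIDE' describes the
# two atoms of a cuttable acyclic single bond; lowercase symbols match
# aromatic atoms, '{...}' lists neighbor conditions (<bond><element>).
# This inventory is a configurable stand-in for published RECAP rule sets;
# replace the file to use a different rule inventory.
amide	C{=O}-N
ester	C{=O}-O
sulfonamide	S{=O}-N
amine	C-N
ether	C-O
thioether	C-S
biaryl	c-c
aryl_amine	n-C
aniline	c-N
aryl_ether	c-O
allylic	C{=C}-C
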