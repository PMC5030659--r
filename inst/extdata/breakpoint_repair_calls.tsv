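# Breakpoint repair verdicts of the nine rearrangement strains isolated in
# the lig-4 mutant background with targeting vectors: one strain carried
# complete targeting-vector copies at both breakpoints (HR), one carried a
# complete copy at one breakpoint and an indel at the other, and the
# remaining seven had indels at both breakpoints (end joining). Strains
# other than tmIn26 and tmT3 are listed under positional labels.
strain	breakpoint	verdict
tmIn26	left	HR
tmIn26	right	HR
tmT3	left	HR
tmT3	right	end_joining
strain_3	left	end_joining
strain_3	right	end_joining
strain_4	left	end_joining
strain_4	right	end_joining
strain_5	left	end_joining
strain_5	right	end_joining
strain_6	left	end_joining
strain_6	right	end_joining
strain_7	left	end_joining
strain_7	right	end_joining
strain_8	left	end_joining
strain_8	right	end_joining
strain_9	left	end_joining
strain_9	right	end_joining
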