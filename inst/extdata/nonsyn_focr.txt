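# Alternate nonsynonymous Variant_Classification set (TMB harmonization
# style). Edit to taste; one classification per line.
Missense_Mutation
Nonsense_Mutation
Frame_Shift_Del
Frame_Shift_Ins
In_Frame_Del
In_Frame_Ins
Splice_Site
Nonstop_Mutation
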