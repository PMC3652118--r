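DN,TN,HN,PN,R,consequent
small,clear,regular,null,negative,normal
small,medium,regular,null,negative,normal
small,dark,regular,null,negative,normal
small,clear,regular,few,negative,normal
small,medium,regular,few,negative,normal
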