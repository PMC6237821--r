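# variants excluded for lack of clinical data, plus the double mutation in cis
p.Arg104Leu
p.Thr105Ala
p.Thr105LeufsX2 + p.Phe223Tyr
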