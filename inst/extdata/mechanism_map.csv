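position,category
104,dimerization
127,hydrolysis
165,dimerization
210,closure
244,unknown
250,closure
251,unknown
259,dimerization
274,dimerization
276,dimerization
277,gtp_site_rearrangement
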