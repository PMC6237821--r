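pair_id,pos_a,code_a,domain_a,pos_b,code_b,domain_b,note
1,210,Asp,GTPase,476,Arg,HR2,tightens paddle domain
2,243,Lys,GTPase,480,Asp,HR2,tightens paddle domain
3,250,Arg,GTPase,598,Glu,HR2,tightens HR2 domain
4,542,Glu,HR2,732,Lys,HR1,tightens HR2 domain
5,377;370,Asp;Glu,HR1,564,Arg,HR2,tightens HR1 domain
6,359,Glu,HR1,575,Arg,HR2,tightens HR1 domain
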