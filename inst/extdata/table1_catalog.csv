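protein_change,nt_change,refs
p.Arg104Gln,c.311 G > A,R27
p.Arg104Trp,c.310 C > T,R15;R25;R26;R28-R30
p.Gly127Asp,c.380 G > A,R2
p.Gly127Val,c.380 G > T,R35
p.His165Arg,c.494 A > G,R2;R3;R22
p.His165Asp,c.493 C > G,R21;R24
p.His165Leu + ALS,c.494 A > T,R23
p.His165Tyr,c.493 C > T,R3
p.Asp210Val,c.629 A > T,R12
p.Asp210Tyr,c.628 G > T,R36
p.Val244Leu,c.730 G > C,R40
p.Val244Met,c.730 G > A,R15;R39
p.Arg250Gln,c.749 G > A,R3;R37
p.Arg250Trp + Arg400* + Arg476*,c.748 C > T,R3;R38
p.Pro251Ala,c.751 C > G,R31
p.Pro251Arg,c.752 C > G,R37;R41
p.Pro251Leu,c.752 C > T,R42
p.Arg259Cys,c.775 C > T,R17
p.Arg259Leu,c.776 G > T,R18
p.Arg259His,c.776 G > C,R19
p.Arg274Gln,c.821 G > A,R31
p.Arg274Trp,c.820 C > T,R1
p.Gln276Arg,c.827 A > G,R32
p.Gln276His,c.828 G > C,R33
p.His277Arg,c.830 A > G,R3
p.His277Tyr,c.829 C > T,R15
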