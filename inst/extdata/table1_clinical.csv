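mutation,onset_age,onset_categories,asymptomatic,major_features,minor_features,score_min,score_max
p.Arg104Gln,,,1,,,0,0
p.Arg104Trp,1-10,early;classical,0,pyramidal_signs;optic_atrophy;mental_retardation,other_minor,5.5,6
p.Gly127Asp,16,classical,0,pyramidal_signs,,3,3
p.Gly127Val,6-62,late;classical,0,,,0.5,1
p.His165Arg,6-16,classical,0,subcortical_mri_lesions,sensorineural_hearing_loss,2,2
p.His165Asp,4-20,classical;early,0,pyramidal_signs,,3,3.5
p.His165Leu,14,classical,0,,,1,1
p.His165Tyr,12,classical,0,,,1,1
p.Asp210Val,1.5,early,0,pyramidal_signs;optic_atrophy,cerebellar_ataxia;hearing_impairment;cataracts;learning_difficulties;mitochondrial_myopathy,7,7
p.Asp210Tyr,0.5,early,0,pyramidal_signs;optic_atrophy;mental_retardation,microcephaly;tremor;sensorineural_hearing_loss,7,7
p.Val244Leu,4,early,0,,periventricular_leukomalacia,2,2
p.Val244Met,<5,early,0,,,1.5,1.5
p.Arg250Gln,12-21,late;classical,0,,,0.5,1
p.Arg250Trp,4-10,classical;early,0,,,1,1.5
p.Pro251Ala,8-50,classical,0,,tremor,1.5,1.5
p.Pro251Arg,1-2,early,0,wheelchair_bound,,2.5,2.5
p.Pro251Leu,25,late,0,,,0.5,0.5
p.Arg259Cys,>30,late,0,sudden_visual_loss,,2,2
p.Arg259Leu,19,classical,0,mild_pyramidal_signs,,2.5,2.5
p.Arg259His,17,classical,0,,,1,1
p.Arg274Gln,11-35,classical,0,,,1,1
p.Arg274Trp,10,classical,0,mental_retardation,reduced_motor_ncv;proximal_weakness,3,3
p.Gln276Arg,10,classical,0,optic_atrophy,,2,2
p.Gln276His,9,classical,0,optic_atrophy,,2,2
p.His277Arg,<15,classical,0,,,1,1
p.His277Tyr,<10,classical,0,pyramidal_signs,vasomotor_troubles,3.5,3.5
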