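feature_id,points,category
onset_early,1.5,onset
onset_classical,1,onset
onset_late,0.5,onset
pyramidal_signs,2,major
mild_pyramidal_signs,1.5,major
sudden_visual_loss,1.5,major
optic_atrophy,1,major
mental_retardation,1,major
wheelchair_bound,1,major
subcortical_mri_lesions,0.5,major
hearing_impairment,0.5,minor
sensorineural_hearing_loss,0.5,minor
cerebellar_ataxia,0.5,minor
vasomotor_troubles,0.5,minor
tremor,0.5,minor
cataracts,0.5,minor
learning_difficulties,0.5,minor
mitochondrial_myopathy,0.5,minor
microcephaly,0.5,minor
periventricular_leukomalacia,0.5,minor
proximal_weakness,0.5,minor
reduced_motor_ncv,0.5,minor
other_minor,0.5,minor
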