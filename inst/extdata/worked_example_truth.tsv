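eye_id	patient_id	band	true_loss_mm2
P01_OD	P01	ELM_MZ	2.34834050855837
P01_OD	P01	EZ	3.26725635973339
P01_OD	P01	RPE	1.5707963267949
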