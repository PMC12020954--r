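{"n_ascans":64,"n_bscans":9,"fov_deg":20,"mm_per_deg":0.293,"bscan_spacing_um":732.5,"axial_pitch_um":3.87,"laterality":"OD","device_label":"standard","fovea_center":[4,32]}
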