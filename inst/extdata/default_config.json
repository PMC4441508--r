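{"detector_seed":101,"detector_path":null,"bandwidth_mm":15,"rank_alpha":0.5,"anatomy":{"min_size_mm":15,"max_size_mm":110,"margin_frac":0.1,"hu_floor":80},"septum":{"scale_mm":3,"dilation_mm":5,"score_floor":3,"edge_suppression_hu_mm":12,"c_ratio":0.5},"levelset":{"propagation_weight":1,"curvature_weight":0.3,"advection_weight":2,"septum_barrier_weight":1.5,"edge_hu_mm":25,"smooth_sigma_mm":1.5,"time_step":0.35,"max_iterations":250,"convergence_tol":0.0005,"region_tau_hu":150,"seed_radius_mm":6,"barrier_tol_mm":1,"clamp_mm":9,"reinit_every":20},"valve":{"rise_frac":0.15,"rise_min_mm":5,"notch_frac":0.25,"notch_min_mm":2,"outlier_factor":1.5},"rv_contrast_floor_hu":150,"rng_seed":1}
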