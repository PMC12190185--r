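{"body_mass_kg":66,"height_m":1.57,"shank_mass_frac":0.0465,"foot_mass_frac":0.0145,"shank_length_frac":0.246,"shank_com_frac":0.433,"intercondylar_width_frac":0.029}
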