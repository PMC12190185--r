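[{"name":"vasti","f_max":4000,"proximal_attachment":[0.042,0.03,0],"distal_attachment":[0.04,-0.045,0]},{"name":"rectus_femoris","f_max":1200,"proximal_attachment":[0.045,0.08,0],"distal_attachment":[0.04,-0.045,0]},{"name":"hamstrings_med","f_max":1500,"proximal_attachment":[-0.03,0.09,0.01],"distal_attachment":[-0.015,-0.03,0.03]},{"name":"hamstrings_lat","f_max":1200,"proximal_attachment":[-0.03,0.09,-0.01],"distal_attachment":[-0.015,-0.04,-0.035]},{"name":"gastroc_med","f_max":1400,"proximal_attachment":[-0.028,0.005,0.022],"distal_attachment":[-0.04,-0.38,0.01]},{"name":"gastroc_lat","f_max":900,"proximal_attachment":[-0.028,0.005,-0.022],"distal_attachment":[-0.04,-0.38,-0.01]},{"name":"tfl_itb","f_max":600,"proximal_attachment":[0.005,0.12,-0.04],"distal_attachment":[0.015,-0.025,-0.035]}]
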