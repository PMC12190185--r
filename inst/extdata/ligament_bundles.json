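[{"bundle_id":"ACL_am","ligament":"ACL","k":2600,"eps_r":0.03,"eps_lim":0.03,"femoral_attachment":[-0.008,0.012,-0.006],"tibial_attachment":[0.015,-0.015,0.002]},{"bundle_id":"ACL_pl","ligament":"ACL","k":2400,"eps_r":0.05,"eps_lim":0.03,"femoral_attachment":[-0.01,0.008,-0.008],"tibial_attachment":[0.012,-0.015,-0.004]},{"bundle_id":"PCL_al","ligament":"PCL","k":3200,"eps_r":-0.02,"eps_lim":0.03,"femoral_attachment":[0.002,0.01,0.008],"tibial_attachment":[-0.022,-0.02,0]},{"bundle_id":"PCL_pm","ligament":"PCL","k":2800,"eps_r":-0.01,"eps_lim":0.03,"femoral_attachment":[-0.002,0.006,0.01],"tibial_attachment":[-0.02,-0.022,0.004]},{"bundle_id":"MCL_sa","ligament":"MCL","k":2500,"eps_r":0.03,"eps_lim":0.03,"femoral_attachment":[0,0.012,0.042],"tibial_attachment":[0.008,-0.065,0.03]},{"bundle_id":"MCL_si","ligament":"MCL","k":2500,"eps_r":0.035,"eps_lim":0.03,"femoral_attachment":[-0.002,0.012,0.043],"tibial_attachment":[0.002,-0.06,0.032]},{"bundle_id":"MCL_sp","ligament":"MCL","k":2200,"eps_r":0.03,"eps_lim":0.03,"femoral_attachment":[-0.006,0.011,0.042],"tibial_attachment":[-0.008,-0.055,0.032]},{"bundle_id":"MCL_da","ligament":"MCL","k":1600,"eps_r":0.02,"eps_lim":0.03,"femoral_attachment":[0.002,0.01,0.04],"tibial_attachment":[0.005,-0.018,0.038]},{"bundle_id":"MCL_dp","ligament":"MCL","k":1600,"eps_r":0.02,"eps_lim":0.03,"femoral_attachment":[-0.005,0.01,0.04],"tibial_attachment":[-0.005,-0.018,0.038]},{"bundle_id":"LCL_a","ligament":"LCL","k":2200,"eps_r":0.012,"eps_lim":0.03,"femoral_attachment":[0.002,0.012,-0.042],"tibial_attachment":[-0.003,-0.048,-0.038]},{"bundle_id":"LCL_i","ligament":"LCL","k":2200,"eps_r":0.01,"eps_lim":0.03,"femoral_attachment":[-0.001,0.012,-0.043],"tibial_attachment":[-0.006,-0.048,-0.038]},{"bundle_id":"LCL_p","ligament":"LCL","k":2000,"eps_r":0.008,"eps_lim":0.03,"femoral_attachment":[-0.005,0.011,-0.042],"tibial_attachment":[-0.01,-0.047,-0.037]},{"bundle_id":"MPFL_s","ligament":"MPFL","k":800,"eps_r":0,"eps_lim":0.03,"femoral_attachment":[0.004,0.018,0.04],"tibial_attachment":[0.038,0.022,0.016]},{"bundle_id":"MPFL_i","ligament":"MPFL","k":800,"eps_r":0,"eps_lim":0.03,"femoral_attachment":[0.004,0.015,0.041],"tibial_attachment":[0.04,0.016,0.018]},{"bundle_id":"MPFL_d","ligament":"MPFL","k":700,"eps_r":-0.01,"eps_lim":0.03,"femoral_attachment":[0.004,0.012,0.041],"tibial_attachment":[0.041,0.01,0.018]},{"bundle_id":"LPFL_s","ligament":"LPFL","k":800,"eps_r":0,"eps_lim":0.03,"femoral_attachment":[0.004,0.018,-0.04],"tibial_attachment":[0.038,0.022,-0.016]},{"bundle_id":"LPFL_i","ligament":"LPFL","k":800,"eps_r":0,"eps_lim":0.03,"femoral_attachment":[0.004,0.015,-0.041],"tibial_attachment":[0.04,0.016,-0.018]},{"bundle_id":"LPFL_d","ligament":"LPFL","k":700,"eps_r":-0.01,"eps_lim":0.03,"femoral_attachment":[0.004,0.012,-0.041],"tibial_attachment":[0.041,0.01,-0.018]},{"bundle_id":"ALL","ligament":"ALL","k":1500,"eps_r":0.005,"eps_lim":0.03,"femoral_attachment":[-0.002,0.01,-0.043],"tibial_attachment":[0.012,-0.025,-0.035]},{"bundle_id":"PML","ligament":"PML","k":1600,"eps_r":0.025,"eps_lim":0.03,"femoral_attachment":[-0.01,0.01,0.035],"tibial_attachment":[-0.018,-0.02,0.03]},{"bundle_id":"POL","ligament":"POL","k":1800,"eps_r":0.03,"eps_lim":0.03,"femoral_attachment":[-0.006,0.014,0.038],"tibial_attachment":[-0.02,-0.025,0.028]},{"bundle_id":"PFL","ligament":"PFL","k":2000,"eps_r":0.01,"eps_lim":0.03,"femoral_attachment":[-0.006,0.008,-0.04],"tibial_attachment":[-0.015,-0.045,-0.036]}]
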