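specimen,sex,age_y,bmi_kg_m2,leg_side,leg_axis_deg,mlc_mean,mlc_sd,llc_mean,llc_sd
1,M,72,31.9,left,176.5,34.6,1.1,46.6,0.8
2,F,82,33.3,right,175.5,28.4,1.2,27.0,1.0
3,M,58,36.6,left,177.3,29.4,0.6,19.9,0.9
4,M,63,27.4,left,167.2,28.7,1.0,27.5,1.5
5,F,85,23.7,right,184.0,39.9,1.1,33.1,0.2
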