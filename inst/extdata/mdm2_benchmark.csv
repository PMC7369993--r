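complex_id,affinity_value,affinity_unit,affinity_type,dg_calculated,dg_calculated_se,dg_correction,dg_correction_se,dg_corrected,dg_corrected_se,dg_experimental
6GGN,0.08,nM,IC50,-17.05,0.33,1.04,0.07,-16.01,0.4,-13.76
5OC8,0.21,nM,Ki,-14.91,0.78,1.15,0.08,-13.76,0.86,-13.18
4ZYF,1.3,nM,Ki,-12.89,0.39,1.34,0.29,-11.55,0.68,-12.11
5LAZ,4,nM,IC50,-12.57,0.35,1.0,0.03,-11.57,0.38,-11.44
5LAY,34,nM,IC50,-12.04,0.29,0.98,0.1,-11.06,0.39,-10.19
5LAW,80,nM,IC50,-11.06,0.36,1.00,0.03,-10.06,0.39,-9.68
WK298,109,nM,Ki,-10.885,0.33,1.15,0.08,-9.73,0.41,-9.49
3TJ2,300,nM,Ki,-11.64,0.39,1.028,0.09,-10.64,0.48,-8.89
4MDN,600,nM,Ki,-9.79,0.40,1.19,0.18,-8.6,0.58,-8.47
5LAV,819,nM,IC50,-15.80,0.25,1.15,0.08,-14.65,0.33,-8.29
4MDQ,900,nM,Ki,-12.52,0.42,1.66,0.18,-10.86,0.6,-8.24
3LBK,916,nM,Ki,-10.49,0.28,1.12,0.03,-9.37,0.31,-8.22
4JV7,1000,nM,IC50,-14.56,0.29,1.42,0.18,-13.14,0.47,-8.63
4JV9,1800,nM,IC50,-15.73,0.29,1.62,0.27,-14.11,0.56,-8.27
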