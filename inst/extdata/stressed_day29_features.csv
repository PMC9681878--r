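feature_id,sample_id,mz,rt_min,ccs_A2,mobility_1k0,intensity,snr,ms2_ref
F01,stressed_d29,331.2265,1.84,183.0,,40000,200,
F02,stressed_d29,331.2266,2.03,188.0,,40000,200,
F03,stressed_d29,347.2216,2.13,194.0,,420000,2100,
F04,stressed_d29,329.2170,2.42,187.0,,178000,890,
F05,stressed_d29,347.2216,2.52,195.0,,420000,2100,
F06,stressed_d29,347.2216,2.76,192.0,,239000,1195,
F07,stressed_d29,331.2263,2.85,184.9,,1120000,5600,
F08,stressed_d29,287.2003,3.20,174.0,,60000,300,
F09,stressed_d29,331.2257,3.22,189.5,,560000,2800,
F10,stressed_d29,347.2216,3.61,192.8,,224000,1120,
F11,stressed_d29,331.2261,3.67,190.5,,560000,2800,
F12,stressed_d29,301.2160,3.92,180.5,,50000,250,
F13,stressed_d29,331.2261,4.17,186.0,,1120000,5600,
F14,stressed_d29,347.2213,4.21,193.0,,224000,1120,
F15,stressed_d29,347.2216,4.75,192.0,,236000,1180,
F16,stressed_d29,315.2319,4.99,185.3,,5000000,25000,
F17,stressed_d29,329.2474,6.56,190.5,,30000,150,
F18,stressed_d29,343.2632,8.95,196.0,,25000,125,
F19,stressed_d29,329.2472,9.65,189.9,,104000,520,
F20,stressed_d29,329.2109,9.92,185.0,,104000,520,
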