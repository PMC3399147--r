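name,family,emission_group,response_class,temp_slope,temp_ci_lo,temp_ci_hi,temp_r2,precip_slope,precip_ci_lo,precip_ci_hi,precip_r2,co2_start,co2_end
A1FI,IPCC-smooth,ipcc,n/a,0.136,0.133,0.140,0.98,0.166,0.161,0.170,0.98,368.448,925.531
A2,IPCC-smooth,ipcc,n/a,0.106,0.102,0.109,0.98,0.127,0.123,0.131,0.98,368.949,818.891
B1,IPCC-smooth,ipcc,n/a,0.056,0.055,0.057,0.99,0.073,0.071,0.074,0.99,368.936,531.371
B2,IPCC-smooth,ipcc,n/a,0.069,0.068,0.069,1.00,0.086,0.086,0.087,1.00,368.903,603.702
X901M,IGSM-latitude-amplified,reference,median,0.073,0.071,0.076,0.97,0.117,0.113,0.122,0.97,370.957,911.319
X902L,IGSM-latitude-amplified,reference,low,0.057,0.055,0.058,0.98,0.087,0.084,0.090,0.97,371.228,947.953
X903H,IGSM-latitude-amplified,reference,high,0.094,0.090,0.098,0.96,0.148,0.142,0.155,0.95,371.281,905.128
X904M,IGSM-latitude-amplified,stabilization,median,0.019,0.018,0.020,0.92,0.035,0.032,0.037,0.87,370.957,476.506
X905L,IGSM-latitude-amplified,stabilization,low,0.013,0.012,0.014,0.85,0.023,0.021,0.026,0.80,371.228,490.717
X906H,IGSM-latitude-amplified,stabilization,high,0.027,0.026,0.028,0.96,0.047,0.044,0.050,0.93,371.281,472.149
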