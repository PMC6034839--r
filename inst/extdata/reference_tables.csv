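table,row,T1a,T1b,T1c,T2,T3
state,pt_diameter_at_surgery_mm,4.5,8.5,15.1,28.5,64.6
state,pt_doublings,26.4,29.2,31.7,34.4,38.0
state,tvdt_pt_days,70.0,70.0,70.0,65.0,60.0
state,k_smts,1.00,1.00,1.00,1.00,1.00
state,tvdt_mts_days,70.0,70.0,70.0,65.0,60.0
state,mts_doublings,6.44,9.19,11.68,14.43,17.97
state,mts_diameter_mm,0.04,0.08,0.15,0.28,0.64
periods,pt_diameter_at_surgery_mm,4.5,8.5,15.1,28.5,64.6
periods,pt_doublings,26.4,29.2,31.7,34.4,38.0
periods,tvdt_pt_days,70.0,70.0,70.0,65.0,60.0
periods,wnh_years,11.5,11.5,11.5,10.7,9.9
periods,total_pt_years,5.1,5.6,6.1,6.1,6.2
periods,nonvisible_pt_years,3.8,3.8,3.8,3.5,3.3
periods,visible_pt_years,1.2,1.8,2.3,2.6,3.0
periods,nonvisible_mts1_years,1.2,1.8,2.3,2.6,3.0
periods,nonvisible_mts2_years,4.4,3.9,3.4,2.7,1.9
periods,visible_mts_years,2.0,2.0,2.0,1.9,1.7
periods,survival_years,6.4,5.9,5.4,4.5,3.6
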