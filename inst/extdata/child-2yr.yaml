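profile:
  label: child-2yr
  HR_bpm: 105.0
  BSA_m2: 0.55
  BM_kg: 12.0
  D_LVOT_cm: 0.9
  D_RVOT_cm: 1.07
chambers:
  LA:
    Emax_mmHg_per_mL: 1.937025511034169
    Emin_mmHg_per_mL: 0.968512755517084
    V0_mL: 1.0
    t_act_frac: 0.8
    tau_sys_frac: 0.2
    rise_frac: 0.5
  LV:
    Emax_mmHg_per_mL: 5.323649684604711
    Emin_mmHg_per_mL: 0.102684515365093
    V0_mL: 2.0
    t_act_frac: 0.0
    tau_sys_frac: 0.719096859609308
    rise_frac: 0.770346808598582
  RA:
    Emax_mmHg_per_mL: 0.441559099918703
    Emin_mmHg_per_mL: 0.220779549959351
    V0_mL: 1.0
    t_act_frac: 0.8
    tau_sys_frac: 0.2
    rise_frac: 0.5
  RV:
    Emax_mmHg_per_mL: 2.034861870436937
    Emin_mmHg_per_mL: 0.079605162734899
    V0_mL: 2.0
    t_act_frac: 0.0
    tau_sys_frac: 0.719096859609308
    rise_frac: 0.770346808598582
valves:
  R_mv_mmHg_s_per_mL: 0.004
  R_av_mmHg_s_per_mL: 0.018582501822094
  R_tv_mmHg_s_per_mL: 0.004
  R_pv_mmHg_s_per_mL: 0.008
systemic:
  arterial:
    R_mmHg_s_per_mL: 1.994069413130284
    C_mL_per_mmHg: 0.424214150259365
    V0_mL: 60.0
  venous:
    R_mmHg_s_per_mL: 0.05
    C_mL_per_mmHg: 20.287524988885981
    V0_mL: 330.0
pulmonary:
  arterial:
    R_mmHg_s_per_mL: 0.191367971771032
    C_mL_per_mmHg: 1.378154803297835
    V0_mL: 25.0
  venous:
    R_mmHg_s_per_mL: 0.035
    C_mL_per_mmHg: 5.409812574863741
    V0_mL: 120.0
total_blood_volume_mL: 793.212915278338869
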