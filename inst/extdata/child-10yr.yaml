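profile:
  label: child-10yr
  HR_bpm: 75.0
  BSA_m2: 1.1
  BM_kg: 32.0
  D_LVOT_cm: 1.6
  D_RVOT_cm: 1.9
chambers:
  LA:
    Emax_mmHg_per_mL: 0.968512755517084
    Emin_mmHg_per_mL: 0.484256377758542
    V0_mL: 2.0
    t_act_frac: 0.8
    tau_sys_frac: 0.2
    rise_frac: 0.5
  LV:
    Emax_mmHg_per_mL: 2.661824842302356
    Emin_mmHg_per_mL: 0.051342257682547
    V0_mL: 4.0
    t_act_frac: 0.0
    tau_sys_frac: 0.719096859609308
    rise_frac: 0.770346808598582
  RA:
    Emax_mmHg_per_mL: 0.220779549959351
    Emin_mmHg_per_mL: 0.110389774979676
    V0_mL: 2.0
    t_act_frac: 0.8
    tau_sys_frac: 0.2
    rise_frac: 0.5
  RV:
    Emax_mmHg_per_mL: 1.017430935218469
    Emin_mmHg_per_mL: 0.03980258136745
    V0_mL: 4.0
    t_act_frac: 0.0
    tau_sys_frac: 0.719096859609308
    rise_frac: 0.770346808598582
valves:
  R_mv_mmHg_s_per_mL: 0.002
  R_av_mmHg_s_per_mL: 0.009291250911047
  R_tv_mmHg_s_per_mL: 0.002
  R_pv_mmHg_s_per_mL: 0.004
systemic:
  arterial:
    R_mmHg_s_per_mL: 0.847479500580371
    C_mL_per_mmHg: 0.84842830051873
    V0_mL: 120.0
  venous:
    R_mmHg_s_per_mL: 0.025
    C_mL_per_mmHg: 40.575049977771961
    V0_mL: 660.0
pulmonary:
  arterial:
    R_mmHg_s_per_mL: 0.095683985885516
    C_mL_per_mmHg: 2.75630960659567
    V0_mL: 50.0
  venous:
    R_mmHg_s_per_mL: 0.0175
    C_mL_per_mmHg: 10.819625149727482
    V0_mL: 240.0
total_blood_volume_mL: 1586.425830556677738
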