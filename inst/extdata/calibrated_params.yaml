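units: SI
constants:
  temperature: 298.14999999999998
parameters:
  Lp: 9.9999999999999998e-13
  A_osm: 1.99e-11
  eps: 6000000
  Pc: 200000
  v_ext: 7.8499999999999994e-15
  eta_eq: 25000000
  k1: 0.32000000000000001
  k2a: 2.15e-14
  fusion_scale: 1
  r0: 5.0000000000000004e-06
  h0: 2.9999999999999999e-07
  L0: 0.00050000000000000001
  Osm_i: 0.29899999999999999
  Ca_o_ref: 0.001
  H_o_ref: 1.9952623149688787e-06
  K_o_ref: 0.001
  Cl_o_ref: 0.0030000000000000001
  Osm_o_ref: 0.35499799999999998
  Cm: 0.01
  ov_scale: 1
  g_vg1: 100
  Vh_vg1: -0.125
  s_vg1: 0.012
  g_vg2: 1100
  Vh_vg2: -0.095000000000000001
  s_vg2: 0.01
  g_vg3: 1200
  Vh_vg3: -0.105
  s_vg3: 0.0080000000000000002
  I_pump_max: 0.085000000000000006
  Vh_pump: -0.14999999999999999
  s_pump: 0.050000000000000003
  Km_pump: 9.9999999999999995e-08
  g_vg5: 0.10000000000000001
  Vh_vg5: -0.10000000000000001
  s_vg5: 0.02
  g_vg6: 50
  Vh_vg6: -0.080000000000000002
  s_vg6: 0.01
  g_Ca_sa: 200
  g_K_sa: 200
  g_Cl_sa: 0
  kOC0: 2
  kCO0: 2.3216170505872297e-19
  ka: 0.00020000000000000001
  k_relax_Ca: 2.7999999999999998
  k_relax_H: 30000
  k_relax_K: 0.02
  k_relax_Cl: 0.02
  setpoint_Ca: 1.9999999999999999e-07
  setpoint_H: 9.9999999999999995e-08
  setpoint_K: 0.20000000000000001
  setpoint_Cl: 0.059999999999999998
  buffer_Ca: 0
  buffer_H: 0
  tau_n: 28.5
init:
  v: 3.9269908169872421e-14
  P: 214533.6726361906
  L: 0.00050000000000000001
  eta: 23297277.550889548
  h: 4.2504375926433032e-07
  Ca_i: 1.2273204888476022e-05
  H_i: 1.0099413398082387e-07
  K_i: 0.19244591294356414
  Cl_i: 0.05886728783980269
  V: -0.12845214957455067
  p_Ca: 0.33299785724979725
  p_K: 0.33299785724979725
  n_K: 0.12352937453288357
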